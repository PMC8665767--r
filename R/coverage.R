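#' Strand-specific per-base coverage
#'
#' A \code{coverage_track} holds per-base, non-negative read counts for each
#' chromosome, one run-length-encoded vector per strand, plus the total
#' library depth (sum over both strands). Minus-strand values are stored
#' non-negative even when the source file encodes them as negatives, the
#' common PRO-seq convention.
#'
#' @param plus,minus named lists (by chromosome) of non-negative numeric
#'   vectors or \code{Rle} objects.
#' @return An object of class \code{coverage_track} with elements
#'   \code{plus}, \code{minus} (lists of \code{Rle}) and
#'   \code{library_depth}.
#' @export
coverage_track <- function(plus = list(), minus = list()) {
  as_rle_list <- function(x) {
    stopifnot(is.list(x))
    if (length(x) > 0 && is.null(names(x)))
      stop("coverage chromosomes must be named")
    lapply(x, function(v) {
      r <- if (inherits(v, "Rle")) v else S4Vectors::Rle(as.numeric(v))
      if (length(r) > 0 && min(S4Vectors::runValue(r)) < 0)
        stop("coverage values must be non-negative")
      r
    })
  }
  plus <- as_rle_list(plus)
  minus <- as_rle_list(minus)
  depth <- sum(vapply(plus, sum, numeric(1)), vapply(minus, sum, numeric(1)))
  structure(list(plus = plus, minus = minus, library_depth = depth),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(union(names(x$plus), names(x$minus))),
      "chromosome(s), library depth", format(x$library_depth), "\n")
  invisible(x)
}

strand_of <- function(track, strand) {
  if (strand == "+") track$plus else if (strand == "-") track$minus
  else stop("strand must be '+' or '-'")
}

#' Sum coverage over genomic windows
#'
#' Windows are 0-based half-open; parts outside the stored chromosome are
#' treated as zero, and chromosomes absent from the track count as zero with
#' a one-time warning (annotation/coverage naming mismatches surface here).
#'
#' @param track a \code{coverage_track}.
#' @param chrom chromosome name (scalar).
#' @param strand \code{"+"} or \code{"-"}.
#' @param starts,ends integer vectors, 0-based half-open windows.
#' @return numeric vector of window sums.
#' @export
coverage_window_sums <- function(track, chrom, strand, starts, ends) {
  stopifnot(length(starts) == length(ends), all(ends >= starts))
  sl <- strand_of(track, strand)
  if (!chrom %in% names(sl)) {
    warning("chromosome '", chrom, "' absent from coverage; treated as zero")
    return(numeric(length(starts)))
  }
  r <- sl[[chrom]]
  L <- length(r)
  s1 <- pmax(starts + 1L, 1L)
  e1 <- pmin(ends, L)
  out <- numeric(length(starts))
  ok <- s1 <= e1
  if (any(ok)) {
    v <- IRanges::Views(r, start = s1[ok], end = e1[ok])
    out[ok] <- IRanges::viewSums(v)
  }
  out
}

#' Extract per-base coverage over one window
#'
#' @inheritParams coverage_window_sums
#' @param start,end a single 0-based half-open window; bases outside the
#'   chromosome are zero-padded so the result always has length
#'   \code{end - start}.
#' @return numeric vector of per-base counts, 5' to 3' in genomic order.
#' @export
coverage_window_values <- function(track, chrom, strand, start, end) {
  stopifnot(end >= start)
  n <- end - start
  out <- numeric(n)
  sl <- strand_of(track, strand)
  if (!chrom %in% names(sl)) return(out)
  r <- sl[[chrom]]
  L <- length(r)
  s1 <- max(start + 1L, 1L)
  e1 <- min(end, L)
  if (s1 <= e1)
    out[(s1 - start):(e1 - start)] <- as.numeric(r[s1:e1])
  out
}

#' Read a strand-specific coverage pair
#'
#' Accepts bigWig (\code{.bw}/\code{.bigwig}) or bedGraph files, one file
#' per strand. Minus-strand values are absolute-valued on read unless
#' \code{abs_minus = FALSE}.
#'
#' @param plus_path,minus_path paths to the plus- and minus-strand files.
#' @param abs_minus take absolute values of the minus-strand signal.
#' @return a \code{coverage_track}.
#' @export
read_coverage <- function(plus_path, minus_path, abs_minus = TRUE) {
  read_one <- function(path, take_abs) {
    fmt <- if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE))
      "BigWig" else "bedGraph"
    gr <- rtracklayer::import(path, format = fmt)
    score <- as.numeric(GenomicRanges::mcols(gr)$score)
    if (take_abs) score <- abs(score)
    if (any(score < 0))
      stop("negative coverage values in ", path,
           " (set abs_minus = TRUE for minus-strand PRO-seq files)")
    cov <- GenomicRanges::coverage(gr, weight = score)
    lapply(as.list(cov), identity)
  }
  coverage_track(plus = read_one(plus_path, FALSE),
                 minus = read_one(minus_path, abs_minus))
}

#' Write a coverage pair as bedGraph
#'
#' @param track a \code{coverage_track}.
#' @param plus_path,minus_path output paths.
#' @param negate_minus write minus-strand values negated (PRO-seq
#'   convention).
#' @export
write_coverage <- function(track, plus_path, minus_path,
                           negate_minus = TRUE) {
  write_one <- function(sl, path, neg) {
    grs <- lapply(names(sl), function(ch) {
      r <- sl[[ch]]
      if (length(r) == 0) return(NULL)
      rl <- S4Vectors::runLength(r)
      rv <- S4Vectors::runValue(r)
      ends <- cumsum(rl)
      keep <- rv != 0
      if (!any(keep)) return(NULL)
      GenomicRanges::GRanges(
        seqnames = ch,
        ranges = IRanges::IRanges(start = (ends - rl + 1L)[keep],
                                  end = ends[keep]),
        score = if (neg) -rv[keep] else rv[keep])
    })
    grs <- grs[!vapply(grs, is.null, logical(1))]
    if (length(grs) == 0) {
      writeLines(character(0), path)
      return(invisible())
    }
    rtracklayer::export(do.call(c, grs), path, format = "bedGraph")
  }
  write_one(track$plus, plus_path, FALSE)
  write_one(track$minus, minus_path, negate_minus)
  invisible(c(plus_path, minus_path))
}
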