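#' Construct a table of mature-isoform annotations
#'
#' Internal coordinates are 0-based half-open on both strands; the
#' strand-aware 5' end (TSS) and 3' end (PAS) are derived columns. Exon
#' structure is never kept: nascent-RNA quantification works on pre-RNA
#' spans.
#'
#' @param df a data.frame with columns \code{transcript_id},
#'   \code{gene_id}, \code{chrom}, \code{start}, \code{end}, \code{strand}.
#' @return the validated data.frame with added \code{tss}, \code{pas} and
#'   \code{length} columns, class \code{c("mature_isoforms", "data.frame")}.
#' @export
mature_isoforms <- function(df) {
  need <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (any(is.na(df$gene_id) | df$gene_id == ""))
    stop("transcript without gene_id: ",
         paste(df$transcript_id[is.na(df$gene_id) | df$gene_id == ""],
               collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(df$start < 0 | df$end <= df$start))
    stop("invalid interval: require 0 <= start < end")
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df$pas <- ifelse(df$strand == "+", df$end - 1L, df$start)
  df$length <- df$end - df$start
  class(df) <- c("mature_isoforms", "data.frame")
  df
}

#' Read isoform annotations from GTF or BED
#'
#' GTF (Ensembl dialect, 1-based closed) is converted to the internal
#' 0-based half-open convention on read; BED is already half-open. One
#' \code{MatureIsoform} row is produced per transcript; exon lines are used
#' only to infer a transcript span when no \code{transcript} feature lines
#' are present.
#'
#' @param path file path.
#' @param format \code{"GTF"} or \code{"BED"}; guessed from the extension
#'   when missing.
#' @return a \code{mature_isoforms} data.frame.
#' @export
read_annotations <- function(path, format = c("auto", "GTF", "BED")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "BED" else "GTF"
  if (format == "GTF") {
    validate_gtf_lines(path)
    gr <- rtracklayer::import(path, format = "gtf")
    md <- GenomicRanges::mcols(gr)
    keep <- if ("type" %in% names(md) && any(md$type == "transcript"))
      md$type == "transcript"
    else if ("type" %in% names(md) && any(md$type == "exon"))
      md$type == "exon"
    else rep(TRUE, length(gr))
    gr <- gr[keep]
    md <- GenomicRanges::mcols(gr)
    if (!"transcript_id" %in% names(md))
      stop("GTF lacks transcript_id attributes")
    gid <- as.character(md$gene_id)
    if (any(is.na(gid) | gid == ""))
      stop("transcript without gene_id in ", path)
    df <- data.frame(
      transcript_id = as.character(md$transcript_id),
      gene_id = gid,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
    # exon rows -> one span per transcript
    if (anyDuplicated(df$transcript_id)) {
      sp <- split(df, df$transcript_id)
      df <- do.call(rbind, lapply(sp, function(d)
        data.frame(transcript_id = d$transcript_id[1],
                   gene_id = d$gene_id[1], chrom = d$chrom[1],
                   start = min(d$start), end = max(d$end),
                   strand = d$strand[1], stringsAsFactors = FALSE)))
      rownames(df) <- NULL
    }
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    nm <- GenomicRanges::mcols(gr)$name
    if (is.null(nm)) nm <- paste0("tx", seq_along(gr))
    df <- data.frame(
      transcript_id = as.character(nm),
      gene_id = as.character(nm),  # BED carries no gene_id
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
    if (any(df$strand == "*"))
      stop("BED input requires a strand column (BED6 or BED12)")
  }
  mature_isoforms(df)
}

# Cheap structural check so malformed GTF lines are reported by number.
validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^(#|\\s*$)", lines)
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  bad <- which(body)[nf < 9]
  if (length(bad) > 0)
    stop("malformed GTF line ", bad[1], " in ", path,
         " (expected 9 tab-separated fields)")
  invisible(TRUE)
}

#' Write a GTF file from a mature-isoform table
#'
#' Writes Ensembl-dialect transcript lines (1-based closed coordinates).
#'
#' @param isoforms a \code{mature_isoforms} data.frame.
#' @param path output path.
#' @export
write_annotations_gtf <- function(isoforms, path) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   isoforms$gene_id, isoforms$transcript_id)
  lines <- paste(isoforms$chrom, "nasdeconv", "transcript",
                 isoforms$start + 1L, isoforms$end, ".",
                 isoforms$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write an isoform abundance table as TSV
#'
#' @param tab an abundance table as returned by \code{\link{quantify}}.
#' @param path output path.
#' @export
write_abundance_table <- function(tab, path) {
  if (is.null(tab) || nrow(tab) == 0)
    stop("abundance table is empty")
  cols <- c("gene_id", "pre_rna_isoform_id", "member_transcript_ids",
            "chrom", "start", "end", "strand", "raw_beta",
            "normalized_abundance", "is_dominant")
  miss <- setdiff(cols, names(tab))
  if (length(miss) > 0)
    stop("abundance table missing columns: ", paste(miss, collapse = ", "))
  utils::write.table(tab[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an isoform abundance table written by \code{write_abundance_table}
#'
#' @param path TSV path.
#' @return a data.frame.
#' @export
read_abundance_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
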