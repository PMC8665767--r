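#' Group isoforms into non-overlapping strand-specific clusters
#'
#' Clusters are the transitive closure of same-strand genomic overlap, so
#' two genes overlapping on the same strand fall in one cluster, while
#' opposite-strand overlaps stay separate. Clusters on one strand never
#' overlap each other (maximality).
#'
#' @param isoforms a \code{mature_isoforms} data.frame.
#' @return a list of \code{isoform_cluster} objects.
#' @export
cluster_isoforms <- function(isoforms) {
  if (is.null(isoforms) || nrow(isoforms) == 0) return(list())
  out <- list()
  key <- paste(isoforms$chrom, isoforms$strand)
  for (k in unique(key)) {
    d <- isoforms[key == k, , drop = FALSE]
    d <- d[order(d$start, d$end), , drop = FALSE]
    cl_id <- integer(nrow(d))
    cur <- 1L
    cur_end <- d$end[1]
    cl_id[1] <- 1L
    if (nrow(d) > 1) for (i in 2:nrow(d)) {
      if (d$start[i] < cur_end) {        # strict overlap, half-open
        cl_id[i] <- cur
        cur_end <- max(cur_end, d$end[i])
      } else {
        cur <- cur + 1L
        cl_id[i] <- cur
        cur_end <- d$end[i]
      }
    }
    for (g in split(seq_len(nrow(d)), cl_id)) {
      m <- d[g, , drop = FALSE]
      out[[length(out) + 1L]] <- structure(list(
        chrom = m$chrom[1], strand = m$strand[1],
        start = min(m$start), end = max(m$end),
        isoforms = m), class = "isoform_cluster")
    }
  }
  ord <- order(vapply(out, `[[`, character(1), "chrom"),
               vapply(out, `[[`, numeric(1), "start"))
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$cluster_id <- sprintf("C%05d", i)
  out
}

#' @export
print.isoform_cluster <- function(x, ...) {
  cat(sprintf("isoform_cluster %s %s:%d-%d(%s): %d mature isoform(s)",
              x$cluster_id %||% "?", x$chrom, x$start, x$end, x$strand,
              nrow(x$isoforms)))
  if (!is.null(x$models)) cat(",", nrow(x$models), "pre-RNA model(s)")
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bin index (1-based, increasing 5'->3' along transcription) of a genomic
# position within a cluster. The grid is anchored at the cluster's 5'-most
# coordinate on its own strand.
cluster_bin_of <- function(cluster, pos) {
  b <- cluster$bin_size
  if (cluster$strand == "+")
    (pos - cluster$start) %/% b + 1L
  else
    (cluster$end - 1L - pos) %/% b + 1L
}

# Genomic 0-based half-open window of bin i (transcription order).
cluster_bin_window <- function(cluster, i) {
  b <- cluster$bin_size
  if (cluster$strand == "+") {
    s <- cluster$start + (i - 1L) * b
    cbind(start = s, end = pmin(s + b, cluster$end))
  } else {
    e <- cluster$end - (i - 1L) * b
    cbind(start = pmax(e - b, cluster$start), end = e)
  }
}

#' Tile a cluster with bins and apply TSS/PAS masks
#'
#' The cluster span is tiled with fixed-width bins from its 5'-most
#' coordinate. Each mature isoform occupies the contiguous bin range from
#' its TSS bin to its PAS bin; the first \code{mask5_bins} and last
#' \code{mask3_bins} of that range are masked to exclude the
#' promoter-proximal pause peak and termination peak from the fit. An
#' isoform too short to retain any unmasked bin keeps its single central
#' bin, with a warning.
#'
#' @param cluster an \code{isoform_cluster}.
#' @param bin_size bin width in bp (default 250).
#' @param mask5_bins,mask3_bins number of masked bins at the isoform 5' and
#'   3' ends (defaults 1 and 4).
#' @return the cluster with \code{bin_size}, \code{m} (bin count) and
#'   per-isoform bin/mask columns filled in.
#' @export
bin_and_mask <- function(cluster, bin_size = 250, mask5_bins = 1,
                         mask3_bins = 4) {
  stopifnot(bin_size >= 1)
  cluster$bin_size <- as.integer(bin_size)
  cluster$m <- as.integer(ceiling((cluster$end - cluster$start) / bin_size))
  cluster$mask5_bins <- as.integer(mask5_bins)
  cluster$mask3_bins <- as.integer(mask3_bins)
  iso <- cluster$isoforms
  iso$start_bin <- cluster_bin_of(cluster, iso$tss)
  iso$end_bin <- cluster_bin_of(cluster, iso$pas)
  stopifnot(all(iso$start_bin <= iso$end_bin))
  iso$ustart_bin <- iso$start_bin + mask5_bins
  iso$uend_bin <- iso$end_bin - mask3_bins
  short <- iso$ustart_bin > iso$uend_bin
  if (any(short)) {
    warning(sum(short), " isoform(s) fully masked by (",
            mask5_bins, ",", mask3_bins,
            ") masks; keeping a single central bin")
    mid <- (iso$start_bin[short] + iso$end_bin[short]) %/% 2L
    iso$ustart_bin[short] <- mid
    iso$uend_bin[short] <- mid
  }
  cluster$isoforms <- iso
  cluster
}

#' Collapse mature isoforms into distinguishable pre-RNA models
#'
#' Mature isoforms of one gene that share both their TSS bin and PAS bin
#' cannot be distinguished from nascent-RNA coverage and are merged into a
#' single pre-RNA isoform model recording all member transcript ids.
#'
#' @param cluster a binned cluster (see \code{\link{bin_and_mask}}).
#' @return the cluster with a \code{models} data.frame (one row per pre-RNA
#'   isoform: id, gene_id, bin range, members, TSS, genomic span, length).
#' @export
collapse_isoforms <- function(cluster) {
  iso <- cluster$isoforms
  stopifnot(!is.null(iso$start_bin))
  key <- paste(iso$gene_id, iso$start_bin, iso$end_bin, sep = "\r")
  groups <- split(seq_len(nrow(iso)), key)
  rows <- lapply(groups, function(idx) {
    m <- iso[idx, , drop = FALSE]
    data.frame(
      gene_id = m$gene_id[1],
      start_bin = m$start_bin[1], end_bin = m$end_bin[1],
      ustart_bin = m$ustart_bin[1], uend_bin = m$uend_bin[1],
      member_transcript_ids = paste(sort(m$transcript_id), collapse = ","),
      n_members = nrow(m),
      tss = if (cluster$strand == "+") min(m$tss) else max(m$tss),
      start = min(m$start), end = max(m$end),
      stringsAsFactors = FALSE)
  })
  models <- do.call(rbind, rows)
  # stable order: 5'-most first in transcription direction
  models <- models[order(models$start_bin, models$end_bin,
                         models$gene_id), , drop = FALSE]
  models$length <- models$end - models$start
  models$id <- sprintf("%s.m%d", models$gene_id,
                       as.integer(stats::ave(seq_len(nrow(models)),
                                             models$gene_id,
                                             FUN = seq_along)))
  rownames(models) <- NULL
  cluster$models <- models
  cluster
}

#' Build the bins-by-isoforms design matrix
#'
#' Entry \eqn{x_{i,j}} is 1 when pre-RNA isoform j spans bin i and the bin
#' is not masked for j, and 0 otherwise. Shape-profile adjustment later
#' replaces the ones by relative densities (see
#' \code{\link{adjust_design_matrix}}).
#'
#' @param cluster a collapsed cluster.
#' @return numeric matrix (m x n) with pre-RNA isoform ids as column names;
#'   a 0-column matrix when the cluster has no models.
#' @export
build_design_matrix <- function(cluster) {
  models <- cluster$models
  stopifnot(!is.null(models))
  X <- matrix(0, nrow = cluster$m, ncol = nrow(models),
              dimnames = list(NULL, models$id))
  for (j in seq_len(nrow(models)))
    X[models$ustart_bin[j]:models$uend_bin[j], j] <- 1
  X
}

#' Observed bin read-counts for a cluster
#'
#' Sums sense-strand coverage in each bin of the cluster grid, in
#' transcription order (bin 1 is 5'-most).
#'
#' @param cluster a binned cluster.
#' @param coverage a \code{coverage_track}.
#' @return numeric vector of length \code{cluster$m}.
#' @export
cluster_bin_counts <- function(cluster, coverage) {
  w <- cluster_bin_window(cluster, seq_len(cluster$m))
  coverage_window_sums(coverage, cluster$chrom, cluster$strand,
                       w[, "start"], w[, "end"])
}

#' Group isoforms whose TSSs lie within a distance
#'
#' Single-linkage grouping of annotated TSS positions within one gene; the
#' longest isoform of each group is returned as the representative (ties
#' broken by lexicographically smallest transcript_id). Used when comparing
#' dominant-isoform calls across samples, where sub-kilobase TSS
#' differences are not trusted.
#'
#' @param isoforms a \code{mature_isoforms} data.frame (one gene).
#' @param distance linkage distance in bp (default 1000).
#' @return the representative subset of \code{isoforms}, with a
#'   \code{tss_group} column.
#' @export
group_tss_within <- function(isoforms, distance = 1000) {
  stopifnot(nrow(isoforms) >= 1)
  ord <- order(isoforms$tss)
  tss <- isoforms$tss[ord]
  grp <- cumsum(c(1L, as.integer(diff(tss) >= distance)))
  gid <- integer(nrow(isoforms))
  gid[ord] <- grp
  isoforms$tss_group <- gid
  reps <- lapply(split(seq_len(nrow(isoforms)), gid), function(idx) {
    m <- isoforms[idx, , drop = FALSE]
    m <- m[order(-m$length, m$transcript_id), , drop = FALSE]
    m[1, , drop = FALSE]
  })
  out <- do.call(rbind, reps)
  rownames(out) <- NULL
  out
}

#' Classify a dominant isoform's TSS as internal or 5'-most
#'
#' A gene uses an internal TSS when its dominant isoform starts at least
#' \code{threshold} bp downstream (strand-aware) of the gene's 5'-most
#' annotated TSS; the boundary is inclusive.
#'
#' @param gene_isoforms all annotated isoforms of the gene
#'   (\code{mature_isoforms} rows).
#' @param dominant_tss TSS position of the dominant isoform.
#' @param threshold distance in bp (default 1000).
#' @return \code{"internal"} or \code{"five_prime"}.
#' @export
classify_internal_tss <- function(gene_isoforms, dominant_tss,
                                  threshold = 1000) {
  strand <- gene_isoforms$strand[1]
  most5 <- if (strand == "+") min(gene_isoforms$tss) else
    max(gene_isoforms$tss)
  d <- if (strand == "+") dominant_tss - most5 else most5 - dominant_tss
  if (d >= threshold) "internal" else "five_prime"
}
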