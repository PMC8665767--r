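#' Labeled TSS examples from a simulated dataset
#'
#' Positives are the TSSs of the placed isoforms (the simulator puts a
#' bidirectional pause-peak there); negatives are positions drawn from
#' gene bodies and intergenic gaps at least \code{min_dist} bp from every
#' true TSS, where only unidirectional gene-body signal or background is
#' present.
#'
#' @param dataset a \code{sim_dataset}.
#' @param n_negative_per_positive negatives drawn per positive
#'   (default 1).
#' @param min_dist exclusion distance around true TSSs (default 2000 bp).
#' @param seed RNG seed.
#' @return list with \code{features} (examples x 42 matrix),
#'   \code{labels} (logical) and \code{positions} (data.frame).
#' @export
sim_tss_training_set <- function(dataset, n_negative_per_positive = 1,
                                 min_dist = 2000, seed = 1L) {
  set.seed(seed)
  iso <- dataset$isoforms
  pos <- unique(data.frame(chrom = iso$chrom, tss = iso$tss,
                           strand = iso$strand,
                           stringsAsFactors = FALSE))
  n_neg <- ceiling(nrow(pos) * n_negative_per_positive)
  neg <- list()
  guard <- 0L
  while (length(neg) < n_neg && guard < 50L * n_neg) {
    guard <- guard + 1L
    i <- sample.int(nrow(iso), 1)
    inside <- stats::runif(1) < 0.7
    p <- if (inside) {
      round(stats::runif(1, iso$start[i], iso$end[i] - 1))
    } else {
      round(iso$end[i] + stats::runif(1, 500, 8000))
    }
    near <- pos$chrom == iso$chrom[i] & abs(pos$tss - p) < min_dist
    if (any(near)) next
    neg[[length(neg) + 1L]] <- data.frame(
      chrom = iso$chrom[i], tss = p,
      strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
  }
  neg <- do.call(rbind, neg)
  all_pos <- rbind(cbind(pos, label = TRUE), cbind(neg, label = FALSE))
  feats <- t(vapply(seq_len(nrow(all_pos)), function(i)
    extract_features(all_pos$tss[i], all_pos$chrom[i],
                     all_pos$strand[i], dataset$coverage),
    numeric(42)))
  list(features = feats, labels = all_pos$label, positions = all_pos)
}
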