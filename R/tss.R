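#' Extract bidirectional-transcription features around a TSS
#'
#' Active TSSs show divergent transcription with near-symmetric pause
#' peaks. The feature vector holds strand-specific read counts in 21
#' contiguous bins of width 51 bp (1071 bp total) centered on the TSS --
#' first the 21 sense-strand bins (5' to 3' in transcription direction),
#' then the 21 antisense bins -- jointly transformed to z-scores for scale
#' independence. If the raw counts are constant the vector is all zeros.
#'
#' @param tss TSS position (0-based).
#' @param chrom chromosome.
#' @param strand isoform strand.
#' @param coverage a \code{coverage_track}.
#' @param n_bins,bin_width feature geometry (defaults 21 and 51 bp).
#' @return numeric vector of length \code{2 * n_bins}.
#' @export
extract_features <- function(tss, chrom, strand, coverage,
                             n_bins = 21, bin_width = 51) {
  half <- (n_bins %/% 2) * bin_width + bin_width %/% 2
  w0 <- tss - half
  starts <- w0 + (seq_len(n_bins) - 1L) * bin_width
  ends <- starts + bin_width
  anti <- if (strand == "+") "-" else "+"
  sense <- coverage_window_sums(coverage, chrom, strand, starts, ends)
  asense <- coverage_window_sums(coverage, chrom, anti, starts, ends)
  if (strand == "-") {
    sense <- rev(sense)
    asense <- rev(asense)
  }
  x <- c(sense, asense)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(numeric(length(x)))
  (x - mean(x)) / s
}

#' Build a labeled TSS training set from cap-analysis evidence
#'
#' Candidate TSSs overlapping an active-TSS peak are positives, keeping
#' per peak only the candidate with the maximum cap-read signal; a
#' candidate is a negative only if it overlaps no peak, lies more than
#' \code{active_dist} bp from every positive and more than \code{read_dist}
#' bp from every cap read. Remaining candidates are dropped.
#'
#' @param candidates data.frame with \code{chrom}, \code{tss},
#'   \code{strand}.
#' @param peaks data.frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open), or a BED path.
#' @param cap_reads data.frame with \code{chrom}, \code{pos}, or a BED
#'   path (read starts are used).
#' @param active_dist,read_dist exclusion distances in bp (defaults 100
#'   and 25).
#' @return \code{candidates} subset with a logical \code{label} column
#'   (TRUE = active).
#' @export
build_training_set <- function(candidates, peaks, cap_reads,
                               active_dist = 100, read_dist = 25) {
  if (is.character(peaks)) peaks <- read_bed_df(peaks)
  if (is.character(cap_reads)) {
    b <- read_bed_df(cap_reads)
    cap_reads <- data.frame(chrom = b$chrom, pos = b$start)
  }
  n <- nrow(candidates)
  peak_of <- rep(NA_integer_, n)
  signal <- numeric(n)
  for (i in seq_len(n)) {
    hit <- which(peaks$chrom == candidates$chrom[i] &
                   peaks$start <= candidates$tss[i] &
                   candidates$tss[i] < peaks$end)
    if (length(hit) > 0) peak_of[i] <- hit[1]
    near <- cap_reads$chrom == candidates$chrom[i] &
      abs(cap_reads$pos - candidates$tss[i]) <= read_dist
    signal[i] <- sum(near)
  }
  pos_idx <- integer(0)
  for (p in unique(stats::na.omit(peak_of))) {
    members <- which(peak_of == p)
    pos_idx <- c(pos_idx, members[which.max(signal[members])])
  }
  active <- candidates[pos_idx, , drop = FALSE]
  neg_ok <- vapply(seq_len(n), function(i) {
    if (!is.na(peak_of[i])) return(FALSE)
    near_active <- any(active$chrom == candidates$chrom[i] &
                         abs(active$tss - candidates$tss[i]) <= active_dist)
    if (near_active) return(FALSE)
    near_read <- any(cap_reads$chrom == candidates$chrom[i] &
                       abs(cap_reads$pos - candidates$tss[i]) <= read_dist)
    !near_read
  }, logical(1))
  pos_df <- candidates[pos_idx, , drop = FALSE]
  pos_df$label <- rep(TRUE, nrow(pos_df))
  neg_df <- candidates[neg_ok, , drop = FALSE]
  neg_df$label <- rep(FALSE, nrow(neg_df))
  if (nrow(pos_df) == 0 || nrow(neg_df) == 0)
    stop("training set needs both positive and negative examples")
  out <- rbind(pos_df, neg_df)
  rownames(out) <- NULL
  out
}

read_bed_df <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Train a TSS activity classifier
#'
#' Two pluggable backends satisfy the 42-features-to-probability contract:
#' \code{"logistic"} (default; a regularized logistic regression) and
#' \code{"conv"}, a small 1-D convolutional network -- one convolution
#' layer over the 21 positions with the two strands as channels, ReLU,
#' max-pooling, dropout, a dense layer and a sigmoid output -- trained
#' with Adam and early stopping on validation loss.
#'
#' @param features matrix (examples x 42) from
#'   \code{\link{extract_features}}.
#' @param labels logical or 0/1 vector.
#' @param method \code{"logistic"} or \code{"conv"}.
#' @param seed RNG seed for weight init / dropout / validation split.
#' @param ... backend options: for \code{"conv"}, \code{filters} (16),
#'   \code{kernel} (5), \code{pool} (2), \code{dropout} (0.3),
#'   \code{lr} (1e-3), \code{epochs} (200), \code{patience} (15),
#'   \code{batch} (32), \code{val_frac} (0.2).
#' @return a \code{tss_model}.
#' @export
train_tss_classifier <- function(features, labels,
                                 method = c("logistic", "conv"),
                                 seed = 1L, ...) {
  method <- match.arg(method)
  y <- as.numeric(labels)
  stopifnot(nrow(features) == length(y), all(y %in% c(0, 1)))
  fit <- if (method == "logistic")
    fit_logistic_tss(features, y)
  else
    fit_conv_tss(features, y, seed = seed, ...)
  structure(list(method = method, fit = fit, n_features = ncol(features)),
            class = "tss_model")
}

#' @export
print.tss_model <- function(x, ...) {
  cat("tss_model (", x$method, " backend, ", x$n_features,
      " features)\n", sep = "")
  invisible(x)
}

fit_logistic_tss <- function(X, y) {
  d <- as.data.frame(X)
  names(d) <- paste0("f", seq_len(ncol(X)))
  # small ridge via glm on augmented data keeps separable fits finite
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = cbind(y = y, d), family = stats::binomial()))
  coefs <- stats::coef(fit)
  coefs[!is.finite(coefs)] <- 0
  list(coef = coefs)
}

predict_logistic_tss <- function(fit, X) {
  eta <- fit$coef[1] + drop(X %*% fit$coef[-1])
  eta <- pmin(pmax(eta, -30), 30)
  1 / (1 + exp(-eta))
}

#' Probability that TSSs are active
#'
#' @param model a \code{tss_model}.
#' @param features matrix (examples x 42).
#' @return numeric vector of probabilities in [0,1].
#' @export
predict_tss <- function(model, features) {
  if (is.null(model$fit)) stop("untrained model: train or load weights")
  features <- rbind(features)
  if (model$method == "logistic")
    predict_logistic_tss(model$fit, features)
  else
    predict_conv_tss(model$fit, features)
}

#' Classify one TSS
#'
#' All-zero feature vectors (no signal in the window) are called inactive
#' without consulting the model; otherwise the model probability is
#' thresholded (boundary inclusive).
#'
#' @param features length-42 feature vector.
#' @param model a \code{tss_model}.
#' @param threshold decision threshold (default 0.5).
#' @return list with \code{probability}, \code{active}, \code{rescued}
#'   (always FALSE here; see \code{\link{rescue_isoforms}}).
#' @export
classify_tss <- function(features, model, threshold = 0.5) {
  if (all(features == 0))
    return(list(probability = 0, active = FALSE, rescued = FALSE))
  p <- as.numeric(predict_tss(model, matrix(features, nrow = 1)))
  list(probability = p, active = p >= threshold, rescued = FALSE)
}

#' Upstream polymerase ratio (UPR)
#'
#' The sense-strand read density inside the isoform (+0.5 to +2 kb from
#' the TSS, in transcription direction) divided by the density upstream
#' (-3 to -0.5 kb). An isoform missed by the TSS classifier but with
#' UPR >= 5 carries polymerase signal that no upstream unit explains.
#' Zero-denominator rule: upstream 0 with inside > 0 gives +Inf; both
#' zero gives 0.
#'
#' @param tss TSS position (0-based).
#' @param chrom chromosome.
#' @param strand isoform strand.
#' @param coverage a \code{coverage_track}.
#' @return list with \code{inside_density}, \code{upstream_density},
#'   \code{ratio} (all reads/bp).
#' @export
compute_upr <- function(tss, chrom, strand, coverage) {
  win <- function(a, b) {  # strand-aware offsets from the TSS
    if (strand == "+") c(tss + a, tss + b) else c(tss - b, tss - a)
  }
  inside <- win(500, 2000)
  upstream <- win(-3000, -500)
  ins <- coverage_window_sums(coverage, chrom, strand,
                              inside[1], inside[2]) / 1500
  ups <- coverage_window_sums(coverage, chrom, strand,
                              upstream[1], upstream[2]) / 2500
  ratio <- if (ups == 0) {
    if (ins > 0) Inf else 0
  } else ins / ups
  list(inside_density = ins, upstream_density = ups, ratio = ratio)
}

#' Call TSS activity for every pre-RNA isoform of a cluster set
#'
#' @param clusters list of collapsed clusters.
#' @param coverage a \code{coverage_track}.
#' @param model a \code{tss_model}.
#' @param threshold decision threshold (default 0.5).
#' @return data.frame of calls: cluster index, model id, chrom, strand,
#'   tss, probability, active, rescued.
#' @export
call_tss_activity <- function(clusters, coverage, model, threshold = 0.5) {
  rows <- list()
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    if (is.null(cl$models) || nrow(cl$models) == 0) next
    for (j in seq_len(nrow(cl$models))) {
      f <- extract_features(cl$models$tss[j], cl$chrom, cl$strand, coverage)
      call <- classify_tss(f, model, threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = i, model_id = cl$models$id[j], chrom = cl$chrom,
        strand = cl$strand, tss = cl$models$tss[j],
        probability = call$probability, active = call$active,
        rescued = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Rescue isoforms with unexplained polymerase density
#'
#' An isoform whose TSS failed classification is re-admitted when its UPR
#' is at least \code{upr_min} and no active isoform TSS lies within
#' \code{upstream_bp} upstream or \code{downstream_bp} downstream of its
#' own TSS (TSS-to-TSS, strand-aware). Rescue only ever adds calls.
#'
#' @param calls a calls data.frame from \code{\link{call_tss_activity}}.
#' @param coverage a \code{coverage_track}.
#' @param upr_min UPR eligibility threshold (default 5, inclusive).
#' @param upstream_bp,downstream_bp isolation distances (defaults 5000 and
#'   6000).
#' @return the calls data.frame with \code{active}/\code{rescued} updated.
#' @export
rescue_isoforms <- function(calls, coverage, upr_min = 5,
                            upstream_bp = 5000, downstream_bp = 6000) {
  act <- calls[calls$active, , drop = FALSE]
  for (i in which(!calls$active)) {
    upr <- compute_upr(calls$tss[i], calls$chrom[i], calls$strand[i],
                       coverage)
    if (upr$ratio < upr_min) next
    same <- act[act$chrom == calls$chrom[i], , drop = FALSE]
    if (nrow(same) > 0) {
      d <- same$tss - calls$tss[i]            # genomic offset
      if (calls$strand[i] == "-") d <- -d     # now + = downstream
      if (any((d < 0 & -d <= upstream_bp) |
                (d >= 0 & d <= downstream_bp))) next
    }
    calls$active[i] <- TRUE
    calls$rescued[i] <- TRUE
  }
  calls
}

#' Restrict a design matrix to allowed isoforms
#'
#' Columns of isoforms not in the allowed set are removed before
#' optimization; their reported abundance is exactly zero. A user-supplied
#' inactive list takes precedence over classifier calls.
#'
#' @param X design matrix with isoform ids as column names.
#' @param allowed character vector of allowed isoform ids.
#' @return the reduced matrix (possibly 0 columns, with a warning when the
#'   cluster carries any excluded isoform and none remain).
#' @export
filter_design_matrix <- function(X, allowed) {
  keep <- colnames(X) %in% allowed
  if (!any(keep) && ncol(X) > 0)
    warning("all isoforms disallowed in cluster; reporting zeros")
  X[, keep, drop = FALSE]
}
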