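#' Deconvolve pre-RNA isoform abundances from nascent-RNA coverage
#'
#' The full analysis: cluster the annotations into strand-specific
#' non-overlapping groups, tile each cluster with bins and mask bins at
#' isoform starts/ends, collapse mature isoforms to distinguishable
#' pre-RNA models, optionally restrict models to active TSSs (classifier
#' calls plus the UPR rescue) and/or apply the shape-profile correction,
#' then estimate non-negative weights per cluster by least squares and
#' depth-normalize.
#'
#' @param isoforms a \code{mature_isoforms} data.frame.
#' @param coverage a \code{coverage_track}.
#' @param bin_size bin width in bp (default 250).
#' @param mask5_bins,mask3_bins masked bins at isoform 5'/3' ends
#'   (defaults 1 and 4).
#' @param log_space optimize in log space (default TRUE).
#' @param shape \code{TRUE} to fit the shape profile from the data,
#'   \code{FALSE} for no correction, or a \code{shape_profile} object.
#' @param tss_model a trained \code{tss_model} to gate isoforms on TSS
#'   activity, or \code{NULL} to skip TSS calling.
#' @param inactive_ids user-supplied pre-RNA isoform ids forced inactive
#'   (takes precedence over classifier calls).
#' @param tss_threshold classifier decision threshold (default 0.5).
#' @param pseudocount log-mode pseudocount (default 1).
#' @param verbose print progress messages.
#' @return an isoform abundance table (data.frame) with columns gene_id,
#'   pre_rna_isoform_id, member_transcript_ids, chrom, start, end, strand,
#'   raw_beta, normalized_abundance, is_dominant; the fitted
#'   \code{shape_profile}, TSS calls and cluster list are attached as
#'   attributes.
#' @export
quantify <- function(isoforms, coverage, bin_size = 250, mask5_bins = 1,
                     mask3_bins = 4, log_space = TRUE, shape = TRUE,
                     tss_model = NULL, inactive_ids = NULL,
                     tss_threshold = 0.5, pseudocount = 1,
                     verbose = FALSE) {
  clusters <- cluster_isoforms(isoforms)
  n_short <- 0L
  clusters <- lapply(clusters, function(cl) {
    withCallingHandlers(
      collapse_isoforms(bin_and_mask(cl, bin_size, mask5_bins,
                                     mask3_bins)),
      warning = function(w) {
        n_short <<- n_short + 1L
        invokeRestart("muffleWarning")
      })
  })
  if (n_short > 0 && verbose)
    message(n_short, " cluster(s) contain fully masked isoforms ",
            "(kept with one central bin)")

  profile <- if (inherits(shape, "shape_profile")) {
    shape
  } else if (isTRUE(shape)) {
    refs <- suppressWarnings(
      select_reference_isoforms(clusters, coverage))
    suppressWarnings(fit_profile(clusters, coverage, refs))
  } else {
    flat_profile()
  }

  calls <- NULL
  allowed_by_cluster <- NULL
  if (!is.null(tss_model)) {
    calls <- call_tss_activity(clusters, coverage, tss_model,
                               tss_threshold)
    calls <- rescue_isoforms(calls, coverage)
    allowed_by_cluster <- split(calls$model_id[calls$active],
                                calls$cluster[calls$active])
  }

  rows <- list()
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    if (is.null(cl$models) || nrow(cl$models) == 0) next
    X <- build_design_matrix(cl)
    X <- adjust_design_matrix(X, profile, cl)
    allowed <- colnames(X)
    if (!is.null(allowed_by_cluster))
      allowed <- intersect(allowed,
                           allowed_by_cluster[[as.character(i)]] %||%
                             character(0))
    if (!is.null(inactive_ids))
      allowed <- setdiff(allowed, inactive_ids)
    Xf <- suppressWarnings(filter_design_matrix(X, allowed))
    Y <- cluster_bin_counts(cl, coverage)
    beta <- numeric(nrow(cl$models))
    names(beta) <- cl$models$id
    if (ncol(Xf) > 0) {
      est <- estimate_abundance(Xf, Y, log_space = log_space,
                                pseudocount = pseudocount,
                                solver = if (log_space) "lbfgsb"
                                         else "nnls")
      beta[names(est)] <- est
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = cl$models$gene_id,
      pre_rna_isoform_id = cl$models$id,
      member_transcript_ids = cl$models$member_transcript_ids,
      chrom = cl$chrom,
      start = cl$models$start, end = cl$models$end,
      strand = cl$strand,
      raw_beta = unname(beta),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no isoforms to quantify")
  tab$normalized_abundance <- normalize_abundance(tab$raw_beta,
                                                  coverage$library_depth)
  tab$is_dominant <- FALSE
  genes <- aggregate_genes(tab)
  tab$is_dominant <- tab$pre_rna_isoform_id %in% genes$dominant_isoform
  attr(tab, "gene_table") <- genes
  attr(tab, "shape_profile") <- profile
  attr(tab, "tss_calls") <- calls
  attr(tab, "clusters") <- clusters
  tab
}
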