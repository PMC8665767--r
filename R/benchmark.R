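#' Pearson correlation and RMSE between estimates and truth
#'
#' Computed on the untransformed abundance scale over matched pairs.
#'
#' @param estimates,truth numeric vectors of equal length (>= 3).
#' @return list with \code{r}, \code{rmse}, \code{n}.
#' @export
evaluate_estimates <- function(estimates, truth) {
  stopifnot(length(estimates) == length(truth))
  if (length(truth) < 3) stop("need at least 3 matched points")
  list(r = stats::cor(estimates, truth),
       rmse = sqrt(mean((estimates - truth)^2)),
       n = length(truth))
}

#' The benchmark option grid
#'
#' All combinations of the optional features: TSS prediction on/off,
#' shape correction on/off, log transformation on/off, and 0/1/4 masked
#' bins at each of the 5' and 3' ends -- 72 schemes (2^3 x 3^2). The
#' default scheme (TSS on, shape on, log on, masks 1/4) is flagged.
#'
#' @return data.frame of 72 schemes with an \code{is_default} column.
#' @export
option_grid <- function() {
  g <- expand.grid(tss = c(TRUE, FALSE), shape = c(TRUE, FALSE),
                   log_space = c(TRUE, FALSE), mask5 = c(0, 1, 4),
                   mask3 = c(0, 1, 4), KEEP.OUT.ATTRS = FALSE)
  g$scheme <- sprintf("tss%d_shape%d_log%d_m5%d_m3%d",
                      g$tss, g$shape, g$log_space, g$mask5, g$mask3)
  g$is_default <- g$tss & g$shape & g$log_space & g$mask5 == 1 &
    g$mask3 == 4
  g
}

#' True abundance of each quantified pre-RNA model
#'
#' A pre-RNA model's truth is the sum of the true abundances of its
#' member transcripts (they share start and end bins, so their counts
#' add).
#'
#' @param tab an abundance table from \code{\link{quantify}}.
#' @param truth the \code{truth} table of a \code{sim_dataset}.
#' @return \code{tab} with \code{true_abundance} and isoform length
#'   columns added.
#' @export
model_truth <- function(tab, truth) {
  alpha <- stats::setNames(truth$true_abundance, truth$transcript_id)
  tab$true_abundance <- vapply(
    strsplit(tab$member_transcript_ids, ",", fixed = TRUE),
    function(ids) sum(alpha[ids]), numeric(1))
  tab$length <- tab$end - tab$start
  tab
}

#' Partition genes by dominant-isoform TSS usage
#'
#' A gene belongs to the internal-TSS stratum when its truly dominant
#' pre-RNA model starts at least \code{threshold} bp downstream
#' (strand-aware) of the gene's 5'-most annotated TSS.
#'
#' @param tab an abundance table augmented by \code{\link{model_truth}}.
#' @param isoforms the annotated \code{mature_isoforms} used for
#'   quantification.
#' @param threshold internal-TSS distance (default 1000 bp).
#' @return data.frame: gene_id, dominant (truth), stratum
#'   (\code{"internal"} or \code{"five_prime"}).
#' @export
stratify_by_tss_usage <- function(tab, isoforms, threshold = 1000) {
  rows <- lapply(split(seq_len(nrow(tab)), tab$gene_id), function(idx) {
    m <- tab[idx, , drop = FALSE]
    dom <- m[which.max(m$true_abundance), ]
    ann <- isoforms[isoforms$gene_id == dom$gene_id, , drop = FALSE]
    dom_tss <- if (dom$strand == "+") dom$start else dom$end - 1L
    data.frame(gene_id = dom$gene_id,
               dominant = dom$pre_rna_isoform_id,
               stratum = classify_internal_tss(ann, dom_tss, threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benchmark the deconvolution method against the read-count baseline
#'
#' Runs both estimators on a simulated dataset and scores them against
#' truth: Pearson r and RMSE at the gene level, the dominant-isoform
#' level (dominant chosen by true abundance) and the longest-isoform
#' level. All quantities are compared in per-million units -- truth
#' scaled to TPM over the gene set, the deconvolution weights
#' self-normalized the same way, and the read-count baseline given by
#' its own TPM formula -- so the methods and the truth share one scale.
#'
#' @param dataset a \code{sim_dataset}.
#' @param tab an abundance table from \code{\link{quantify}} run on the
#'   dataset.
#' @param trim5,trim3 RCB isoform-mode trims (defaults 250 and 1000 bp).
#' @return list with \code{results} (data.frame: method, level, r, rmse,
#'   n), \code{gene} (per-gene TPM estimates and truth), \code{strata}
#'   (from \code{\link{stratify_by_tss_usage}}) and the per-isoform
#'   tables \code{dominant} and \code{longest}.
#' @export
benchmark_deconv_rcb <- function(dataset, tab, trim5 = 250, trim3 = 1000) {
  tab <- model_truth(tab, dataset$truth)
  truth_scale <- 1e6 / sum(tab$true_abundance)
  beta_scale <- 1e6 / sum(tab$raw_beta)
  tab$truth_tpm <- tab$true_abundance * truth_scale
  tab$deconv_tpm <- tab$raw_beta * beta_scale

  # gene level ---------------------------------------------------------
  gene_truth <- tapply(tab$truth_tpm, tab$gene_id, sum)
  gene_est <- tapply(tab$deconv_tpm, tab$gene_id, sum)
  rcb_gene <- rcb_quantify(dataset$isoforms, dataset$coverage, "gene")
  gid <- names(gene_truth)
  stopifnot(all(gid %in% rcb_gene$id))
  gene_df <- data.frame(gene_id = gid,
                        truth = as.numeric(gene_truth),
                        deconv = as.numeric(gene_est),
                        rcb = rcb_gene$rcb[match(gid, rcb_gene$id)],
                        stringsAsFactors = FALSE)

  # isoform level: RCB with trims, TPM normalizer from gene unions -----
  models_iso <- mature_isoforms(data.frame(
    transcript_id = tab$pre_rna_isoform_id, gene_id = tab$gene_id,
    chrom = tab$chrom, start = tab$start, end = tab$end,
    strand = tab$strand, stringsAsFactors = FALSE))
  rcb_iso <- rcb_quantify(models_iso, dataset$coverage, "isoform",
                          trim5, trim3)
  tab$rcb_tpm <- rcb_iso$rcb[match(tab$pre_rna_isoform_id, rcb_iso$id)]

  pick <- function(score) {
    idx <- unlist(lapply(split(seq_len(nrow(tab)), tab$gene_id),
                         function(i) i[which.max(score[i])]))
    tab[idx, , drop = FALSE]
  }
  dom <- pick(tab$true_abundance)
  lng <- pick(tab$length)
  res <- rbind(
    data.frame(method = "deconv", level = "gene",
               evaluate_estimates(gene_df$deconv, gene_df$truth)),
    data.frame(method = "rcb", level = "gene",
               evaluate_estimates(gene_df$rcb, gene_df$truth)),
    data.frame(method = "deconv", level = "dominant",
               evaluate_estimates(dom$deconv_tpm, dom$truth_tpm)),
    data.frame(method = "rcb", level = "dominant",
               evaluate_estimates(dom$rcb_tpm, dom$truth_tpm)),
    data.frame(method = "deconv", level = "longest",
               evaluate_estimates(lng$deconv_tpm, lng$truth_tpm)),
    data.frame(method = "rcb", level = "longest",
               evaluate_estimates(lng$rcb_tpm, lng$truth_tpm)))
  strata <- stratify_by_tss_usage(tab, dataset$isoforms)
  list(results = res, gene = gene_df, strata = strata,
       dominant = dom, longest = lng)
}

#' Run the full 72-scheme option grid
#'
#' Quantifies a simulated dataset under every scheme of
#' \code{\link{option_grid}} and evaluates gene-level and
#' dominant-isoform accuracy in per-million space. Intended for
#' moderate-size datasets; the shape profile is refit per scheme when
#' enabled.
#'
#' @param dataset a \code{sim_dataset}.
#' @param tss_model a trained \code{tss_model} (used by schemes with TSS
#'   prediction on).
#' @param schemes scheme table (default the full grid).
#' @param bin_size bin width in bp.
#' @return the scheme table with gene-level and dominant-isoform r and
#'   RMSE columns appended.
#' @export
run_option_grid <- function(dataset, tss_model, schemes = option_grid(),
                            bin_size = 250) {
  out <- schemes
  out$r_gene <- out$rmse_gene <- out$r_dominant <-
    out$rmse_dominant <- NA_real_
  for (i in seq_len(nrow(schemes))) {
    s <- schemes[i, ]
    tab <- quantify(dataset$isoforms, dataset$coverage,
                    bin_size = bin_size, mask5_bins = s$mask5,
                    mask3_bins = s$mask3, log_space = s$log_space,
                    shape = s$shape,
                    tss_model = if (s$tss) tss_model else NULL)
    tab <- model_truth(tab, dataset$truth)
    tab$truth_tpm <- tab$true_abundance * 1e6 / sum(tab$true_abundance)
    tab$deconv_tpm <- if (sum(tab$raw_beta) > 0)
      tab$raw_beta * 1e6 / sum(tab$raw_beta) else tab$raw_beta
    g_truth <- tapply(tab$truth_tpm, tab$gene_id, sum)
    g_est <- tapply(tab$deconv_tpm, tab$gene_id, sum)
    ev_g <- evaluate_estimates(as.numeric(g_est), as.numeric(g_truth))
    idx <- unlist(lapply(split(seq_len(nrow(tab)), tab$gene_id),
                         function(k) k[which.max(tab$true_abundance[k])]))
    ev_d <- evaluate_estimates(tab$deconv_tpm[idx], tab$truth_tpm[idx])
    out$r_gene[i] <- ev_g$r; out$rmse_gene[i] <- ev_g$rmse
    out$r_dominant[i] <- ev_d$r; out$rmse_dominant[i] <- ev_d$rmse
  }
  out
}
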