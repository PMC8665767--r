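#' Shannon entropy of an isoform-usage distribution
#'
#' @param p probabilities (non-negative; normalized to sum to one if not
#'   already). The convention 0 * log2(0) = 0 applies.
#' @return entropy in bits.
#' @export
gene_entropy <- function(p) {
  if (any(p < 0)) stop("negative probability")
  s <- sum(p)
  if (s == 0) return(0)
  p <- p / s
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Decompose isoform diversity into transcriptional and
#' post-transcriptional entropy
#'
#' For each gene, pre-RNA isoform usage X (abundances \code{q}) and
#' mature-RNA isoform usage Y (abundances \code{q'}) give Shannon
#' entropies H(X) and H(Y). Because each mature isoform maps to exactly
#' one pre-RNA isoform, the joint entropy H(X,Y) equals H(Y), so the
#' chain rule attributes H(Y|X) = H(Y) - H(X) to post-transcriptional
#' processes and the fraction H(X)/H(X,Y) to primary transcription.
#' Set-level entropies are sums over genes (independence assumption),
#' also reported per gene; the set-level fraction uses summed entropies,
#' not a mean of per-gene ratios. Since X and Y are measured by different
#' upstream methods, H(Y) < H(X) can occur for individual genes; such
#' negative H(Y|X) values are reported as-is and flagged.
#'
#' @param pre data.frame of pre-RNA abundances: \code{gene_id},
#'   \code{isoform_id}, \code{abundance}.
#' @param mature data.frame of mature abundances: \code{gene_id},
#'   \code{transcript_id}, \code{abundance}.
#' @param map compatibility map: \code{transcript_id} (mature) to
#'   \code{isoform_id} (pre-RNA); every mature isoform must map to
#'   exactly one pre-RNA isoform.
#' @param genes optional gene subset (default: genes present in both
#'   tables).
#' @return an \code{entropy_decomposition}: \code{per_gene} data.frame
#'   (H_x, H_y, H_y_given_x, flagged negatives) and \code{summary} with
#'   total and per-gene-mean entropies and the transcriptional fraction.
#' @export
decompose_entropy <- function(pre, mature, map, genes = NULL) {
  unmapped <- setdiff(mature$transcript_id, map$transcript_id)
  if (length(unmapped) > 0)
    stop("mature isoform(s) with no mapped pre-RNA isoform: ",
         paste(utils::head(unmapped, 10), collapse = ", "))
  if (anyDuplicated(map$transcript_id))
    stop("compatibility map must assign each mature isoform to exactly ",
         "one pre-RNA isoform")
  if (is.null(genes))
    genes <- intersect(unique(pre$gene_id), unique(mature$gene_id))
  rows <- lapply(genes, function(g) {
    qx <- pre$abundance[pre$gene_id == g]
    qy <- mature$abundance[mature$gene_id == g]
    hx <- gene_entropy(qx)
    hy <- gene_entropy(qy)
    data.frame(gene_id = g, H_x = hx, H_y = hy,
               H_y_given_x = hy - hx,
               negative_conditional = hy < hx,
               stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, rows)
  tot_x <- sum(per_gene$H_x)
  tot_y <- sum(per_gene$H_y)
  summary <- list(
    n_genes = nrow(per_gene),
    H_x_total = tot_x, H_xy_total = tot_y,
    H_y_given_x_total = tot_y - tot_x,
    H_x_per_gene = tot_x / nrow(per_gene),
    H_xy_per_gene = tot_y / nrow(per_gene),
    H_y_given_x_per_gene = (tot_y - tot_x) / nrow(per_gene),
    fraction_transcriptional = if (tot_y > 0) tot_x / tot_y else
      NA_real_)
  structure(list(per_gene = per_gene, summary = summary),
            class = "entropy_decomposition")
}

#' @export
print.entropy_decomposition <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("entropy decomposition over %d genes:\n",
                     "  H(X,Y) = %.3f bits/gene, H(X) = %.3f, ",
                     "H(Y|X) = %.3f\n",
                     "  transcriptional fraction H(X)/H(X,Y) = %.3f\n"),
              s$n_genes, s$H_xy_per_gene, s$H_x_per_gene,
              s$H_y_given_x_per_gene, s$fraction_transcriptional))
  if (any(x$per_gene$negative_conditional))
    cat("  note:", sum(x$per_gene$negative_conditional),
        "gene(s) with negative H(Y|X)\n")
  invisible(x)
}

#' Bootstrap SD of the set-level entropy quantities
#'
#' Genes are resampled with replacement; the SD over replicates of the
#' per-gene-mean entropies and the transcriptional fraction estimates the
#' uncertainty of the set-level summary.
#'
#' @param decomposition an \code{entropy_decomposition}.
#' @param n_boot replicates (default 100).
#' @param seed RNG seed.
#' @return named numeric vector of SDs.
#' @export
bootstrap_entropy_sd <- function(decomposition, n_boot = 100, seed = 1L) {
  pg <- decomposition$per_gene
  stopifnot(nrow(pg) >= 2)
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(nrow(pg), replace = TRUE)
    tx <- sum(pg$H_x[idx]); ty <- sum(pg$H_y[idx])
    c(H_x_per_gene = tx / length(idx),
      H_xy_per_gene = ty / length(idx),
      H_y_given_x_per_gene = (ty - tx) / length(idx),
      fraction_transcriptional = if (ty > 0) tx / ty else NA_real_)
  }, numeric(4))
  apply(reps, 1, stats::sd, na.rm = TRUE)
}

#' Read the abundance TSVs consumed by the entropy analysis
#'
#' @param path TSV with a header; pre-RNA tables need columns
#'   \code{gene_id}, \code{isoform_id}, \code{abundance}; mature tables
#'   \code{gene_id}, \code{transcript_id}, \code{abundance}; maps
#'   \code{transcript_id}, \code{isoform_id}.
#' @return data.frame.
#' @export
read_entropy_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
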