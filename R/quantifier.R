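#' Non-negative least squares by the Lawson-Hanson active-set method
#'
#' Solves \eqn{\min_{\beta \ge 0} \|y - A\beta\|^2} exactly. This is the
#' default linear-mode solver for isoform weights; the bounded
#' quasi-Newton path (\code{\link{estimate_abundance}} with
#' \code{solver = "lbfgsb"}) must agree with it to high precision.
#'
#' @param A design matrix (m x n).
#' @param y response vector of length m.
#' @param tol dual-feasibility tolerance.
#' @return non-negative coefficient vector of length n.
#' @export
nnls_fit <- function(A, y, tol = 1e-10) {
  n <- ncol(A)
  if (n == 0) return(numeric(0))
  x <- numeric(n)
  passive <- logical(n)
  scale <- max(abs(crossprod(A, y)), 1)
  w <- drop(crossprod(A, y - A %*% x))
  it <- 0
  solve_passive <- function(idx) {
    Ap <- A[, idx, drop = FALSE]
    s <- tryCatch(solve(crossprod(Ap), crossprod(Ap, y)),
                  error = function(e) NULL)
    if (is.null(s)) {  # collinear columns: least-norm via QR
      s <- qr.coef(qr(Ap), y)
      s[is.na(s)] <- 0
    }
    drop(s)
  }
  while (any(!passive) && max(w[!passive]) > tol * scale) {
    it <- it + 1
    if (it > 30 * n) break
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      idx <- which(passive)
      s_p <- solve_passive(idx)
      if (all(s_p > tol)) {
        x[] <- 0
        x[idx] <- s_p
        break
      }
      neg <- s_p <= tol
      alpha <- min(x[idx][neg] / (x[idx][neg] - s_p[neg]))
      x[idx] <- x[idx] + alpha * (s_p - x[idx])
      passive[idx][x[idx] <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, y - A %*% x))
  }
  x
}

# Documented optimizer start point: per-isoform mean of Y over its
# unmasked bins divided by the column's mean positive weight.
abundance_start <- function(X, Y) {
  vapply(seq_len(ncol(X)), function(j) {
    rows <- X[, j] > 0
    if (!any(rows)) return(0)
    max(mean(Y[rows]) / mean(X[rows, j]), 0)
  }, numeric(1))
}

#' Estimate isoform weights for one cluster
#'
#' Minimizes the squared difference between observed and expected bin
#' read-counts subject to non-negative weights. In linear mode the exact
#' active-set NNLS solver is the default; \code{solver = "lbfgsb"} uses
#' box-constrained quasi-Newton (BFGS with a boundary of zero) instead. In
#' log mode the residuals are
#' \eqn{\log(y_i + c) - \log((X\beta)_i + c)} with pseudocount \eqn{c},
#' optimized by box-constrained quasi-Newton from a documented start
#' point, corresponding to a log-normal read-count assumption. Bins in
#' which no isoform has positive weight carry no information and are
#' dropped from the objective.
#'
#' @param X design matrix (m x n), possibly shape-adjusted.
#' @param Y observed bin counts of length m.
#' @param log_space use the log-space objective.
#' @param pseudocount log-mode pseudocount (default 1).
#' @param solver linear-mode solver: \code{"nnls"} (exact) or
#'   \code{"lbfgsb"}.
#' @param maxit,gr_tol optimizer controls for the quasi-Newton path.
#' @return non-negative weight vector named by isoform id.
#' @export
estimate_abundance <- function(X, Y, log_space = FALSE, pseudocount = 1,
                               solver = c("nnls", "lbfgsb"),
                               maxit = 500, gr_tol = 1e-8) {
  solver <- match.arg(solver)
  stopifnot(nrow(X) == length(Y))
  if (ncol(X) == 0) return(numeric(0))
  keep <- rowSums(X > 0) > 0
  A <- X[keep, , drop = FALSE]
  y <- Y[keep]
  beta <- if (all(y == 0)) {
    numeric(ncol(X))
  } else if (!log_space && solver == "nnls") {
    nnls_fit(A, y)
  } else {
    obj <- if (log_space) {
      ly <- log(y + pseudocount)
      function(b) sum((ly - log(drop(A %*% b) + pseudocount))^2)
    } else {
      function(b) sum((y - drop(A %*% b))^2)
    }
    grad <- if (log_space) {
      ly <- log(y + pseudocount)
      function(b) {
        mu <- drop(A %*% b) + pseudocount
        drop(crossprod(A, -2 * (ly - log(mu)) / mu))
      }
    } else {
      function(b) drop(crossprod(A, -2 * (y - drop(A %*% b))))
    }
    start <- abundance_start(A, y)
    res <- stats::optim(start, obj, grad, method = "L-BFGS-B",
                        lower = rep(0, ncol(A)),
                        control = list(maxit = maxit, factr = 10,
                                       pgtol = gr_tol))
    if (res$convergence != 0 && res$convergence != 52)
      warning("optimizer did not converge (code ", res$convergence,
              "); returning best iterate")
    pmax(res$par, 0)
  }
  names(beta) <- colnames(X)
  beta
}

#' Depth-normalize raw isoform weights
#'
#' @param beta raw weights.
#' @param library_depth total mapped read count; must be positive.
#' @return weights scaled by \code{1e6 / library_depth} (per-million
#'   units).
#' @export
normalize_abundance <- function(beta, library_depth) {
  if (!is.numeric(library_depth) || library_depth <= 0)
    stop("library_depth must be > 0")
  beta * 1e6 / library_depth
}

#' Aggregate isoform abundances to genes and call dominant isoforms
#'
#' Gene abundance is the exact sum of member isoform weights. The dominant
#' isoform is the argmax weight; ties go to the longer isoform, then the
#' lexicographically smallest id.
#'
#' @param tab an isoform abundance table (from \code{\link{quantify}}).
#' @return data.frame: gene_id, n_isoforms, raw_abundance,
#'   normalized_abundance, dominant_isoform.
#' @export
aggregate_genes <- function(tab) {
  sp <- split(seq_len(nrow(tab)), tab$gene_id)
  rows <- lapply(sp, function(idx) {
    m <- tab[idx, , drop = FALSE]
    len <- m$end - m$start
    ord <- order(-m$raw_beta, -len, m$pre_rna_isoform_id)
    data.frame(gene_id = m$gene_id[1], n_isoforms = nrow(m),
               raw_abundance = sum(m$raw_beta),
               normalized_abundance = sum(m$normalized_abundance),
               dominant_isoform = m$pre_rna_isoform_id[ord[1]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read-count-based (RCB) abundance in transcripts per million
#'
#' The field's naive baseline: \eqn{q_i = r_i \cdot 10^6 / (f_i T)} with
#' \eqn{T = \sum_g r_g / f_g} over all genes, where \eqn{r_i} is the read
#' count in the region and \eqn{f_i} its length.
#'
#' @param reads read counts per region.
#' @param lengths region lengths in bp (all > 0).
#' @param T optional normalizer; computed from \code{reads}/\code{lengths}
#'   when missing (gene mode). Pass a gene-level T when scoring isoform
#'   regions.
#' @return TPM-style abundances.
#' @export
rcb_formula <- function(reads, lengths, T = NULL) {
  if (any(lengths <= 0)) stop("region length must be > 0")
  if (is.null(T)) T <- sum(reads / lengths)
  reads * 1e6 / (lengths * T)
}

#' RCB quantification of genes or isoforms
#'
#' Gene mode counts reads over the union of the gene's annotated isoform
#' spans. Isoform mode counts reads over each isoform span trimmed by
#' \code{trim5} bp after the TSS and \code{trim3} bp before the PAS (to
#' skip pause and termination peaks), while the TPM normalizer T is always
#' computed at the gene level so isoform values share the gene scale.
#'
#' @param isoforms a \code{mature_isoforms} data.frame (isoform mode
#'   scores each row; ids taken from \code{transcript_id}).
#' @param coverage a \code{coverage_track}.
#' @param mode \code{"gene"} or \code{"isoform"}.
#' @param trim5,trim3 isoform-mode trims in bp (defaults 250 and 1000).
#' @return data.frame with id, reads, length and \code{rcb} (TPM).
#' @export
rcb_quantify <- function(isoforms, coverage, mode = c("gene", "isoform"),
                         trim5 = 250, trim3 = 1000) {
  mode <- match.arg(mode)
  genes <- split(seq_len(nrow(isoforms)), isoforms$gene_id)
  gene_stats <- lapply(genes, function(idx) {
    m <- isoforms[idx, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(m$start + 1L, m$end))
    r <- sum(coverage_window_sums(coverage, m$chrom[1], m$strand[1],
                                  IRanges::start(ir) - 1L,
                                  IRanges::end(ir)))
    c(reads = r, len = sum(IRanges::width(ir)))
  })
  gr <- vapply(gene_stats, `[[`, numeric(1), "reads")
  gf <- vapply(gene_stats, `[[`, numeric(1), "len")
  T <- sum(gr / gf)
  if (mode == "gene") {
    out <- data.frame(id = names(genes), reads = unname(gr),
                      length = unname(gf),
                      rcb = rcb_formula(unname(gr), unname(gf), T),
                      stringsAsFactors = FALSE)
    return(out)
  }
  s <- ifelse(isoforms$strand == "+", isoforms$start + trim5,
              isoforms$start + trim3)
  e <- ifelse(isoforms$strand == "+", isoforms$end - trim3,
              isoforms$end - trim5)
  bad <- e <= s
  if (any(bad)) {  # isoform shorter than the trims: fall back to full span
    s[bad] <- isoforms$start[bad]
    e[bad] <- isoforms$end[bad]
  }
  reads <- vapply(seq_len(nrow(isoforms)), function(i)
    coverage_window_sums(coverage, isoforms$chrom[i], isoforms$strand[i],
                         s[i], e[i]), numeric(1))
  data.frame(id = isoforms$transcript_id, gene_id = isoforms$gene_id,
             reads = reads, length = e - s,
             rcb = rcb_formula(reads, e - s, T),
             stringsAsFactors = FALSE)
}

#' Keep robustly expressed genes (top expression fraction)
#'
#' Genes with positive abundance are ranked in descending order and the
#' top \code{top_fraction} retained.
#'
#' @param gene_tab a gene table with a \code{normalized_abundance} (or
#'   \code{rcb}) column.
#' @param top_fraction fraction to keep (default 0.75).
#' @param column abundance column name.
#' @return the retained subset.
#' @export
filter_by_expression_rank <- function(gene_tab, top_fraction = 0.75,
                                      column = "normalized_abundance") {
  a <- gene_tab[[column]]
  expressed <- gene_tab[a > 0, , drop = FALSE]
  if (nrow(expressed) == 0) return(expressed)
  ord <- order(-expressed[[column]])
  keep <- ord[seq_len(floor(top_fraction * nrow(expressed)))]
  out <- expressed[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
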