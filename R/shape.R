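#' Map an offset within an isoform to the canonical [0,1] coordinate
#'
#' Fixes the scale of the promoter-proximal and termination regions while
#' letting the gene body stretch: for isoforms longer than 6 kb the first
#' 3 kb maps proportionally onto [0, 0.2], the last 3 kb onto [0.8, 1], and
#' the remainder onto (0.2, 0.8). For isoforms of length l <= 6 kb the
#' first 0.75 l maps onto [0, 0.2] and the last 0.25 l onto [0.8, 1]; the
#' open interval (0.2, 0.8) is unused.
#'
#' @param offset_bp offset(s) from the TSS in the direction of
#'   transcription, 0-based; must satisfy \code{0 <= offset_bp < l}.
#' @param l isoform length in bp.
#' @return canonical coordinate(s) in [0, 1].
#' @export
map_to_canonical <- function(offset_bp, l) {
  if (any(offset_bp < 0 | offset_bp >= l))
    stop("offset out of range [0, l)")
  if (l > 6000) {
    u <- 0.2 + 0.6 * (offset_bp - 3000) / (l - 6000)
    head5 <- offset_bp < 3000
    tail3 <- offset_bp >= l - 3000
    u[head5] <- 0.2 * offset_bp[head5] / 3000
    u[tail3] <- 0.8 + 0.2 * (offset_bp[tail3] - (l - 3000)) / 3000
  } else {
    cut <- 0.75 * l
    u <- ifelse(offset_bp < cut,
                0.2 * offset_bp / cut,
                0.8 + 0.2 * (offset_bp - cut) / (l - cut))
  }
  u
}

#' Select reference isoforms for shape-profile fitting
#'
#' References must look like the sole source of signal in their region:
#' single-isoform clusters at least \code{min_length} bp long, at least
#' \code{isolation_bp} from the nearest cluster on either strand, and
#' robustly expressed (mean unmasked-bin density at or above
#' \code{min_mean_density}; by default the top expression quartile of the
#' surviving candidates).
#'
#' @param clusters list of collapsed clusters.
#' @param coverage a \code{coverage_track}.
#' @param min_length minimum isoform length in bp (default 10000).
#' @param min_mean_density reads/bp threshold; \code{NULL} means top
#'   quartile among candidates.
#' @param isolation_bp required distance to the nearest neighboring
#'   cluster (default 5000).
#' @return a data.frame of selected references (cluster index, model id,
#'   length, mean density).
#' @export
select_reference_isoforms <- function(clusters, coverage,
                                      min_length = 10000,
                                      min_mean_density = NULL,
                                      isolation_bp = 5000) {
  if (length(clusters) == 0) return(empty_reference_df())
  chrom <- vapply(clusters, `[[`, character(1), "chrom")
  starts <- vapply(clusters, `[[`, numeric(1), "start")
  ends <- vapply(clusters, `[[`, numeric(1), "end")
  cand <- list()
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    if (is.null(cl$models) || nrow(cl$models) != 1) next
    mod <- cl$models[1, ]
    if (mod$length < min_length) next
    same <- which(chrom == chrom[i])
    same <- setdiff(same, i)
    if (length(same) > 0) {
      gap <- pmax(starts[same] - ends[i], starts[i] - ends[same])
      if (min(gap) < isolation_bp) next
    }
    y <- cluster_bin_counts(cl, coverage)
    ub <- mod$ustart_bin:mod$uend_bin
    dens <- sum(y[ub]) / (length(ub) * cl$bin_size)
    cand[[length(cand) + 1L]] <- data.frame(
      cluster = i, model_id = mod$id, length = mod$length,
      mean_density = dens, stringsAsFactors = FALSE)
  }
  if (length(cand) == 0) return(empty_reference_df())
  cand <- do.call(rbind, cand)
  thr <- if (is.null(min_mean_density))
    stats::quantile(cand$mean_density, 0.75) else min_mean_density
  refs <- cand[cand$mean_density >= thr, , drop = FALSE]
  if (nrow(refs) < 20)
    warning("only ", nrow(refs), " reference isoform(s) for the shape ",
            "profile; the fit may be unstable")
  rownames(refs) <- NULL
  refs
}

empty_reference_df <- function() {
  data.frame(cluster = integer(0), model_id = character(0),
             length = numeric(0), mean_density = numeric(0),
             stringsAsFactors = FALSE)
}

#' A flat shape profile (density one everywhere)
#'
#' Quantifying with the flat profile is bit-identical to quantifying with
#' no shape correction.
#'
#' @param n_grid grid size on [0,1].
#' @return a \code{shape_profile}.
#' @export
flat_profile <- function(n_grid = 1000) {
  u <- seq(0, 1, length.out = n_grid)
  new_shape_profile(u, rep(1, n_grid), span = NA_real_, flat = TRUE)
}

new_shape_profile <- function(u, density, span, flat = FALSE) {
  stopifnot(all(density > 0))
  structure(list(u = u, density = density, span = span, flat = flat),
            class = "shape_profile")
}

#' @export
print.shape_profile <- function(x, ...) {
  cat(sprintf(
    "shape_profile: %d grid points, median %.3f, range [%.3f, %.3f]%s\n",
    length(x$u), stats::median(x$density), min(x$density), max(x$density),
    if (x$flat) " (flat)" else ""))
  invisible(x)
}

#' Evaluate a shape profile at canonical coordinates
#'
#' @param profile a \code{shape_profile}.
#' @param u coordinates in [0,1].
#' @return interpolated relative densities.
#' @export
profile_density <- function(profile, u) {
  stats::approx(profile$u, profile$density, xout = u, rule = 2)$y
}

#' Fit the canonical shape profile from reference isoforms
#'
#' Each reference's unmasked bin densities are normalized to the
#' reference's own mean, placed at the canonical coordinates of the bin
#' midpoints, pooled across references, and loess-smoothed. The smoothed
#' curve is rescaled so its median over a 1000-point grid on [0,1] equals
#' one; non-positive smoothed values are clipped to 0.05 with a warning.
#' With fewer than 5 references the fit is refused and a flat profile is
#' returned with a warning.
#'
#' @param clusters list of collapsed clusters.
#' @param coverage a \code{coverage_track}.
#' @param references a reference data.frame from
#'   \code{\link{select_reference_isoforms}}.
#' @param loess_span loess smoothing span (default 0.1).
#' @param n_grid evaluation grid size (default 1000).
#' @return a \code{shape_profile}.
#' @export
fit_profile <- function(clusters, coverage, references,
                        loess_span = 0.1, n_grid = 1000) {
  if (nrow(references) < 5) {
    warning("fewer than 5 reference isoforms; falling back to a flat ",
            "shape profile")
    return(flat_profile(n_grid))
  }
  pts_u <- list()
  pts_d <- list()
  for (r in seq_len(nrow(references))) {
    cl <- clusters[[references$cluster[r]]]
    mod <- cl$models[1, ]
    y <- cluster_bin_counts(cl, coverage)
    ub <- mod$ustart_bin:mod$uend_bin
    dens <- y[ub] / cl$bin_size
    mu <- mean(dens)
    if (mu <= 0) next
    # offset of each bin midpoint from the isoform 5' end, along
    # transcription; l taken as the isoform's bin-range extent
    rel <- ub - mod$start_bin
    off <- (rel + 0.5) * cl$bin_size
    l <- (mod$end_bin - mod$start_bin + 1) * cl$bin_size
    pts_u[[length(pts_u) + 1L]] <- map_to_canonical(off, l)
    pts_d[[length(pts_d) + 1L]] <- dens / mu
  }
  u <- unlist(pts_u)
  d <- unlist(pts_d)
  if (length(u) < 50) {
    warning("too few usable reference bins; falling back to a flat profile")
    return(flat_profile(n_grid))
  }
  fit <- stats::loess(d ~ u, span = loess_span, degree = 2,
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(0, 1, length.out = n_grid)
  dens <- stats::predict(fit, newdata = data.frame(u = grid))
  if (any(!is.finite(dens) | dens <= 0)) {
    warning("non-positive smoothed densities clipped to a floor of 0.05")
    dens[!is.finite(dens)] <- 0.05
    dens <- pmax(dens, 0.05)
  }
  dens <- dens / stats::median(dens)
  new_shape_profile(grid, dens, span = loess_span)
}

#' Apply the shape profile to a design matrix
#'
#' Every positive entry \eqn{x_{i,j}} is replaced by the profile's relative
#' density at the canonical coordinate of bin i's midpoint within isoform
#' j; masked or unspanned entries stay zero. With a flat profile the matrix
#' is returned unchanged.
#'
#' @param X design matrix from \code{\link{build_design_matrix}}.
#' @param profile a \code{shape_profile}.
#' @param cluster the collapsed cluster that produced \code{X}.
#' @return the adjusted design matrix.
#' @export
adjust_design_matrix <- function(X, profile, cluster) {
  if (isTRUE(profile$flat)) return(X)
  models <- cluster$models
  for (j in seq_len(ncol(X))) {
    rows <- which(X[, j] > 0)
    if (length(rows) == 0) next
    rel <- rows - models$start_bin[j]
    off <- (rel + 0.5) * cluster$bin_size
    l <- (models$end_bin[j] - models$start_bin[j] + 1) * cluster$bin_size
    X[rows, j] <- profile_density(profile, map_to_canonical(off, l))
  }
  X
}

#' Write / read a shape profile as two-column TSV
#'
#' @param profile a \code{shape_profile}.
#' @param path TSV path (columns \code{u}, \code{density}).
#' @export
write_profile <- function(profile, path) {
  utils::write.table(data.frame(u = profile$u, density = profile$density),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE)
  new_shape_profile(d$u, d$density, span = NA_real_,
                    flat = all(d$density == 1))
}
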