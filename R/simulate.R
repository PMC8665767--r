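#' Generate synthetic single-isoform read-count archetypes
#'
#' Each archetype is a transcription-unit read-count template with the
#' hallmark PRO-seq features: a promoter-proximal pause peak within the
#' first 500 bp, a U-shaped gene body (density rising toward both ends), a
#' 3' termination bump, and a divergent antisense peak just upstream of
#' the TSS. Per-base counts are drawn once with negative-binomial noise at
#' a fixed native abundance, so each archetype is a frozen, resampleable
#' read-count pattern. Deterministic given the seed.
#'
#' @param k number of archetypes (62 matches the curated set size the
#'   simulator is modeled on; 145 is the expanded robustness scale).
#' @param length_range min/max archetype length in bp.
#' @param seed RNG seed.
#' @param native_abundance the abundance (TPM-like units) at which the
#'   archetype counts were drawn.
#' @param depth_per_abundance expected per-base read count per abundance
#'   unit at shape density 1.
#' @param nb_size negative-binomial size (dispersion) for per-base noise.
#' @param antisense_width width of the upstream antisense window in bp.
#' @return list of archetypes, each with \code{length}, \code{sense}
#'   (per-base counts, 5' to 3'), \code{antisense} (per-base counts over
#'   the \code{antisense_width} bp immediately upstream of the TSS, in
#'   genomic-away-from-TSS order ending at offset -1), and
#'   \code{native_abundance}.
#' @export
generate_archetypes <- function(k, length_range = c(2000, 30000),
                                seed = 1L, native_abundance = 100,
                                depth_per_abundance = 0.02,
                                nb_size = 5, antisense_width = 1000) {
  stopifnot(k >= 1)
  set.seed(seed)
  lens <- round(exp(seq(log(length_range[1]), log(length_range[2]),
                        length.out = k)) *
                  exp(stats::runif(k, -0.08, 0.08)))
  lens <- pmax(lens, 1000)
  lapply(seq_len(k), function(i) {
    L <- lens[i]
    b <- seq_len(L)
    u <- (b - 0.5) / L
    body <- 0.75 + 0.9 * (2 * u - 1)^2
    pause <- 12 * exp(-(b - 125)^2 / (2 * 60^2))
    term <- 3 * exp(-(b - (L - 400))^2 / (2 * 200^2))
    s <- body + pause + term
    # abundance unit = gene-body polymerase density: scale so the body
    # interior (past the pause, before the termination bump) has mean 1
    interior <- max(min(500, L %/% 4), 1):max(L - 1000, L %/% 2)
    s <- s / mean(s[interior])
    mu <- depth_per_abundance * native_abundance * s
    sense <- stats::rnbinom(L, size = nb_size, mu = mu)
    d <- seq(-antisense_width, -1)
    mu_a <- 0.35 * max(mu) * exp(-(d + 125)^2 / (2 * 80^2))
    antisense <- stats::rnbinom(antisense_width, size = nb_size,
                                mu = mu_a)
    list(id = sprintf("A%03d", i), length = L, sense = sense,
         antisense = antisense, native_abundance = native_abundance,
         depth_per_abundance = depth_per_abundance)
  })
}

#' Synthetic template isoform annotations
#'
#' A deterministic, realistic template gene set for the simulator: genes
#' of 1-6 mature isoforms with nested and staggered TSS/PAS
#' configurations on both strands; about 30 percent of multi-isoform genes
#' carry an isoform whose TSS lies at least 1 kb downstream of the
#' 5'-most TSS, so that (with iid abundance draws) roughly 15 percent of
#' genes end up dominated by an internal-TSS isoform.
#'
#' @param n_genes number of template genes.
#' @param seed RNG seed.
#' @return a \code{mature_isoforms} data.frame.
#' @export
synthetic_template_annotations <- function(n_genes = 60, seed = 20260926) {
  set.seed(seed)
  rows <- list()
  cursor <- 10000
  for (g in seq_len(n_genes)) {
    strand <- sample(c("+", "-"), 1)
    k <- sample(1:6, 1, prob = c(0.30, 0.25, 0.18, 0.12, 0.09, 0.06))
    L <- round(exp(stats::rnorm(1, log(12000), 0.6)))
    L <- min(max(L, 3000), 45000)
    alt_tss <- k >= 2 && L >= 6000 && stats::runif(1) < 0.60
    # offsets are in transcription direction from the gene 5' end
    tss_off <- numeric(k)
    pas_off <- rep(L, k)                      # 3' end offset (exclusive)
    if (k >= 2) {
      # alternative promoters and PASs are discrete: isoforms either
      # share a boundary (sub-bin annotation jitter, collapsed later) or
      # differ by at least ~1 kb
      for (j in 2:k) {
        if (alt_tss && j == 2) {
          tss_off[j] <- round(stats::runif(1, 1200, 0.6 * L))
        } else if (stats::runif(1) < 0.55 && L >= 7000) {
          tss_off[j] <- round(stats::runif(1, 0, 200))
          pas_off[j] <- L - round(stats::runif(1, 2000, 0.5 * L))
        } else {
          tss_off[j] <- round(stats::runif(1, 0, 200))
          pas_off[j] <- L - round(stats::runif(1, 0, 300))
        }
        if (pas_off[j] - tss_off[j] < 1500)
          pas_off[j] <- min(L, tss_off[j] + 1500)
      }
    }
    gene_id <- sprintf("TG%04d", g)
    for (j in seq_len(k)) {
      if (strand == "+") {
        s <- cursor + tss_off[j]
        e <- cursor + pas_off[j]
      } else {
        e <- cursor + L - tss_off[j]
        s <- cursor + L - pas_off[j]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = sprintf("%s.t%d", gene_id, j),
        gene_id = gene_id, chrom = "tmpl1", start = s, end = e,
        strand = strand, stringsAsFactors = FALSE)
    }
    gap <- round(exp(stats::rnorm(1, log(9000), 0.5)))
    cursor <- cursor + L + min(max(gap, 4000), 40000)
  }
  mature_isoforms(do.call(rbind, rows))
}

#' Simulate a nascent RNA-sequencing dataset with known truth
#'
#' The five-step archetype-resampling scheme: (1) template annotations are
#' grouped into strand-specific non-overlapping clusters; (2) clusters and
#' inter-cluster distances are resampled with replacement until
#' \code{n_genes} genes are placed; (3) each isoform is replaced by the
#' archetype nearest to it in genomic length, keeping its TSS at the
#' original offset from the cluster start; (4) a true abundance is drawn
#' for every isoform from a log-normal distribution; (5) per-base counts
#' are drawn as Poisson resamples of the archetype counts scaled by
#' (true abundance / archetype native abundance), with overlapping
#' isoforms' counts added, plus the archetype's divergent antisense signal
#' on the opposite strand.
#'
#' @param archetypes from \code{\link{generate_archetypes}}.
#' @param n_genes number of genes to place (default 1500).
#' @param templates template annotations (default
#'   \code{\link{synthetic_template_annotations}}).
#' @param seed RNG seed; the full simulate-export path is deterministic
#'   given it.
#' @param abundance_meanlog,abundance_sdlog log-normal abundance
#'   parameters (defaults 4 and 1.2, TPM-like scale).
#' @param chrom_size_limit start a new synthetic chromosome past this
#'   coordinate.
#' @param keep_contributions also return each isoform's per-base count
#'   contribution (memory-heavy; for conservation checks on small runs).
#' @return a \code{sim_dataset}: \code{isoforms} (a
#'   \code{mature_isoforms} table of the placed isoforms), \code{truth}
#'   (per-isoform true abundance, archetype, realized and expected total
#'   counts), \code{coverage} (a \code{coverage_track}), and
#'   \code{params}.
#' @export
simulate_dataset <- function(archetypes, n_genes = 1500,
                             templates = synthetic_template_annotations(),
                             seed = 1L, abundance_meanlog = 4,
                             abundance_sdlog = 1.2,
                             chrom_size_limit = 12e6,
                             keep_contributions = FALSE) {
  set.seed(seed)
  tmpl_clusters <- cluster_isoforms(templates)
  stopifnot(length(tmpl_clusters) > 0)
  gaps <- template_gaps(tmpl_clusters)
  arch_lens <- vapply(archetypes, `[[`, numeric(1), "length")
  aw <- length(archetypes[[1]]$antisense)

  # --- layout pass: resample clusters and gaps until n_genes placed ----
  placements <- list()
  gene_total <- 0L
  gene_n <- 0L
  tx_n <- 0L
  chrom_i <- 1L
  cursor <- 5000
  while (gene_total < n_genes) {
    cl <- tmpl_clusters[[sample.int(length(tmpl_clusters), 1)]]
    gap <- sample(gaps, 1)
    origin <- cursor + gap
    iso <- cl$isoforms
    arch_idx <- vapply(iso$length, function(l)
      which.min(abs(arch_lens - l)), integer(1))
    far <- abs(arch_lens[arch_idx] - iso$length) > iso$length
    if (any(far))
      warning("no archetype within 2x length of ", sum(far),
              " isoform(s); using nearest anyway")
    tss_off <- iso$tss - cl$start
    new_tss <- origin + tss_off
    s <- ifelse(iso$strand == "+", new_tss,
                new_tss + 1L - arch_lens[arch_idx])
    e <- s + arch_lens[arch_idx]
    shift <- origin - min(s)       # keep the placed cluster at origin
    s <- s + shift; e <- e + shift; new_tss <- new_tss + shift
    gmap <- match(iso$gene_id, unique(iso$gene_id))
    placements[[length(placements) + 1L]] <- data.frame(
      transcript_id = sprintf("ST%06d", tx_n + seq_len(nrow(iso))),
      gene_id = sprintf("SG%05d", gene_n + gmap),
      chrom = sprintf("sim%d", chrom_i),
      start = s, end = e, strand = iso$strand,
      archetype = arch_idx, stringsAsFactors = FALSE)
    tx_n <- tx_n + nrow(iso)
    gene_n <- gene_n + max(gmap)
    gene_total <- gene_total + max(gmap)
    cursor <- max(e)
    if (cursor > chrom_size_limit) {
      chrom_i <- chrom_i + 1L
      cursor <- 5000
    }
  }
  placed <- do.call(rbind, placements)
  placed$true_abundance <- stats::rlnorm(nrow(placed),
                                         abundance_meanlog,
                                         abundance_sdlog)

  # --- count pass: Poisson-resample archetype counts per isoform ------
  plus <- list(); minus <- list()
  contribs <- if (keep_contributions) vector("list", nrow(placed))
  placed$total_counts <- NA_real_
  placed$expected_counts <- NA_real_
  for (ch in unique(placed$chrom)) {
    rows_i <- which(placed$chrom == ch)
    clen <- max(placed$end[rows_i]) + aw + 2000
    pv <- numeric(clen); mv <- numeric(clen)
    for (i in rows_i) {
      a <- archetypes[[placed$archetype[i]]]
      scale <- placed$true_abundance[i] / a$native_abundance
      sense <- stats::rpois(a$length, a$sense * scale)
      anti <- stats::rpois(aw, a$antisense * scale)
      s0 <- placed$start[i]
      if (placed$strand[i] == "+") {
        idx <- (s0 + 1):(s0 + a$length)
        pv[idx] <- pv[idx] + sense
        ai <- (s0 - aw + 1):s0
        ok <- ai >= 1
        mv[ai[ok]] <- mv[ai[ok]] + anti[ok]
      } else {
        idx <- (s0 + 1):(s0 + a$length)
        mv[idx] <- mv[idx] + rev(sense)
        tss <- placed$end[i]            # 0-based tss is end-1; antisense
        ai <- (tss + 1):(tss + aw)      # occupies [tss+1, tss+aw] 1-based
        ok <- ai <= clen
        pv[ai[ok]] <- pv[ai[ok]] + rev(anti)[ok]
      }
      placed$total_counts[i] <- sum(sense)
      placed$expected_counts[i] <- scale * sum(a$sense)
      if (keep_contributions)
        contribs[[i]] <- list(chrom = ch, strand = placed$strand[i],
                              start = s0, sense = sense, anti = anti)
    }
    plus[[ch]] <- S4Vectors::Rle(pv)
    minus[[ch]] <- S4Vectors::Rle(mv)
  }
  iso_tab <- mature_isoforms(placed[, c("transcript_id", "gene_id",
                                        "chrom", "start", "end",
                                        "strand")])
  truth <- placed[, c("transcript_id", "gene_id", "chrom", "start",
                      "end", "strand", "archetype", "true_abundance",
                      "total_counts", "expected_counts")]
  structure(list(
    isoforms = iso_tab, truth = truth,
    coverage = coverage_track(plus, minus),
    contributions = if (keep_contributions) contribs,
    params = list(seed = seed, n_genes = gene_total,
                  abundance_meanlog = abundance_meanlog,
                  abundance_sdlog = abundance_sdlog,
                  depth_per_abundance =
                    archetypes[[1]]$depth_per_abundance,
                  n_archetypes = length(archetypes))),
    class = "sim_dataset")
}

template_gaps <- function(clusters) {
  gaps <- numeric(0)
  chrom <- vapply(clusters, `[[`, character(1), "chrom")
  for (ch in unique(chrom)) {
    cc <- clusters[chrom == ch]
    if (length(cc) < 2) next
    s <- vapply(cc, `[[`, numeric(1), "start")
    e <- vapply(cc, `[[`, numeric(1), "end")
    ord <- order(s)
    g <- s[ord][-1] - e[ord][-length(e)]
    gaps <- c(gaps, g[g > 0])
  }
  if (length(gaps) == 0) gaps <- c(5000, 8000, 12000, 20000)
  gaps
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(paste0("sim_dataset: %d isoforms in %d genes, library ",
                     "depth %.3g (seed %d)\n"),
              nrow(x$isoforms), length(unique(x$isoforms$gene_id)),
              x$coverage$library_depth, x$params$seed))
  invisible(x)
}

#' Export a simulated dataset to standard files
#'
#' Writes the strand-specific coverage as a bedGraph pair (minus strand
#' negated, PRO-seq convention), the placed isoforms as an Ensembl-style
#' GTF and the truth table as TSV, so the files round-trip through the
#' package's own readers.
#'
#' @param dataset a \code{sim_dataset}.
#' @param dir output directory (created if needed).
#' @return named character vector of the four paths.
#' @export
export_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(plus = file.path(dir, "coverage_plus.bedGraph"),
             minus = file.path(dir, "coverage_minus.bedGraph"),
             gtf = file.path(dir, "annotations.gtf"),
             truth = file.path(dir, "truth.tsv"))
  write_coverage(dataset$coverage, paths["plus"], paths["minus"])
  write_annotations_gtf(dataset$isoforms, paths["gtf"])
  tt <- dataset$truth
  tt$true_abundance <- sprintf("%.6f", tt$true_abundance)
  tt$expected_counts <- sprintf("%.6f", tt$expected_counts)
  utils::write.table(tt, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
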