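test_that("archetypes are deterministic and carry the stated features", {
  a1 <- generate_archetypes(5, seed = 12)
  a2 <- generate_archetypes(5, seed = 12)
  expect_identical(a1, a2)
  expect_length(generate_archetypes(62, seed = 1), 62)
  expect_length(generate_archetypes(145, seed = 1), 145)
  a <- a1[[3]]
  L <- a$length
  expect_true(all(a$sense >= 0))
  expect_length(a$sense, L)
  # pause peak: the first 500 bp are much denser than the mid body
  expect_gt(mean(a$sense[1:500]), 3 * mean(a$sense[(L / 2):(L / 2 + 500)]))
  # U-shaped body: both ends denser than the middle
  body <- a$sense[500:(L - 1000)]
  nb <- length(body)
  expect_gt(mean(body[1:(nb / 5)]), mean(body[(2 * nb / 5):(3 * nb / 5)]))
  expect_gt(mean(body[(4 * nb / 5):nb]),
            mean(body[(2 * nb / 5):(3 * nb / 5)]))
  # antisense peak is present just upstream of the TSS
  expect_gt(sum(a$antisense[800:1000]), sum(a$antisense[1:200]))
})

test_that("isoforms adopt the archetype nearest in length", {
  arch <- generate_archetypes(10, length_range = c(5000, 20000),
                              seed = 2)
  lens <- vapply(arch, `[[`, numeric(1), "length")
  tmpl <- synthetic_template_annotations(10, seed = 3)
  ds <- simulate_dataset(arch, n_genes = 12, templates = tmpl, seed = 4)
  for (i in seq_len(nrow(ds$truth))) {
    l_new <- ds$truth$end[i] - ds$truth$start[i]
    expect_equal(l_new, lens[ds$truth$archetype[i]])
  }
})

test_that("simulation is deterministic and counts are conserved", {
  arch <- generate_archetypes(8, length_range = c(2000, 12000), seed = 5)
  tmpl <- synthetic_template_annotations(12, seed = 6)
  ds1 <- simulate_dataset(arch, n_genes = 15, templates = tmpl, seed = 7,
                          keep_contributions = TRUE)
  ds2 <- simulate_dataset(arch, n_genes = 15, templates = tmpl, seed = 7)
  expect_identical(ds1$truth, ds2$truth)
  expect_equal(ds1$coverage$library_depth, ds2$coverage$library_depth)
  # per-base coverage equals the sum of per-isoform contributions
  for (ch in unique(ds1$isoforms$chrom)) {
    L <- length(ds1$coverage$plus[[ch]])
    pv <- numeric(L); mv <- numeric(L)
    for (co in ds1$contributions) {
      if (co$chrom != ch) next
      n <- length(co$sense); aw <- length(co$anti)
      if (co$strand == "+") {
        pv[(co$start + 1):(co$start + n)] <-
          pv[(co$start + 1):(co$start + n)] + co$sense
        ai <- (co$start - aw + 1):co$start
        ok <- ai >= 1
        mv[ai[ok]] <- mv[ai[ok]] + co$anti[ok]
      } else {
        mv[(co$start + 1):(co$start + n)] <-
          mv[(co$start + 1):(co$start + n)] + rev(co$sense)
        ai <- (co$start + n + 1):(co$start + n + aw)
        ok <- ai <= L
        pv[ai[ok]] <- pv[ai[ok]] + rev(co$anti)[ok]
      }
    }
    expect_equal(as.numeric(ds1$coverage$plus[[ch]]), pv)
    expect_equal(as.numeric(ds1$coverage$minus[[ch]]), mv)
  }
})

test_that("doubling abundance doubles expected isoform read counts", {
  arch <- generate_archetypes(1, length_range = c(5000, 5000), seed = 9)
  a <- arch[[1]]
  set.seed(10)
  alpha <- 40
  reps <- 100
  tot1 <- replicate(reps, sum(rpois(a$length,
                                    a$sense * alpha / a$native_abundance)))
  tot2 <- replicate(reps, sum(rpois(a$length,
                                    a$sense * 2 * alpha /
                                      a$native_abundance)))
  se <- sqrt(var(tot2) / reps + 4 * var(tot1) / reps)
  expect_lt(abs(mean(tot2) - 2 * mean(tot1)), 3 * se)
})

test_that("mean total counts are proportional to true abundance", {
  ds <- small_sim()
  arch_big <- generate_archetypes(15, length_range = c(2000, 25000),
                                  seed = 41)
  tmpl <- synthetic_template_annotations(30, seed = 42)
  big <- simulate_dataset(arch_big, n_genes = 220, templates = tmpl,
                          seed = 44)
  expect_gte(nrow(big$truth), 500)
  slope <- coef(lm(total_counts ~ 0 + expected_counts,
                   data = big$truth))
  expect_lt(abs(slope - 1), 0.05)
})

test_that("export round-trips through the package readers", {
  ds <- small_sim()
  dir <- tempfile("simexp")
  paths <- export_dataset(ds, dir)
  iso <- read_annotations(paths[["gtf"]], "GTF")
  expect_equal(nrow(iso), nrow(ds$isoforms))
  m <- match(ds$isoforms$transcript_id, iso$transcript_id)
  expect_equal(iso$start[m], ds$isoforms$start)
  expect_equal(iso$end[m], ds$isoforms$end)
  expect_equal(iso$strand[m], ds$isoforms$strand)
  cov <- read_coverage(paths[["plus"]], paths[["minus"]])
  expect_equal(cov$library_depth, ds$coverage$library_depth)
  ch <- ds$isoforms$chrom[1]
  w <- c(ds$isoforms$start[1], ds$isoforms$end[1])
  expect_equal(
    coverage_window_sums(cov, ch, "+", w[1], w[2]),
    coverage_window_sums(ds$coverage, ch, "+", w[1], w[2]))
  # truth table rows match simulated isoforms; fixed seed reproduces
  # the file byte-for-byte
  truth <- read.table(paths[["truth"]], header = TRUE, sep = "\t")
  expect_equal(nrow(truth), nrow(ds$isoforms))
  dir2 <- tempfile("simexp2")
  arch <- generate_archetypes(15, length_range = c(2000, 25000),
                              seed = 41)
  tmpl <- synthetic_template_annotations(30, seed = 42)
  ds_again <- simulate_dataset(arch, n_genes = 60, templates = tmpl,
                               seed = 43)
  paths2 <- export_dataset(ds_again, dir2)
  expect_identical(readLines(paths2[["truth"]]),
                   readLines(paths[["truth"]]))
})

test_that("quantifying exported data closes the loop", {
  ds <- small_sim()
  dir <- tempfile("loop")
  paths <- export_dataset(ds, dir)
  iso <- read_annotations(paths[["gtf"]], "GTF")
  cov <- read_coverage(paths[["plus"]], paths[["minus"]])
  tab <- quantify(iso, cov, shape = FALSE, log_space = FALSE)
  tab <- model_truth(tab, ds$truth)
  expect_gt(cor(tab$raw_beta, tab$true_abundance), 0.6)
})
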