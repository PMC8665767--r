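test_that("clustering is the transitive closure of same-strand overlap", {
  iso <- iso_df(list("a1", "gA", "chr1", 0, 1000, "+"),
                list("b1", "gB", "chr1", 900, 2000, "+"),
                list("c1", "gC", "chr1", 2000, 3000, "+"),
                list("d1", "gD", "chr1", 500, 1500, "-"))
  cl <- cluster_isoforms(iso)
  expect_length(cl, 3)
  members <- lapply(cl, function(x) sort(x$isoforms$transcript_id))
  # overlapping same-strand genes share a cluster; opposite strand and
  # adjacent-but-disjoint spans do not
  expect_true(any(vapply(members, identical, logical(1), c("a1", "b1"))))
  expect_true(any(vapply(members, identical, logical(1), "c1")))
  expect_true(any(vapply(members, identical, logical(1), "d1")))
  # partition: every isoform in exactly one cluster
  expect_setequal(unlist(members), iso$transcript_id)
  expect_length(cluster_isoforms(iso[0, ]), 0)
})

test_that("binning assigns isoform bin ranges and masks", {
  iso <- iso_df(list("t1", "g1", "chr1", 0, 2500, "+"))
  cl <- bin_and_mask(cluster_isoforms(iso)[[1]], bin_size = 250,
                     mask5_bins = 1, mask3_bins = 4)
  # spans bins 1-10; masks (1,4) leave bins 2-6 usable
  expect_equal(cl$m, 10L)
  expect_equal(cl$isoforms$start_bin, 1L)
  expect_equal(cl$isoforms$end_bin, 10L)
  expect_equal(cl$isoforms$ustart_bin, 2L)
  expect_equal(cl$isoforms$uend_bin, 6L)
  # no masks: all 10 bins usable
  cl0 <- bin_and_mask(cluster_isoforms(iso)[[1]], 250, 0, 0)
  expect_equal(cl0$isoforms$ustart_bin, 1L)
  expect_equal(cl0$isoforms$uend_bin, 10L)
  # halving the bin size doubles the grid
  cl125 <- bin_and_mask(cluster_isoforms(iso)[[1]], 125, 0, 0)
  expect_equal(cl125$m, 20L)
  expect_equal(cl125$isoforms$end_bin, 20L)
})

test_that("minus-strand bins run 5' to 3' in transcription direction", {
  iso <- iso_df(list("t1", "g1", "chr1", 1000, 3500, "-"))
  cl <- bin_and_mask(cluster_isoforms(iso)[[1]], 250, 0, 0)
  # TSS at 3499 is bin 1; PAS at 1000 is bin 10
  expect_equal(cl$isoforms$start_bin, 1L)
  expect_equal(cl$isoforms$end_bin, 10L)
  v <- numeric(4000); v[1001:3500] <- 1; v[3251:3500] <- 9  # 5' bin hot
  tr <- track_from(plus = numeric(4000), minus = v)
  y <- cluster_bin_counts(cl, tr)
  expect_equal(y[1], 9 * 250)
  expect_equal(y[10], 250)
})

test_that("fully masked short isoforms keep one central bin", {
  iso <- iso_df(list("t1", "g1", "chr1", 0, 1000, "+"))
  expect_warning(cl <- bin_and_mask(cluster_isoforms(iso)[[1]],
                                    250, 1, 4), "masked")
  expect_equal(cl$isoforms$ustart_bin, cl$isoforms$uend_bin)
  expect_true(cl$isoforms$ustart_bin %in% 1:4)
})

test_that("collapsing merges same-bin isoforms and is idempotent", {
  iso <- iso_df(list("t1", "g1", "chr1", 0, 5000, "+"),
                list("t2", "g1", "chr1", 40, 5000, "+"),   # same TSS bin
                list("t3", "g1", "chr1", 400, 5000, "+"))  # 400 bp apart
  cl <- collapse_isoforms(bin_and_mask(cluster_isoforms(iso)[[1]],
                                       250, 0, 0))
  expect_equal(nrow(cl$models), 2)
  merged <- cl$models[cl$models$n_members == 2, ]
  expect_equal(merged$member_transcript_ids, "t1,t2")
  # idempotent and order-independent
  cl2 <- collapse_isoforms(cl)
  expect_equal(cl2$models$member_transcript_ids,
               cl$models$member_transcript_ids)
  iso_rev <- iso[rev(seq_len(nrow(iso))), ]
  cl3 <- collapse_isoforms(bin_and_mask(cluster_isoforms(iso_rev)[[1]],
                                        250, 0, 0))
  expect_setequal(cl3$models$member_transcript_ids,
                  cl$models$member_transcript_ids)
})

test_that("same-span isoforms of different genes are not merged", {
  iso <- iso_df(list("t1", "g1", "chr1", 0, 5000, "+"),
                list("t2", "g2", "chr1", 0, 5000, "+"))
  cl <- collapse_isoforms(bin_and_mask(cluster_isoforms(iso)[[1]],
                                       250, 0, 0))
  expect_equal(nrow(cl$models), 2)
  expect_setequal(cl$models$gene_id, c("g1", "g2"))
})

test_that("design matrix columns follow unmasked spans", {
  iso <- iso_df(list("long", "g1", "chr1", 0, 2500, "+"),
                list("short", "g1", "chr1", 0, 1250, "+"))
  cl <- collapse_isoforms(bin_and_mask(cluster_isoforms(iso)[[1]],
                                       250, 0, 0))
  X <- build_design_matrix(cl)
  expect_equal(dim(X), c(10L, 2L))
  long_col <- X[, which(cl$models$end_bin == 10)]
  short_col <- X[, which(cl$models$end_bin == 5)]
  expect_equal(unname(long_col), rep(1, 10))
  expect_equal(unname(short_col), c(rep(1, 5), rep(0, 5)))
  # masked bins are zero even though spanned (the 5-bin isoform is
  # fully masked by (1,4) and keeps its central bin, with a warning)
  expect_warning(
    clm <- collapse_isoforms(bin_and_mask(cluster_isoforms(iso)[[1]],
                                          250, 1, 4)),
    "masked")
  Xm <- build_design_matrix(clm)
  expect_equal(unname(Xm[1, ]), c(0, 0))
  # row count = ceil(span / bin_size)
  expect_equal(nrow(Xm), as.integer(ceiling(2500 / 250)))
})

test_that("TSS grouping is single-linkage with longest representative", {
  brute_single_linkage <- function(tss, d) {
    # oracle: grow groups by exhaustive pairwise linkage
    n <- length(tss)
    grp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (grp[i] != grp[j] && abs(tss[i] - tss[j]) < d) {
          grp[grp == grp[j]] <- grp[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    match(grp, unique(grp))
  }
  iso <- iso_df(list("t1", "g1", "chr1", 0, 9000, "+"),
                list("t2", "g1", "chr1", 800, 10000, "+"),
                list("t3", "g1", "chr1", 1600, 4000, "+"))
  reps <- group_tss_within(iso, 1000)
  oracle <- brute_single_linkage(iso$tss, 1000)
  expect_equal(length(unique(oracle)), 1)  # chained: one group
  expect_equal(nrow(reps), 1)
  expect_equal(reps$transcript_id, "t2")   # longest member kept
  # 0 and 1200: two groups
  iso2 <- iso_df(list("t1", "g1", "chr1", 0, 5000, "+"),
                 list("t2", "g1", "chr1", 1200, 5000, "+"))
  expect_equal(nrow(group_tss_within(iso2, 1000)), 2)
  # singleton returns itself
  expect_equal(group_tss_within(iso2[1, ], 1000)$transcript_id, "t1")
  # property: representative count matches the brute-force oracle
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    tss <- sort(sample(0:20000, n))
    isoP <- mature_isoforms(data.frame(
      transcript_id = paste0("t", seq_len(n)), gene_id = "g",
      chrom = "chr1", start = tss, end = tss + sample(1000:9000, n),
      strand = "+"))
    expect_equal(nrow(group_tss_within(isoP, 1000)),
                 length(unique(brute_single_linkage(isoP$tss, 1000))))
  }
})

test_that("internal-TSS classification is strand-aware and inclusive", {
  iso <- iso_df(list("t1", "g1", "chr1", 0, 80000, "+"),
                list("t2", "g1", "chr1", 60000, 80000, "+"))
  expect_equal(classify_internal_tss(iso, 60000), "internal")
  expect_equal(classify_internal_tss(iso, 0), "five_prime")
  expect_equal(classify_internal_tss(iso, 1000), "internal")  # boundary
  expect_equal(classify_internal_tss(iso, 999), "five_prime")
  neg <- iso_df(list("t1", "g1", "chr1", 0, 80000, "-"),
                list("t2", "g1", "chr1", 0, 20000, "-"))
  expect_equal(classify_internal_tss(neg, 19999), "internal")
  expect_equal(classify_internal_tss(neg, 79999), "five_prime")
})
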