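# Coverage with a bidirectional peak at a chosen position.
bidir_track <- function(center, len = 20000, amp = 30) {
  p <- numeric(len); m <- numeric(len)
  idx <- seq_len(len)
  p <- amp * exp(-(idx - (center + 150))^2 / (2 * 60^2))
  m <- amp * exp(-(idx - (center - 150))^2 / (2 * 60^2))
  track_from(p, m)
}

test_that("feature windows span 21 x 51 bp and z-score to zero mean", {
  tr <- bidir_track(5000)
  f <- extract_features(5000, "chr1", "+", tr)
  expect_length(f, 42)
  expect_equal(mean(f), 0, tolerance = 1e-12)
  expect_equal(sd(f), 1, tolerance = 1e-12)
  # all-zero window yields the all-zero vector (sd = 0 rule)
  f0 <- extract_features(15000, "chr1", "+", tr)
  expect_equal(f0, numeric(42))
  # a symmetric bidirectional peak mirrors between sense and antisense
  # (up to the one-base asymmetry of the centered window)
  expect_equal(f[1:21], rev(f[22:42]), tolerance = 0.05)
})

test_that("feature extraction is translation-equivariant", {
  tr1 <- bidir_track(4000)
  tr2 <- bidir_track(9000)
  expect_equal(extract_features(4000, "chr1", "+", tr1),
               extract_features(9000, "chr1", "+", tr2),
               tolerance = 1e-10)
  # minus-strand features of the mirrored configuration match
  f_minus <- extract_features(4000, "chr1", "-", tr1)
  expect_length(f_minus, 42)
  expect_gt(max(f_minus), 1)
})

test_that("UPR follows the density windows and boundary rules", {
  len <- 20000
  v <- numeric(len)
  tss <- 10000
  v[(tss + 500 + 1):(tss + 2000)] <- 10   # inside density 10/bp
  v[(tss - 3000 + 1):(tss - 500)] <- 2    # upstream density 2/bp
  u <- compute_upr(tss, "chr1", "+", track_from(v))
  expect_equal(u$inside_density, 10)
  expect_equal(u$upstream_density, 2)
  expect_equal(u$ratio, 5)
  # inside zero -> ratio 0; upstream zero with signal -> +Inf
  u0 <- compute_upr(tss, "chr1", "+", track_from(numeric(len)))
  expect_equal(u0$ratio, 0)
  v2 <- numeric(len); v2[(tss + 501):(tss + 2000)] <- 1
  expect_equal(compute_upr(tss, "chr1", "+", track_from(v2))$ratio, Inf)
  # minus strand: windows flip in genomic space
  vm <- numeric(len)
  vm[(tss - 2000 + 1):(tss - 500)] <- 4
  um <- compute_upr(tss, "chr1", "-", track_from(numeric(len), vm))
  expect_equal(um$inside_density, 4)
})

test_that("training-set labels follow the peak and proximity rules", {
  cand <- data.frame(
    chrom = "chr1",
    tss = c(1000, 1030, 5000, 5090, 9000, 12000),
    strand = "+", stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "chr1", start = 950, end = 1100)
  cap <- data.frame(chrom = "chr1", pos = c(1000, 1010, 1030, 9020))
  set <- build_training_set(cand, peaks, cap)
  # two candidates in one peak: only the stronger-signal one is positive
  expect_equal(set$tss[set$label], 1000)
  # 5090 is within 100 bp of no active TSS and >25 bp from reads -> kept;
  # 9000 is within 25 bp of a cap read -> dropped
  expect_true(5090 %in% set$tss[!set$label])
  expect_false(9000 %in% set$tss)
  expect_true(12000 %in% set$tss[!set$label])
  # candidate 90 bp from an active TSS with no peak overlap is dropped
  cand2 <- rbind(cand, data.frame(chrom = "chr1", tss = 1090,
                                  strand = "+"))
  set2 <- build_training_set(cand2, peaks, cap)
  expect_false(1090 %in% set2$tss)
  expect_error(build_training_set(cand[5:6, ], peaks, cap),
               "positive")
})

test_that("classifiers learn synthetic bidirectional TSSs", {
  ds <- small_sim()
  tr <- sim_tss_training_set(ds, n_negative_per_positive = 1, seed = 8)
  n <- nrow(tr$features)
  set.seed(80)
  holdout <- sample(n, round(0.3 * n))
  fitme <- setdiff(seq_len(n), holdout)
  model <- train_tss_classifier(tr$features[fitme, ], tr$labels[fitme],
                                "logistic")
  acc <- mean((predict_tss(model, tr$features[holdout, ]) >= 0.5) ==
                tr$labels[holdout])
  expect_gte(acc, 0.9)
  # the convolutional backend clears the same bar
  conv <- train_tss_classifier(tr$features[fitme, ], tr$labels[fitme],
                               "conv", seed = 2, epochs = 60)
  acc_conv <- mean((predict_tss(conv, tr$features[holdout, ]) >= 0.5) ==
                     tr$labels[holdout])
  expect_gte(acc_conv, 0.9)
  # all-zero features bypass the model as inactive; threshold inclusive
  expect_false(classify_tss(numeric(42), model)$active)
  expect_error(predict_tss(structure(list(method = "logistic",
                                          fit = NULL),
                                     class = "tss_model"),
                           tr$features),
               "train")
})

test_that("UPR rescue respects thresholds and isolation", {
  len <- 40000
  v <- numeric(len)
  tss <- 20000
  v[(tss + 501):(tss + 2000)] <- 8   # UPR = 8 / 0 upstream -> Inf
  tr <- track_from(v)
  base <- data.frame(cluster = 1L, model_id = c("a", "b"),
                     chrom = "chr1", strand = "+",
                     tss = c(tss, tss - 7000),
                     probability = c(0.1, 0.9),
                     active = c(FALSE, TRUE), rescued = FALSE,
                     stringsAsFactors = FALSE)
  out <- rescue_isoforms(base, tr)
  expect_true(out$active[1])
  expect_true(out$rescued[1])
  expect_true(out$active[2])      # rescue never removes a call
  # an active TSS 3 kb upstream blocks the rescue
  blocked <- base; blocked$tss[2] <- tss - 3000
  expect_false(rescue_isoforms(blocked, tr)$rescued[1])
  # UPR below 5 is ineligible, boundary 5 is eligible
  v5 <- numeric(len)
  v5[(tss + 501):(tss + 2000)] <- 4.9
  v5[(tss - 2999):(tss - 500)] <- 1
  low <- base[1, ]
  expect_false(rescue_isoforms(low, track_from(v5))$rescued[1])
  v5[(tss + 501):(tss + 2000)] <- 5
  expect_true(rescue_isoforms(low, track_from(v5))$rescued[1])
})

test_that("design-matrix filtering removes disallowed isoform columns", {
  X <- matrix(1, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  Xf <- filter_design_matrix(X, c("b"))
  expect_equal(colnames(Xf), "b")
  expect_warning(X0 <- filter_design_matrix(X, character(0)), "zeros")
  expect_equal(ncol(X0), 0)
  expect_identical(filter_design_matrix(X, c("a", "b", "c")), X)
})
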