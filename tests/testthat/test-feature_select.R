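test_that("RFECV recovers planted signal features", {
  tb <- planted_table(n_per_class = 40, n_signal = 3, n_noise = 17, delta = 2,
                      seed = 2)
  sel <- rfecv_select(tb, cv_folds = 5, step = 1, seed = 3)
  picked <- colnames(tb$features)[sel$selected_mask]
  expect_true(all(c("sig01", "sig02", "sig03") %in% picked))
  expect_equal(sel$n_selected, sum(sel$selected_mask))
  expect_equal(nrow(sel$cv_curve), length(sel$cv_curve$size))
})

test_that("a single feature is trivially selected", {
  tb <- planted_table(10, 1, 0, seed = 4)
  sel <- rfecv_select(tb)
  expect_true(all(sel$selected_mask))
  expect_equal(sel$n_selected, 1L)
})

test_that("label permutation drives the CV curve to chance", {
  tb <- planted_table(n_per_class = 30, n_signal = 2, n_noise = 18, seed = 5)
  withr::with_seed(6, tb$labels <- sample(tb$labels))
  sel <- rfecv_select(tb, cv_folds = 5, seed = 7)
  expect_lt(max(sel$cv_curve$accuracy), 0.75)
})

test_that("selection is deterministic under a fixed seed", {
  tb <- planted_table(20, 2, 8, seed = 8)
  a <- rfecv_select(tb, seed = 9)
  b <- rfecv_select(tb, seed = 9)
  expect_identical(a$selected_mask, b$selected_mask)
  expect_identical(a$cv_curve, b$cv_curve)
})

test_that("pure-noise columns cannot buy more than fold noise in CV accuracy", {
  tb <- planted_table(n_per_class = 30, n_signal = 3, n_noise = 5, seed = 10)
  sel_small <- rfecv_select(tb, seed = 11)
  wide <- planted_table(n_per_class = 30, n_signal = 3, n_noise = 25, seed = 10)
  sel_wide <- rfecv_select(wide, seed = 11)
  expect_lte(max(sel_wide$cv_curve$accuracy),
             max(sel_small$cv_curve$accuracy) + 0.05)
})

test_that("two-pass selection fuses survivors from both families", {
  tf <- planted_table(n_per_class = 35, n_signal = 2, n_noise = 10, delta = 2,
                      seed = 12)
  cf <- planted_table(n_per_class = 35, n_signal = 2, n_noise = 10, delta = 2,
                      seed = 13)
  colnames(cf$features) <- paste0("cf_", colnames(cf$features))
  cf$labels <- tf$labels  # same label vector for both tables
  res <- two_pass_select(tf, cf, cv_folds = 4, seed = 14)
  final <- colnames(res$table$features)
  expect_gt(sum(final %in% colnames(tf$features)), 0)
  expect_gt(sum(startsWith(final, "cf_")), 0)
  expect_equal(res$fused$n_selected, ncol(res$table$features))
})

test_that("signal confined to TF leaves at least one TF survivor and shrinks CF share", {
  tf <- planted_table(n_per_class = 35, n_signal = 3, n_noise = 9, delta = 2.5,
                      seed = 15)
  cf <- planted_table(n_per_class = 35, n_signal = 0, n_noise = 12, seed = 16)
  colnames(cf$features) <- paste0("cf_", colnames(cf$features))
  cf$labels <- tf$labels
  res <- two_pass_select(tf, cf, cv_folds = 4, seed = 17)
  final <- colnames(res$table$features)
  cf_share_in <- res$cf$n_selected / (res$tf$n_selected + res$cf$n_selected)
  cf_share_out <- mean(startsWith(final, "cf_"))
  expect_gt(sum(final %in% colnames(tf$features)), 0)
  expect_lte(cf_share_out, cf_share_in + 1e-9)
})

test_that("selection never sees held-out subjects: test-only signal is not found", {
  # a sentinel feature predictive ONLY among test-split subjects must not be
  # preferred by selection fitted on the training split
  withr::with_seed(18, {
    n <- 80
    y <- rep(c("mild", "severe"), each = n / 2)
    x <- matrix(rnorm(n * 12), n)
    colnames(x) <- sprintf("f%02d", 1:12)
  })
  split <- stratified_split(y, 0.6, seed = 19)
  withr::with_seed(20, {
    x[split$test, 1] <- ifelse(y[split$test] == "severe", 3, -3) + rnorm(length(split$test))
    x[, 2] <- ifelse(y == "severe", 2, -2) + rnorm(n)  # genuine signal everywhere
  })
  tb <- feature_table(x, y)
  sel <- rfecv_select(subset_table(tb, subjects = split$train), seed = 21)
  picked <- colnames(x)[sel$selected_mask]
  expect_true("f02" %in% picked)
  expect_gt(sel$ranking[1], sel$ranking[2])  # sentinel ranked below real signal
})

test_that("degenerate selection inputs are rejected", {
  tb <- planted_table(10, 1, 4, seed = 22)
  tb$labels <- factor(rep("mild", 20))
  expect_error(rfecv_select(tb), "two classes")
})
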