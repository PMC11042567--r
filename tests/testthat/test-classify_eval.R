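test_that("the stratified 60/40 split reproduces the study composition", {
  labels <- c(rep("severe", 82), rep("mild", 58))
  sp <- stratified_split(labels, 0.6, seed = 1)
  expect_equal(sum(labels[sp$train] == "severe"), 49)
  expect_equal(sum(labels[sp$train] == "mild"), 35)
  expect_equal(sum(labels[sp$test] == "severe"), 33)
  expect_equal(sum(labels[sp$test] == "mild"), 23)
  # 10/10 at 0.5 -> 5/5 per class
  sp2 <- stratified_split(rep(c("a", "b"), each = 10), 0.5, seed = 2)
  expect_equal(length(sp2$train), 10)
  # partition property on random label vectors
  for (s in 1:3) {
    lab <- withr::with_seed(s, sample(c("mild", "severe"), 30, replace = TRUE,
                                      prob = c(0.4, 0.6)))
    sp3 <- stratified_split(lab, 0.6, seed = s)
    expect_setequal(c(sp3$train, sp3$test), seq_along(lab))
    expect_length(intersect(sp3$train, sp3$test), 0)
  }
  expect_error(stratified_split(c("a", "a", "b", "b"), 0.9), "empty class")
})

test_that("classification metrics match the hand-computed confusion matrix", {
  # TP=3, FN=1, TN=4, FP=2 with positive class "severe"
  y_true <- c(rep("severe", 4), rep("mild", 6))
  y_pred <- c("severe", "severe", "severe", "mild",
              "severe", "severe", "mild", "mild", "mild", "mild")
  m <- classification_metrics(y_true, y_pred)
  expect_equal(unname(m["sensitivity"]), 0.75)
  expect_equal(unname(m["specificity"]), 2 / 3, tolerance = 1e-9)
  expect_equal(unname(m["accuracy"]), 0.7)
  expect_equal(unname(m["f1"]), 2 * (3 / 5) * (3 / 4) / ((3 / 5) + (3 / 4)),
               tolerance = 1e-9)
  # perfect predictions
  mp <- classification_metrics(y_true, y_true, scores = c(rep(1, 4), rep(0, 6)))
  expect_true(all(mp == 1))
  # uninformative constant scores -> AUC 0.5
  mu <- classification_metrics(y_true, y_pred, scores = rep(0.3, 10))
  expect_equal(unname(mu["auc"]), 0.5)
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(3, {
    y <- sample(c("mild", "severe"), 60, replace = TRUE)
    s <- rnorm(60) + (y == "severe")
  })
  m <- classification_metrics(y, y, scores = s)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, levels = c("mild", "severe"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(unname(m["auc"]), ref, tolerance = 1e-12)
})

test_that("grid search refits the winning lattice point deterministically", {
  tb <- planted_table(n_per_class = 25, n_signal = 3, n_noise = 3, delta = 3,
                      seed = 4)
  x <- scale(tb$features)
  # size-1 grid returns that configuration
  g1 <- grid_search_fit(x, tb$labels, "svm",
                        data.frame(cost = 1, kernel = "linear", gamma = NA),
                        inner_folds = 3, seed = 5)
  expect_equal(g1$best_params$cost, 1)
  # separable toy data: training accuracy 1 for the margin classifier
  expect_equal(mean(nirsdepress:::predict_labels(g1$model, x) == tb$labels), 1)
  # best parameters stable under subject order shuffling with the same seed
  # (both costs separate this toy problem perfectly, so the tie-break to the
  # first lattice point must win regardless of row order)
  grid <- data.frame(cost = c(1, 100), kernel = "linear", gamma = NA)
  a <- grid_search_fit(x, tb$labels, "svm", grid, inner_folds = 3, seed = 6)
  perm <- withr::with_seed(7, sample(nrow(x)))
  b <- grid_search_fit(x[perm, ], tb$labels[perm], "svm", grid,
                       inner_folds = 3, seed = 6)
  expect_equal(a$best_params, b$best_params)
})

test_that("every model family trains, scores and beats chance on separable data", {
  tb <- planted_table(n_per_class = 25, n_signal = 4, n_noise = 4, delta = 3,
                      seed = 8)
  sp <- stratified_split(tb$labels, 0.6, seed = 9)
  grids <- list(svm = data.frame(cost = 1, kernel = "linear", gamma = NA),
                lr = data.frame(cost = 1),
                rf = data.frame(ntree = 100, maxdepth = NA),
                mlp = data.frame(size = 8, decay = 1e-2))
  for (mod in c("svm", "lr", "rf", "mlp")) {
    ev <- holdout_evaluate(tb, sp, mod, grids[[mod]], inner_folds = 3, seed = 10)
    expect_gt(unname(ev$metrics["accuracy"]), 0.8, label = mod)
    expect_true(all(ev$metrics >= 0 & ev$metrics <= 1), label = mod)
  }
})

test_that("nested CV on constant features falls back to the majority class", {
  x <- matrix(1, 60, 3, dimnames = list(NULL, c("a", "b", "c")))
  tb <- feature_table(x, rep(c("mild", "severe"), times = c(24, 36)))
  res <- nested_cv_evaluate(tb, "rf", data.frame(ntree = 50, maxdepth = 3),
                            outer_folds = 5, inner_folds = 2, seed = 11)
  expect_equal(unname(res$mean["accuracy"]), 0.6, tolerance = 0.05)
})

test_that("the comparison report has the full model x feature-set x metric shape", {
  tf <- planted_table(n_per_class = 20, n_signal = 2, n_noise = 4, seed = 12)
  cf <- planted_table(n_per_class = 20, n_signal = 2, n_noise = 4, seed = 13)
  colnames(cf$features) <- paste0("cf_", colnames(cf$features))
  cf$labels <- tf$labels
  tables <- list(TF = tf, CF = cf, TCF = fuse_tables(tf, cf))
  grids <- list(svm = data.frame(cost = 1, kernel = "linear", gamma = NA),
                lr = data.frame(cost = 1),
                rf = data.frame(ntree = 50, maxdepth = 3),
                mlp = data.frame(size = 4, decay = 1e-2))
  rep1 <- run_model_comparison(tables, c("svm", "lr", "rf", "mlp"), grids,
                               inner_folds = 2, seed = 14)
  expect_equal(nrow(rep1$report), 12)
  expect_true(all(c("auc", "accuracy", "sensitivity", "specificity", "f1") %in%
                    names(rep1$report)))
  rep2 <- run_model_comparison(tables, c("svm", "lr", "rf", "mlp"), grids,
                               inner_folds = 2, seed = 14)
  expect_identical(rep1$report, rep2$report)
})

test_that("metric identities hold on every report row", {
  tf <- planted_table(n_per_class = 20, n_signal = 2, n_noise = 4, seed = 15)
  sp <- stratified_split(tf$labels, 0.6, seed = 16)
  ev <- holdout_evaluate(tf, sp, "svm",
                         data.frame(cost = 1, kernel = "linear", gamma = NA),
                         inner_folds = 2, seed = 17)
  n_test <- length(sp$test)
  p <- sum(tf$labels[sp$test] == "severe"); n <- n_test - p
  expect_equal(unname(ev$metrics["accuracy"]),
               unname((ev$metrics["sensitivity"] * p + ev$metrics["specificity"] * n) /
                        (p + n)),
               tolerance = 1e-9)
})
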