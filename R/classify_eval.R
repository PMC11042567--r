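# Stratified splitting, grid-search model fitting, nested cross-validation,
# classification metrics, and the model x feature-set comparison report.

#' Stratified train/test split
#'
#' Per class, `floor(fraction * n + 0.5)` subjects (round half up) go to the
#' training split and the remainder to the test split; assignment within class
#' is a seeded random draw. For 82 severe + 58 mild at fraction 0.6 this gives
#' a 49/35 training and 33/23 test composition.
#'
#' @param labels Per-subject class labels.
#' @param train_fraction Training fraction in (0, 1) (default 0.6).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.6, seed = 1L) {
  assert_that(is_number(train_fraction) && train_fraction > 0 && train_fraction < 1,
              "train_fraction must be in (0, 1)")
  labels <- factor(labels)
  assert_that(all(table(labels) >= 2), "need at least 2 subjects per class")
  with_seed(seed, {
    train <- integer(0)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      n_tr <- as.integer(floor(train_fraction * length(idx) + 0.5))
      if (n_tr == 0 || n_tr == length(idx)) {
        stop("train_fraction leaves an empty class partition", call. = FALSE)
      }
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Default hyperparameter grids for the four model families
#'
#' Margin classifier (SVM): cost over `10^(-2..2)`, linear and RBF kernels,
#' RBF gamma `"scale"` (1/(p * var)) or `10^(-3..0)`. Logistic regression
#' (ridge-penalized): cost `10^(-2..2)`. Random forest: 100 or 300 trees,
#' depth 3, 5 or unlimited. Multi-layer perceptron: one hidden layer of 16 or
#' 64 units, weight decay `1e-4` or `1e-2`.
#'
#' @return Named list of parameter data.frames, lattice order preserved.
#' @export
default_grids <- function() {
  list(
    svm = rbind(
      expand.grid(cost = 10^(-2:2), kernel = "linear", gamma = NA,
                  stringsAsFactors = FALSE),
      expand.grid(cost = 10^(-2:2), kernel = "radial",
                  gamma = c(NA, 10^(-3:0)), stringsAsFactors = FALSE)
    ),
    lr = expand.grid(cost = 10^(-2:2)),
    rf = expand.grid(ntree = c(100, 300), maxdepth = c(3, 5, NA)),
    mlp = expand.grid(size = c(16, 64), decay = c(1e-4, 1e-2))
  )
}

# Fit one model configuration on standardized features. Returns an object
# with enough state to score new subjects.
fit_model <- function(x, y, model, params, seed = 1L) {
  pos <- levels(y)[2]  # scores favor the second level; metrics fix positive class
  if (all(apply(x, 2, stats::sd) == 0)) {
    # no informative feature: the only defensible rule is the majority class
    # (several backends hang or error on all-constant predictors)
    maj <- levels(y)[which.max(tabulate(y))]
    return(structure(list(model = "majority", fit = maj, params = params,
                          levels = levels(y), positive = pos),
                     class = "nirs_model"))
  }
  fit <- with_seed(seed, switch(model,
    svm = {
      gamma <- if (is.na(params$gamma)) 1 / (ncol(x) * max(mean(apply(x, 2, stats::var)), 1e-12))
               else params$gamma
      e1071::svm(x, y, kernel = params$kernel, cost = params$cost, gamma = gamma,
                 scale = FALSE)
    },
    lr = glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = 1 / (params$cost * nrow(x)), standardize = FALSE),
    rf = randomForest::randomForest(
      x, y, ntree = params$ntree,
      maxnodes = if (is.na(params$maxdepth)) NULL else 2^params$maxdepth),
    mlp = nnet::nnet(x, nnet::class.ind(y), size = params$size, decay = params$decay,
                     maxit = 200, softmax = TRUE, trace = FALSE,
                     MaxNWts = 200000)
  ))
  structure(list(model = model, fit = fit, params = params, levels = levels(y),
                 positive = pos), class = "nirs_model")
}

# Decision scores: larger = more like levels(y)[2].
predict_scores <- function(obj, x) {
  switch(obj$model,
    majority = rep(if (obj$fit == obj$levels[2]) 1 else -1, nrow(x)),
    svm = {
      dv <- attr(stats::predict(obj$fit, x, decision.values = TRUE), "decision.values")
      s <- as.numeric(dv)
      # e1071 orients the decision value toward the first-seen class; normalize
      if (grepl(paste0("^", obj$levels[2], "/"), colnames(dv)[1])) s else -s
    },
    lr = as.numeric(stats::predict(obj$fit, x, type = "link")),
    rf = stats::predict(obj$fit, x, type = "prob")[, obj$levels[2]],
    mlp = stats::predict(obj$fit, x)[, obj$levels[2]]
  )
}

predict_labels <- function(obj, x) {
  s <- predict_scores(obj, x)
  factor(ifelse(s > score_cutoff(obj), obj$levels[2], obj$levels[1]),
         levels = obj$levels)
}

score_cutoff <- function(obj) {
  switch(obj$model, svm = 0, lr = 0, rf = 0.5, mlp = 0.5, majority = 0)
}

#' Classification metrics from labels and scores
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy, F1
#' (`2 * precision * sensitivity / (precision + sensitivity)`), and AUC of the
#' ROC computed from the ranking of `scores` (trapezoidal; ties get half
#' credit). The positive class defaults to `"severe"` when present.
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels.
#' @param scores Optional decision scores (higher = more positive); without
#'   them AUC is `NA`.
#' @param positive Positive-class label.
#' @return Named numeric vector `auc, accuracy, sensitivity, specificity, f1`.
#' @export
classification_metrics <- function(y_true, y_pred, scores = NULL,
                                   positive = NULL) {
  assert_that(length(y_true) == length(y_pred), "label vectors must match")
  y_true <- factor(y_true)
  if (is.null(positive)) {
    positive <- if ("severe" %in% levels(y_true)) "severe" else levels(y_true)[2]
  }
  is_pos <- y_true == positive
  pred_pos <- y_pred == positive
  tp <- sum(is_pos & pred_pos); fn <- sum(is_pos & !pred_pos)
  tn <- sum(!is_pos & !pred_pos); fp <- sum(!is_pos & pred_pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / length(y_true)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (!is.na(sens) && prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  auc <- NA_real_
  if (!is.null(scores)) {
    assert_that(any(is_pos) && any(!is_pos),
                "AUC needs both classes present in y_true")
    or <- rank(scores)  # average ranks handle ties (trapezoidal equivalence)
    auc <- (sum(or[is_pos]) - sum(is_pos) * (sum(is_pos) + 1) / 2) /
      (sum(is_pos) * sum(!is_pos))
  }
  out <- c(auc = auc, accuracy = acc, sensitivity = sens, specificity = spec, f1 = f1)
  # identity check: accuracy decomposes over class counts
  if (!is.na(sens) && !is.na(spec)) {
    p <- sum(is_pos); n <- sum(!is_pos)
    stopifnot(abs(acc - (sens * p + spec * n) / (p + n)) < 1e-9)
  }
  out
}

#' Grid-search model fitting
#'
#' Exhaustive evaluation of a parameter lattice by stratified inner-CV
#' accuracy; ties go to the first configuration in lattice order; the winner
#' is refit on the full training set. Features must already be standardized
#' (with statistics fitted on training data only).
#'
#' @param x Standardized feature matrix (training subjects).
#' @param y Training labels (factor, 2 classes).
#' @param model One of `"svm", "lr", "rf", "mlp"`.
#' @param grid Parameter data.frame (one row per configuration); default from
#'   [default_grids()].
#' @param inner_folds Stratified CV folds (default 5, >= 2).
#' @param seed Integer seed.
#' @return List: fitted `model` object, `best_params`, `cv_accuracy` per
#'   configuration.
#' @export
grid_search_fit <- function(x, y, model = c("svm", "lr", "rf", "mlp"),
                            grid = NULL, inner_folds = 5, seed = 1L) {
  model <- match.arg(model)
  y <- droplevels(factor(y))
  assert_that(nlevels(y) == 2, "need exactly two classes")
  assert_that(is_count(inner_folds, min = 2L), "inner_folds must be >= 2")
  if (is.null(grid)) grid <- default_grids()[[model]]
  assert_that(nrow(grid) >= 1, "grid must be nonempty")
  fold <- stratified_folds(y, inner_folds, seed)
  seeds <- derive_seeds(seed, nrow(grid) * inner_folds)
  cv_acc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    accs <- c()
    for (f in seq_len(inner_folds)) {
      tr <- fold != f
      if (length(unique(y[!tr])) < 1 || length(unique(y[tr])) < 2) next
      fit <- fit_model(x[tr, , drop = FALSE], y[tr], model, grid[gi, , drop = FALSE],
                       seed = seeds[(gi - 1) * inner_folds + f])
      accs <- c(accs, mean(predict_labels(fit, x[!tr, , drop = FALSE]) == y[!tr]))
    }
    cv_acc[gi] <- mean(accs)
  }
  best <- which.max(cv_acc)  # ties -> first in lattice order
  final <- fit_model(x, y, model, grid[best, , drop = FALSE], seed = seeds[1])
  list(model = final, best_params = grid[best, , drop = FALSE], cv_accuracy = cv_acc)
}

#' Nested cross-validated evaluation
#'
#' Outer stratified folds hold out test subjects; for each outer fold the
#' inner loop grid-searches hyperparameters on the outer-training subjects
#' only (features z-scored with outer-training statistics), the winning
#' configuration is refit and evaluated once on the outer-test fold. No
#' subject ever appears on both sides of a fold.
#'
#' @param table A [feature_table()].
#' @param model One of `"svm", "lr", "rf", "mlp"`.
#' @param grid Parameter lattice (default [default_grids()]).
#' @param outer_folds,inner_folds Fold counts (default 5 and 5).
#' @param seed Integer seed.
#' @param positive Positive class for metrics (default `"severe"` if present).
#' @return List: `fold_metrics` (matrix folds x metrics), `mean`, `sd`,
#'   `chosen_params` per fold.
#' @export
nested_cv_evaluate <- function(table, model = "svm", grid = NULL,
                               outer_folds = 5, inner_folds = 5, seed = 1L,
                               positive = NULL) {
  assert_that(inherits(table, "feature_table"), "table must be a feature_table")
  y <- droplevels(table$labels)
  assert_that(min(table(y)) >= outer_folds, "too few subjects per class for the outer folds")
  x <- table$features
  fold <- stratified_folds(y, outer_folds, seed)
  seeds <- derive_seeds(seed, outer_folds)
  fm <- NULL; chosen <- list()
  for (f in seq_len(outer_folds)) {
    tr <- fold != f
    sc <- standardize_fit(x[tr, , drop = FALSE])
    xtr <- standardize_apply(x[tr, , drop = FALSE], sc)
    xte <- standardize_apply(x[!tr, , drop = FALSE], sc)
    gs <- grid_search_fit(xtr, y[tr], model, grid, inner_folds, seed = seeds[f])
    m <- classification_metrics(y[!tr], predict_labels(gs$model, xte),
                                predict_scores(gs$model, xte), positive)
    fm <- rbind(fm, m)
    chosen[[f]] <- gs$best_params
  }
  rownames(fm) <- paste0("fold", seq_len(outer_folds))
  list(fold_metrics = fm, mean = colMeans(fm), sd = apply(fm, 2, stats::sd),
       chosen_params = chosen)
}

#' Train on a split, grid-search, and evaluate on the held-out test set
#'
#' @param table A [feature_table()].
#' @param split A list with `train`/`test` indices from [stratified_split()].
#' @param model,grid,inner_folds,seed,positive As in [nested_cv_evaluate()].
#' @return List: `metrics`, `best_params`, fitted `model`.
#' @export
holdout_evaluate <- function(table, split, model = "svm", grid = NULL,
                             inner_folds = 5, seed = 1L, positive = NULL) {
  x <- table$features; y <- droplevels(table$labels)
  sc <- standardize_fit(x[split$train, , drop = FALSE])
  xtr <- standardize_apply(x[split$train, , drop = FALSE], sc)
  xte <- standardize_apply(x[split$test, , drop = FALSE], sc)
  gs <- grid_search_fit(xtr, y[split$train], model, grid, inner_folds, seed)
  m <- classification_metrics(y[split$test], predict_labels(gs$model, xte),
                              predict_scores(gs$model, xte), positive)
  list(metrics = m, best_params = gs$best_params, model = gs$model)
}

#' Compare models across TF, CF and fused feature sets
#'
#' Evaluates each requested model on each feature table with one stratified
#' 60/40-style split: grid search (inner CV) on the training split, metrics on
#' the held-out test split; optionally also nested CV on the full table. The
#' result mirrors a model x feature-set metrics table.
#'
#' @param tables Named list of [feature_table()]s, e.g.
#'   `list(TF = ..., CF = ..., TCF = ...)`, over the same subjects.
#' @param models Character subset of `c("svm", "lr", "rf", "mlp")`.
#' @param grids Named list of grids (default [default_grids()]).
#' @param train_fraction Split fraction (default 0.6).
#' @param inner_folds Inner CV folds for the grid search.
#' @param nested Also run [nested_cv_evaluate()] per cell (default FALSE).
#' @param outer_folds Outer folds when `nested = TRUE`.
#' @param seed Integer seed (split and fits).
#' @param positive Positive class for metrics.
#' @return An object of class `eval_report`: data.frame `report` with one row
#'   per model x feature set, plus `details`.
#' @export
run_model_comparison <- function(tables, models = c("svm", "lr", "rf", "mlp"),
                                 grids = NULL, train_fraction = 0.6,
                                 inner_folds = 5, nested = FALSE,
                                 outer_folds = 5, seed = 1L, positive = NULL) {
  assert_that(is.list(tables) && !is.null(names(tables)), "tables must be a named list")
  labels0 <- tables[[1]]$labels
  for (tb in tables) assert_that(identical(tb$labels, labels0),
                                 "tables must share subjects and labels")
  if (is.null(grids)) grids <- default_grids()
  split <- stratified_split(labels0, train_fraction, seed)
  rows <- list(); details <- list()
  for (model in models) {
    for (set in names(tables)) {
      ev <- holdout_evaluate(tables[[set]], split, model, grids[[model]],
                             inner_folds, seed, positive)
      nc <- if (nested) nested_cv_evaluate(tables[[set]], model, grids[[model]],
                                           outer_folds, inner_folds, seed, positive)
            else NULL
      rows[[length(rows) + 1]] <- data.frame(
        model = model, feature_set = set, t(ev$metrics),
        nested_accuracy = if (nested) nc$mean[["accuracy"]] else NA_real_)
      details[[paste(model, set, sep = ".")]] <-
        list(best_params = ev$best_params, nested = nc)
    }
  }
  structure(list(report = do.call(rbind, rows), details = details, split = split),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Model comparison (held-out test split):\n")
  print(x$report, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write an evaluation report as JSON
#' @param report An `eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(list(report = report$report,
                            best_params = lapply(report$details, `[[`, "best_params")),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
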