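# Recursive feature elimination with cross-validation (RFECV), and the
# two-pass select-fuse-select procedure.

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}

standardize_apply <- function(x, sc) {
  sweep(sweep(x, 2, sc$mu, "-"), 2, sc$sd, "/")
}

stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# Squared linear-SVM weights as feature importances.
linear_svm_importance <- function(x, y, cost = 1) {
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- crossprod(fit$coefs, fit$SV)
  as.numeric(w)^2
}

svm_accuracy <- function(x_tr, y_tr, x_te, y_te, cost = 1) {
  fit <- e1071::svm(x_tr, y_tr, kernel = "linear", cost = cost, scale = FALSE)
  mean(stats::predict(fit, x_te) == y_te)
}

# One RFE path on (x, y): eliminate `step` least-important features at a time.
# Returns elimination order (indices, first eliminated first) and the sequence
# of surviving sets at each evaluated size.
rfe_path <- function(x, y, step, cost = 1) {
  p <- ncol(x)
  surviving <- seq_len(p)
  order_out <- integer(0)
  sets <- list()
  sizes <- integer(0)
  while (length(surviving) >= 1) {
    sets[[length(sets) + 1]] <- surviving
    sizes <- c(sizes, length(surviving))
    if (length(surviving) == 1) break
    imp <- linear_svm_importance(x[, surviving, drop = FALSE], y, cost)
    k <- min(step, length(surviving) - 1L)
    drop_local <- order(imp)[seq_len(k)]
    order_out <- c(order_out, surviving[drop_local])
    surviving <- surviving[-drop_local]
  }
  list(sets = sets, sizes = sizes, elim_order = c(order_out, rev(surviving)))
}

#' Recursive feature elimination with cross-validation
#'
#' Features are recursively eliminated by linear maximum-margin (SVM)
#' importance (squared weights); the optimal subset size maximizes mean
#' stratified-CV accuracy (ties broken toward the smaller subset). The final
#' ranking comes from an RFE pass on the full table; the selected mask keeps
#' the top-ranked features at the CV-optimal size. Features are z-scored
#' inside each fold from the training part only.
#'
#' @param table A [feature_table()] (>= 2 classes).
#' @param cv_folds Number of stratified folds (default 5).
#' @param step Features eliminated per iteration (default 1).
#' @param cost Linear-SVM cost parameter (default 1).
#' @param seed Integer seed (fold assignment).
#' @return An object of class `selection_result`: `selected_mask`, `ranking`
#'   (1 = retained longest), `cv_curve` (data.frame size/accuracy),
#'   `n_selected`, `feature_names`.
#' @export
rfecv_select <- function(table, cv_folds = 5, step = 1, cost = 1, seed = 1L) {
  assert_that(inherits(table, "feature_table"), "table must be a feature_table")
  y <- droplevels(table$labels)
  assert_that(nlevels(y) >= 2, "need at least two classes")
  x <- table$features
  p <- ncol(x)
  assert_that(p >= 1, "need at least one feature")
  if (p == 1) {
    return(structure(list(selected_mask = TRUE, ranking = 1L,
                          cv_curve = data.frame(size = 1L, accuracy = NA_real_),
                          n_selected = 1L, feature_names = colnames(x)),
                     class = "selection_result"))
  }
  fold <- stratified_folds(y, cv_folds, seed)
  acc <- NULL
  for (f in seq_len(cv_folds)) {
    tr <- fold != f; te <- !tr
    if (length(unique(y[te])) < 1 || length(unique(y[tr])) < 2) next
    sc <- standardize_fit(x[tr, , drop = FALSE])
    xtr <- standardize_apply(x[tr, , drop = FALSE], sc)
    xte <- standardize_apply(x[te, , drop = FALSE], sc)
    path <- rfe_path(xtr, y[tr], step, cost)
    a <- vapply(path$sets, function(s) {
      svm_accuracy(xtr[, s, drop = FALSE], y[tr], xte[, s, drop = FALSE], y[te], cost)
    }, numeric(1))
    acc <- if (is.null(acc)) rbind(a) else rbind(acc, a)
  }
  sizes <- rfe_path_sizes(p, step)
  mean_acc <- colMeans(acc)
  best <- which(mean_acc == max(mean_acc))
  n_selected <- min(sizes[best])          # ties -> smallest subset
  # final ranking on the full table
  sc <- standardize_fit(x)
  full_path <- rfe_path(standardize_apply(x, sc), y, step, cost)
  ranking <- integer(p)
  ranking[rev(full_path$elim_order)] <- seq_len(p)  # 1 = survived longest
  mask <- ranking <= n_selected
  structure(list(selected_mask = mask, ranking = ranking,
                 cv_curve = data.frame(size = sizes, accuracy = mean_acc),
                 n_selected = as.integer(n_selected),
                 feature_names = colnames(x)),
            class = "selection_result")
}

rfe_path_sizes <- function(p, step) {
  sizes <- p
  while (sizes[length(sizes)] > 1) {
    sizes <- c(sizes, max(1L, sizes[length(sizes)] - step))
  }
  as.integer(sizes)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("RFECV selection: %d of %d features (best mean CV accuracy %.3f)\n",
              x$n_selected, length(x$ranking), max(x$cv_curve$accuracy, na.rm = TRUE)))
  invisible(x)
}

#' Two-pass RFECV: select TF and CF separately, fuse, re-select
#'
#' Pass 1 runs RFECV independently on the temporal-feature table and the
#' correlation-feature table; the survivors are concatenated and pass 2 runs
#' RFECV on the fused table. Selection must be fed training subjects only; the
#' test split of a study never touches it.
#'
#' @param tf_table,cf_table [feature_table()]s over the same subjects.
#' @param cv_folds,step,cost,seed Passed to [rfecv_select()].
#' @return List with the final fused `table` and the three `selection_result`s
#'   (`tf`, `cf`, `fused`).
#' @export
two_pass_select <- function(tf_table, cf_table, cv_folds = 5, step = 1,
                            cost = 1, seed = 1L) {
  assert_that(identical(tf_table$labels, cf_table$labels),
              "tables must share subjects and labels")
  seeds <- derive_seeds(seed, 3)
  sel_tf <- rfecv_select(tf_table, cv_folds, step, cost, seeds[1])
  sel_cf <- rfecv_select(cf_table, cv_folds, step, cost, seeds[2])
  if (sel_tf$n_selected + sel_cf$n_selected == 0) {
    stop("no features survived the first selection pass", call. = FALSE)
  }
  fused <- fuse_tables(subset_table(tf_table, features = sel_tf$selected_mask),
                       subset_table(cf_table, features = sel_cf$selected_mask))
  sel_fused <- rfecv_select(fused, cv_folds, step, cost, seeds[3])
  list(table = subset_table(fused, features = sel_fused$selected_mask),
       tf = sel_tf, cf = sel_cf, fused = sel_fused)
}
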