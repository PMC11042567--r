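# Channel-activation statistics: per-subject GLM betas, one-sample activation
# t-tests, and the between-group activation contrast.

#' Per-channel GLM activation amplitude (beta)
#'
#' Least-squares fit of `[intercept, boxcar(task) convolved with the canonical
#' HRF]` to each channel; the returned beta is the task-regressor coefficient,
#' the activation intensity of that channel. HbO by default.
#'
#' @param recording A preprocessed [hemo_recording()] with a paradigm.
#' @param paradigm Optional override of the recording's paradigm.
#' @param species `"HbO"` (default) or `"HbR"`.
#' @return Named numeric vector of per-channel betas.
#' @export
glm_beta <- function(recording, paradigm = NULL, species = c("HbO", "HbR")) {
  species <- match.arg(species)
  assert_that(inherits(recording, "hemo_recording"), "recording must be a hemo_recording")
  if (is.null(paradigm)) paradigm <- recording$paradigm
  assert_that(!is.null(paradigm), "a paradigm is required")
  reg <- task_regressor(paradigm)
  X <- cbind(intercept = 1, task = reg)
  if (qr(X)$rank < 2) stop("design matrix is collinear", call. = FALSE)
  data <- if (species == "HbO") recording$hbo else recording$hbr
  coefs <- as.matrix(stats::lm.fit(X, data)$coefficients)
  stats::setNames(as.numeric(coefs["task", ]), recording$channel_ids)
}

#' One-sample channel activation test
#'
#' Per-channel one-sample t-test of the betas against zero; a channel is
#' "activated" when p < alpha.
#'
#' @param betas Matrix, subjects x channels.
#' @param alpha Significance level (default 0.05).
#' @param bonferroni Apply Bonferroni correction across channels (default
#'   FALSE, matching raw per-channel thresholding).
#' @return An object of class `activation_result`: data.frame with `channel`,
#'   `beta` (mean), `t_value`, `p_value`, `significant`.
#' @export
channel_activation_test <- function(betas, alpha = 0.05, bonferroni = FALSE) {
  betas <- as.matrix(betas)
  assert_that(nrow(betas) >= 2, "need at least 2 subjects")
  res <- lapply(seq_len(ncol(betas)), function(ch) {
    b <- betas[, ch]
    if (stats::sd(b) == 0) {
      data.frame(channel = ch, beta = mean(b), t_value = NA_real_,
                 p_value = NA_real_, significant = NA)
    } else {
      tt <- stats::t.test(b)
      data.frame(channel = ch, beta = mean(b), t_value = unname(tt$statistic),
                 p_value = tt$p.value, significant = NA)
    }
  })
  out <- do.call(rbind, res)
  thr <- if (bonferroni) alpha / ncol(betas) else alpha
  out$significant <- !is.na(out$p_value) & out$p_value < thr
  if (!is.null(colnames(betas))) out$channel <- colnames(betas)
  structure(out, class = c("activation_result", "data.frame"), alpha = alpha)
}

#' Between-group activation contrast
#'
#' Per-channel Welch two-sample t-test of group A betas against group B betas;
#' the sign convention is A minus B (call with the mild group first to get the
#' mild-minus-severe contrast).
#'
#' @param betas_a,betas_b Matrices, subjects x channels (same channel count).
#' @param alpha Significance level (default 0.05).
#' @param bonferroni Bonferroni-correct across channels (default FALSE).
#' @return An `activation_result` data.frame with the contrast mean in `beta`.
#' @export
group_activation_contrast <- function(betas_a, betas_b, alpha = 0.05,
                                      bonferroni = FALSE) {
  betas_a <- as.matrix(betas_a); betas_b <- as.matrix(betas_b)
  assert_that(ncol(betas_a) == ncol(betas_b), "channel counts must match")
  assert_that(nrow(betas_a) >= 2 && nrow(betas_b) >= 2,
              "need at least 2 subjects per group")
  res <- lapply(seq_len(ncol(betas_a)), function(ch) {
    tt <- stats::t.test(betas_a[, ch], betas_b[, ch])
    data.frame(channel = ch, beta = mean(betas_a[, ch]) - mean(betas_b[, ch]),
               t_value = unname(tt$statistic), p_value = tt$p.value,
               significant = NA)
  })
  out <- do.call(rbind, res)
  thr <- if (bonferroni) alpha / ncol(betas_a) else alpha
  out$significant <- out$p_value < thr
  if (!is.null(colnames(betas_a))) out$channel <- colnames(betas_a)
  structure(out, class = c("activation_result", "data.frame"), alpha = alpha)
}

#' Betas for every subject of a cohort
#'
#' Convenience wrapper: preprocess (optional) and fit the activation GLM per
#' subject.
#'
#' @param cohort An `fnirs_cohort`.
#' @param species `"HbO"` or `"HbR"`.
#' @param detrend_order Polynomial detrend order applied before the GLM
#'   (`NULL` skips detrending).
#' @param tddr Run TDDR motion correction first (default FALSE; slower).
#' @param filter Optional [filter_spec()] applied before the GLM.
#' @return Matrix subjects x channels of betas.
#' @export
cohort_betas <- function(cohort, species = "HbO", detrend_order = 3,
                         tddr = FALSE, filter = NULL) {
  assert_that(length(cohort) > 0, "empty cohort")
  do.call(rbind, lapply(cohort, function(s) {
    rec <- s$recording
    data <- if (species == "HbO") rec$hbo else rec$hbr
    fs <- rec$sampling_hz
    for (ch in seq_len(ncol(data))) {
      x <- data[, ch]
      if (!is.null(detrend_order)) x <- detrend_poly(x, detrend_order)
      if (tddr) x <- tddr_correct(x, fs)
      if (!is.null(filter)) x <- bandpass_filter(x, filter, fs)
      data[, ch] <- x
    }
    rec2 <- hemo_recording(data, data, fs, rec$paradigm, rec$channel_ids)
    glm_beta(rec2, species = "HbO")
  }))
}
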