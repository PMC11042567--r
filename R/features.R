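# Temporal (per-channel) and correlation (channel-pair) features from the
# task-window segment of each recording.

one_sided_periodogram <- function(x, sampling_hz) {
  n <- length(x)
  X <- stats::fft(x)
  kmax <- n %/% 2L
  k <- seq_len(kmax)              # bins 1..floor(n/2); DC excluded
  list(freq = k * sampling_hz / n, power = Mod(X[k + 1L])^2 / n)
}

#' Power spectral entropy
#'
#' Shannon entropy (natural log) of the normalized one-sided periodogram
#' (unwindowed FFT periodogram, DC bin excluded):
#' `H_f = -sum(p_k log p_k)` with `p_k = S_k / sum(S_k)`.
#'
#' @param x Numeric signal with nonzero energy off DC.
#' @param sampling_hz Sampling rate in Hz (affects only bin labelling).
#' @return Entropy in nats.
#' @export
power_spectral_entropy <- function(x, sampling_hz = 10) {
  pg <- one_sided_periodogram(x, sampling_hz)
  s <- sum(pg$power)
  assert_that(s > 0, "signal has zero spectral energy off DC")
  p <- pg$power / s
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Singular spectral entropy
#'
#' Embeds the signal in a Hankel trajectory matrix with window `embed_len`,
#' takes its singular values `lambda_i`, and returns the Shannon entropy
#' (natural log) of `lambda_i / sum(lambda_i)`.
#'
#' @param x Numeric signal.
#' @param embed_len Embedding window in samples (default 50, i.e. 5 s at
#'   10 Hz); must satisfy `1 < embed_len < length(x)`.
#' @return Entropy in nats.
#' @export
singular_spectral_entropy <- function(x, embed_len = 50) {
  n <- length(x)
  assert_that(is_count(embed_len, min = 2L) && embed_len < n,
              "embed_len must satisfy 1 < embed_len < length(x)")
  k <- n - embed_len + 1L
  H <- matrix(0, embed_len, k)
  for (i in seq_len(embed_len)) H[i, ] <- x[i:(i + k - 1L)]
  lambda <- svd(H, nu = 0, nv = 0)$d
  s <- sum(lambda)
  if (s == 0) return(0)
  p <- lambda / s
  p <- p[p > 1e-300]
  -sum(p * log(p))
}

#' Mean square frequency
#'
#' Power-weighted mean of squared frequency over the one-sided periodogram:
#' `sum(f_k^2 P_k) / sum(P_k)`.
#'
#' @inheritParams power_spectral_entropy
#' @return Mean square frequency in Hz^2.
#' @export
mean_square_frequency <- function(x, sampling_hz = 10) {
  pg <- one_sided_periodogram(x, sampling_hz)
  s <- sum(pg$power)
  assert_that(s > 0, "signal has zero spectral energy off DC")
  sum(pg$freq^2 * pg$power) / s
}

#' The nine temporal features of one signal segment
#'
#' Computed on the task-window segment: maximum, minimum, mean, rectified mean
#' (`mean(|x|)`), skewness (standardized third central moment), peak (crest)
#' factor (`max(|x|)/RMS`), mean square frequency, power spectral entropy and
#' singular spectral entropy. A constant segment has undefined skewness and
#' peak factor; the defined sentinels 0 and 1 are returned (with a warning).
#'
#' @param x Task-window signal segment.
#' @param sampling_hz Sampling rate in Hz.
#' @param ssa_embed Embedding window for the singular spectral entropy.
#' @return Named numeric vector of length 9.
#' @export
temporal_features <- function(x, sampling_hz = 10, ssa_embed = 50) {
  assert_that(length(x) > 2, "segment too short")
  m2 <- mean((x - mean(x))^2)
  r <- rms(x)
  if (m2 == 0) {
    warning("constant segment: skewness and peak factor set to sentinels 0 and 1")
    skew <- 0
    pf <- 1
    pse <- 0
    msf <- 0
  } else {
    skew <- mean((x - mean(x))^3) / m2^1.5
    pf <- max(abs(x)) / r
    pse <- power_spectral_entropy(x, sampling_hz)
    msf <- mean_square_frequency(x, sampling_hz)
  }
  c(maximum = max(x), minimum = min(x), mean = mean(x),
    rectified_mean = mean(abs(x)), skewness = skew, peak_factor = pf,
    mean_square_frequency = msf, power_spectral_entropy = pse,
    singular_spectral_entropy = singular_spectral_entropy(x, min(ssa_embed, length(x) - 1L)))
}

tf_kinds <- c("maximum", "minimum", "mean", "rectified_mean", "skewness",
              "peak_factor", "mean_square_frequency", "power_spectral_entropy",
              "singular_spectral_entropy")

#' Inter-channel Pearson correlation features
#'
#' Pearson correlation of the task-window segments for every unordered channel
#' pair, separately for HbO and HbR: `choose(n, 2) * 2` values in `[-1, 1]`.
#' A zero-variance channel yields 0 for its pairs, with a warning.
#'
#' @param recording A [hemo_recording()] with a paradigm.
#' @return Named numeric vector (`CF.pearson.chAA-chBB.<species>`).
#' @export
correlation_features <- function(recording) {
  assert_that(inherits(recording, "hemo_recording"), "recording must be a hemo_recording")
  assert_that(!is.null(recording$paradigm), "recording needs a paradigm for the task window")
  nc <- ncol(recording$hbo)
  assert_that(nc >= 2, "correlation features require at least 2 channels")
  win <- task_window(recording$paradigm)
  out <- c()
  for (species in c("HbO", "HbR")) {
    seg <- (if (species == "HbO") recording$hbo else recording$hbr)[win, , drop = FALSE]
    sds <- apply(seg, 2, stats::sd)
    if (any(sds == 0)) warning("zero-variance channel: its correlations set to 0")
    cm <- suppressWarnings(stats::cor(seg))
    cm[!is.finite(cm)] <- 0
    for (i in seq_len(nc - 1)) {
      for (j in (i + 1):nc) {
        out[sprintf("CF.pearson.%s-%s.%s", recording$channel_ids[i],
                    recording$channel_ids[j], species)] <- cm[i, j]
      }
    }
  }
  out
}

#' Feature table container
#'
#' Subjects x features matrix with labels and subject ids; column names encode
#' provenance (`TF.<kind>.chNN.<species>` or `CF.pearson.chAA-chBB.<species>`).
#'
#' @param features Numeric matrix with unique column names.
#' @param labels Per-subject labels (coerced to factor).
#' @param subject_ids Optional subject identifiers.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, labels, subject_ids = NULL) {
  features <- as.matrix(features)
  assert_that(!anyDuplicated(colnames(features)), "feature names must be unique")
  assert_that(nrow(features) == length(labels), "labels must match rows")
  if (is.null(subject_ids)) subject_ids <- sprintf("sub%03d", seq_len(nrow(features)))
  structure(list(features = features, labels = factor(labels),
                 subject_ids = subject_ids),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d subjects x %d features (%s)\n",
              nrow(x$features), ncol(x$features),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$features)

#' Subset a feature table
#' @param table A [feature_table()].
#' @param subjects Row (subject) indices, optional.
#' @param features Column selector (indices, names or logical mask), optional.
#' @return A [feature_table()].
#' @export
subset_table <- function(table, subjects = NULL, features = NULL) {
  x <- table$features; y <- table$labels; id <- table$subject_ids
  if (!is.null(subjects)) { x <- x[subjects, , drop = FALSE]; y <- y[subjects]; id <- id[subjects] }
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  feature_table(x, droplevels(y), id)
}

#' Column-bind two feature tables over the same subjects
#' @param a,b [feature_table()]s with identical subjects and labels.
#' @return A fused [feature_table()].
#' @export
fuse_tables <- function(a, b) {
  assert_that(identical(a$subject_ids, b$subject_ids) && identical(a$labels, b$labels),
              "tables must share subjects and labels")
  feature_table(cbind(a$features, b$features), a$labels, a$subject_ids)
}

#' Build the cohort feature table
#'
#' Extracts temporal features (9 per channel per species: `n * 2 * 9` columns)
#' and/or correlation features (`choose(n, 2) * 2` columns) from the
#' task-window segment of each subject's recording. For 18 channels this is
#' the 324-column TF and 306-column CF battery. Column order is deterministic:
#' family, then feature kind, then channel index, then species.
#'
#' @param cohort An `fnirs_cohort`, or a list of [hemo_recording()]s with a
#'   `labels` argument.
#' @param families Subset of `c("tf", "cf")`.
#' @param labels Required when `cohort` is a plain recording list.
#' @param ssa_embed Singular-spectrum embedding window (samples).
#' @return A [feature_table()].
#' @export
build_feature_table <- function(cohort, families = c("tf", "cf"), labels = NULL,
                                ssa_embed = 50) {
  families <- match.arg(families, several.ok = TRUE)
  if (inherits(cohort, "fnirs_cohort")) {
    labels <- cohort_labels(cohort)
    recordings <- lapply(cohort, function(s) s$recording)
  } else {
    assert_that(!is.null(labels), "labels required for a plain recording list")
    recordings <- cohort
  }
  assert_that(length(recordings) > 0, "empty cohort")
  ncs <- vapply(recordings, function(r) ncol(r$hbo), integer(1))
  assert_that(length(unique(ncs)) == 1, "recordings have heterogeneous channel counts")
  rows <- lapply(recordings, function(r) {
    win <- task_window(r$paradigm)
    out <- c()
    if ("tf" %in% families) {
      tf <- list()
      for (ch in seq_len(ncol(r$hbo))) {
        for (species in c("HbO", "HbR")) {
          seg <- (if (species == "HbO") r$hbo else r$hbr)[win, ch]
          tf[[paste(ch, species)]] <-
            suppressWarnings(temporal_features(seg, r$sampling_hz, ssa_embed))
        }
      }
      for (kind in tf_kinds) {
        for (ch in seq_len(ncol(r$hbo))) {
          for (species in c("HbO", "HbR")) {
            out[sprintf("TF.%s.%s.%s", kind, r$channel_ids[ch], species)] <-
              tf[[paste(ch, species)]][kind]
          }
        }
      }
    }
    if ("cf" %in% families) out <- c(out, suppressWarnings(correlation_features(r)))
    out
  })
  feature_table(do.call(rbind, rows), labels)
}
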