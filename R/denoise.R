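# CEEMDAN-WPT combined denoising, baselines, and the SNR/RMSE harness.

# Mean zero-crossing rate in Hz-equivalent cycles: crossings per second / 2
# estimates the dominant frequency of a narrowband component.
zero_crossing_rate <- function(x, sampling_hz) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0)
  crossings <- sum(s[-1] != s[-length(s)])
  crossings / (length(x) / sampling_hz)
}

#' Classify IMFs as high- or low-frequency
#'
#' An IMF is high-frequency when its zero-crossing rate exceeds twice the
#' filter stopband edge (default 0.2 Hz, so the threshold is 0.4 crossings/s,
#' i.e. an implied dominant frequency above 0.2 Hz). An empty high-frequency
#' set is a valid outcome: a signal with no content above the edge needs no
#' thresholding, and forcing one would distort clean recordings.
#'
#' @param set An `imf_set`.
#' @param sampling_hz Sampling rate in Hz.
#' @param edge_hz Frequency boundary in Hz (default 0.2).
#' @return Logical vector over IMFs, TRUE = high-frequency.
#' @export
split_imfs <- function(set, sampling_hz, edge_hz = 0.2) {
  k <- ncol(set$imfs)
  if (k == 0) return(logical(0))
  zcr <- apply(set$imfs, 2, zero_crossing_rate, sampling_hz = sampling_hz)
  zcr > 2 * edge_hz
}

#' CEEMDAN-WPT denoising
#'
#' Decomposes the signal with CEEMDAN, wavelet-packet-thresholds only the
#' high-frequency IMFs (per [split_imfs()]), and reconstructs by summing the
#' denoised high-frequency modes, the untouched low-frequency modes and the
#' residual.
#'
#' @param x Numeric signal.
#' @param ceemdan A [ceemdan_config()].
#' @param wpt A [wpt_config()].
#' @param sampling_hz Sampling rate in Hz (drives the high/low split rule).
#' @param edge_hz High/low frequency boundary in Hz (default 0.2).
#' @return List with `signal` (the denoised signal), `imf_set`, and `high`
#'   (the logical high-frequency mask).
#' @export
ceemdan_wpt_denoise <- function(x, ceemdan = ceemdan_config(), wpt = wpt_config(),
                                sampling_hz = 10, edge_hz = 0.2) {
  set <- ceemdan_decompose(x, ceemdan)
  high <- split_imfs(set, sampling_hz, edge_hz)
  out <- set$residual
  if (ncol(set$imfs) > 0) {
    for (j in seq_len(ncol(set$imfs))) {
      comp <- set$imfs[, j]
      if (high[j]) comp <- wpt_denoise_imf(comp, wpt, threshold_approx = TRUE)
      out <- out + comp
    }
  }
  list(signal = out, imf_set = set, high = high)
}

#' EMD partial-reconstruction denoising baseline
#'
#' Plain EMD followed by discarding the high-frequency IMFs (same split rule
#' as [ceemdan_wpt_denoise()]); the classical EMD denoising comparator.
#'
#' @inheritParams ceemdan_wpt_denoise
#' @return Denoised signal.
#' @export
emd_denoise <- function(x, sampling_hz = 10, edge_hz = 0.2) {
  set <- emd_decompose(x)
  high <- split_imfs(set, sampling_hz, edge_hz)
  out <- set$residual
  if (ncol(set$imfs) > 0 && any(!high)) {
    out <- out + rowSums(set$imfs[, !high, drop = FALSE])
  }
  out
}

#' Signal-to-noise ratio in dB
#'
#' `SNR = 10 log10( sum(x^2) / sum((x - y)^2) )` with `x` the reference
#' (original/clean) signal and `y` the signal under evaluation.
#'
#' @param x Reference signal (not all zero).
#' @param y Comparison signal, same length.
#' @return SNR in dB.
#' @export
snr <- function(x, y) {
  assert_that(length(x) == length(y), "signals must have equal length")
  ex <- sum(x^2)
  assert_that(ex > 0, "reference signal has zero energy")
  ed <- sum((x - y)^2)
  if (ed == 0) stop("signals are identical: SNR is infinite", call. = FALSE)
  10 * log10(ex / ed)
}

#' Root-mean-square error
#'
#' `RMSE = sqrt( mean( (x - y)^2 ) )`.
#'
#' @param x,y Signals of equal length (>= 1).
#' @return RMSE in signal units.
#' @export
rmse <- function(x, y) {
  assert_that(length(x) == length(y), "signals must have equal length")
  assert_that(length(x) >= 1, "signals must be non-empty")
  sqrt(mean((x - y)^2))
}

#' Benchmark denoising methods on synthetic fixtures
#'
#' Runs each method on the noisy recordings of a set of synthetic subjects and
#' scores it against the known clean ground truth: per-fixture SNR of the
#' denoised signal versus the clean reference (`snr_vs_clean`), SNR versus the
#' noisy input (`snr_vs_input`), and RMSE versus clean. One channel's HbO trace
#' per fixture is used.
#'
#' @param fixtures List of `synthetic_subject`s (e.g. a [simulate_cohort()]).
#' @param methods Character subset of `c("none", "emd", "wavelet", "ceemdan_wpt")`.
#' @param ceemdan,wpt Configs forwarded to the methods.
#' @param channel Channel index to score (default 1).
#' @return A data.frame with one row per fixture x method and a `summary`
#'   attribute of per-method medians.
#' @export
benchmark_denoisers <- function(fixtures,
                                methods = c("none", "emd", "wavelet", "ceemdan_wpt"),
                                ceemdan = ceemdan_config(), wpt = wpt_config(),
                                channel = 1) {
  assert_that(length(fixtures) > 0, "fixture set is empty")
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (f in seq_along(fixtures)) {
    sub <- fixtures[[f]]
    assert_that(inherits(sub, "synthetic_subject"), "fixtures must be synthetic subjects")
    fs <- sub$recording$sampling_hz
    noisy <- sub$recording$hbo[, channel]
    clean <- sub$ground_truth$hbo[, channel]
    for (m in methods) {
      cfg <- ceemdan
      cfg$seed <- cfg$seed + f  # independent noise ensemble per fixture
      den <- switch(m,
        none = noisy,
        emd = emd_denoise(noisy, fs),
        wavelet = wpt_denoise_imf(noisy, wpt),
        ceemdan_wpt = ceemdan_wpt_denoise(noisy, cfg, wpt, fs)$signal
      )
      rows[[length(rows) + 1]] <- data.frame(
        fixture = f, method = m,
        snr_vs_clean = snr(clean, den),
        snr_vs_input = if (identical(den, noisy)) NA_real_ else snr(noisy, den),
        rmse = rmse(clean, den)
      )
    }
  }
  out <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(out, out$method), function(d) {
    data.frame(method = d$method[1],
               median_snr_vs_clean = stats::median(d$snr_vs_clean),
               median_rmse = stats::median(d$rmse))
  }))
  attr(out, "summary") <- summ[order(match(summ$method, methods)), ]
  out
}
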