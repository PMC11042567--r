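#' Optical recording container
#'
#' Raw optical-density change (or intensity) per channel at two wavelengths
#' (nominal 659 and 830 nm), with source-detector geometry needed by the
#' modified Beer-Lambert conversion.
#'
#' @param od_short,od_long Matrices (samples x channels) of optical-density
#'   change at the shorter and longer wavelength.
#' @param sampling_hz Sampling rate in Hz.
#' @param distance_cm Source-detector separation in cm (default 3.0).
#' @param channel_ids Optional channel labels.
#' @return An object of class `optical_recording`.
#' @export
optical_recording <- function(od_short, od_long, sampling_hz, distance_cm = 3.0,
                              channel_ids = NULL) {
  od_short <- as.matrix(od_short); od_long <- as.matrix(od_long)
  assert_that(all(dim(od_short) == dim(od_long)), "wavelength blocks must share dimensions")
  assert_that(is_number(sampling_hz) && sampling_hz > 0, "sampling_hz must be positive")
  assert_that(is_number(distance_cm) && distance_cm > 0, "distance_cm must be positive")
  if (is.null(channel_ids)) channel_ids <- sprintf("ch%02d", seq_len(ncol(od_short)))
  structure(list(od_short = od_short, od_long = od_long, sampling_hz = sampling_hz,
                 distance_cm = distance_cm, channel_ids = channel_ids),
            class = "optical_recording")
}

#' Default extinction coefficient table
#'
#' Molar extinction coefficients (1/(mM*cm)) of HbO and HbR at the two nominal
#' wavelengths, rows = wavelengths (short, long), columns = (HbO, HbR). Values
#' are the widely used compiled in-vitro coefficients for 660/830 nm; any
#' published table may be substituted, and the one used is recorded in run
#' manifests.
#'
#' @return A 2x2 numeric matrix.
#' @export
default_extinction <- function() {
  matrix(c(0.32, 3.227,   # 660 nm: HbO, HbR
           1.058, 0.74),  # 830 nm: HbO, HbR
         nrow = 2, byrow = TRUE,
         dimnames = list(c("short", "long"), c("HbO", "HbR")))
}

#' Modified Beer-Lambert conversion to hemoglobin concentration changes
#'
#' Solves, per sample and channel, the 2x2 linear system
#' `dOD_lambda = d * DPF_lambda * (eps_HbO,lambda * dHbO + eps_HbR,lambda * dHbR)`
#' for the concentration changes.
#'
#' @param optical An [optical_recording()].
#' @param dpf Differential pathlength factors, length 2 (short, long
#'   wavelength); defaults 6.0 and 5.0.
#' @param extinction 2x2 extinction matrix as in [default_extinction()].
#' @param paradigm Optional [task_paradigm()] to attach.
#' @return A [hemo_recording()] in mM units (scaled by the chosen table).
#' @export
od_to_hemoglobin <- function(optical, dpf = c(6.0, 5.0),
                             extinction = default_extinction(),
                             paradigm = NULL) {
  assert_that(inherits(optical, "optical_recording"), "optical must be an optical_recording")
  assert_that(length(dpf) == 2 && all(dpf > 0), "dpf must be two positive factors")
  A <- extinction * (optical$distance_cm * dpf) # row-wise scaling: row i by d*dpf[i]
  if (abs(det(A)) < .Machine$double.eps * 100) {
    stop("extinction matrix is singular; cannot separate HbO from HbR", call. = FALSE)
  }
  Ainv <- solve(A)
  n <- nrow(optical$od_short); nc <- ncol(optical$od_short)
  hbo <- matrix(0, n, nc); hbr <- matrix(0, n, nc)
  for (ch in seq_len(nc)) {
    od <- rbind(optical$od_short[, ch], optical$od_long[, ch])
    hb <- Ainv %*% od
    hbo[, ch] <- hb[1, ]; hbr[, ch] <- hb[2, ]
  }
  hemo_recording(hbo, hbr, optical$sampling_hz, paradigm = paradigm,
                 channel_ids = optical$channel_ids, units = "mM")
}

#' Polynomial detrending
#'
#' Fits a least-squares polynomial of the given order to the signal and
#' returns the residual, removing linear or slow nonlinear baseline trends.
#'
#' @param x Numeric signal.
#' @param order Polynomial order (>= 0); default 3.
#' @return Detrended signal, same length.
#' @export
detrend_poly <- function(x, order = 3) {
  assert_that(is_count(order), "order must be a non-negative integer")
  n <- length(x)
  assert_that(n > order, "signal must be longer than the polynomial order")
  t <- seq_len(n) / n
  X <- stats::poly(t, degree = max(order, 1), raw = FALSE)
  if (order == 0) return(x - mean(x))
  fit <- stats::lm.fit(cbind(1, X[, seq_len(order), drop = FALSE]), x)
  as.numeric(fit$residuals)
}

#' Temporal derivative distribution repair (TDDR) motion correction
#'
#' Robust iteratively reweighted (Tukey biweight) estimation applied to the
#' temporal derivative of the low-frequency part of the signal, followed by
#' reintegration; the high-frequency part (above 0.5 Hz) is split off before
#' correction and added back unchanged, so genuine fast content is preserved.
#' Spike and step (baseline shift) artifacts produce derivative outliers that
#' receive near-zero weight and are suppressed.
#'
#' @param x Numeric signal.
#' @param sampling_hz Sampling rate in Hz.
#' @param tune Tukey biweight tuning constant (default 4.685).
#' @param tol Convergence tolerance on the weighted estimate (default 1e-9).
#' @param max_iter Maximum reweighting iterations (default 50).
#' @return Motion-corrected signal, same length.
#' @export
tddr_correct <- function(x, sampling_hz, tune = 4.685, tol = 1e-9, max_iter = 50) {
  n <- length(x)
  assert_that(n >= 3, "signal too short for TDDR")
  assert_that(is_number(sampling_hz) && sampling_hz > 0, "sampling_hz must be positive")
  if (stats::sd(x) == 0) return(x)
  mu <- mean(x)
  xc <- x - mu
  # Split: correct only the low-frequency part (below 0.5 Hz).
  if (sampling_hz / 2 > 0.5) {
    bf <- signal::butter(3, 0.5 / (sampling_hz / 2), type = "low")
    x_low <- signal::filtfilt(bf, xc)
  } else {
    x_low <- xc
  }
  x_high <- xc - x_low
  d <- diff(x_low)
  w <- rep(1, length(d))
  mu_d <- 0
  for (iter in seq_len(max_iter)) {
    mu_new <- sum(w * d) / sum(w)
    dev <- d - mu_new
    s <- 1.4826 * stats::median(abs(dev))
    if (s == 0) { mu_d <- mu_new; break }
    r <- dev / (tune * s)
    w <- ifelse(abs(r) < 1, (1 - r^2)^2, 0)
    if (sum(w) == 0) { w <- rep(1, length(d)); mu_d <- mu_new; break }
    if (abs(mu_new - mu_d) < tol) { mu_d <- mu_new; break }
    mu_d <- mu_new
  }
  d_corr <- w * (d - mu_d)
  x_low_corr <- cumsum(c(0, d_corr))
  x_low_corr <- x_low_corr - mean(x_low_corr)
  x_low_corr + x_high + mu
}

#' Band filter specification (Chebyshev type II)
#'
#' The physiological-noise filter: a third-order Chebyshev type II low-pass
#' with stopband edge 0.2 Hz (suppressing respiration at 0.2-0.4 Hz and
#' cardiac pulsation at 0.5-2.0 Hz), applied forward-backward (zero phase).
#' Drift below the 0.01 Hz cutoff is handled by polynomial detrending; a
#' Chebyshev type II high-pass section can be enabled instead
#' (`highpass = TRUE`), but a task block of 60 s in a 120 s recording has its
#' fundamental near 0.008 Hz, which such a high-pass attenuates, so it is off
#' by default.
#'
#' @param passband_edge High-pass passband edge in Hz (default 0.01; used only
#'   when `highpass = TRUE`).
#' @param stopband_edge Low-pass stopband edge in Hz (default 0.2).
#' @param stopband_atten_db Stopband attenuation in dB (default 30).
#' @param highpass Enable the high-pass section (default FALSE).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(passband_edge = 0.01, stopband_edge = 0.2,
                        stopband_atten_db = 30, highpass = FALSE) {
  assert_that(is_number(passband_edge) && passband_edge > 0, "passband_edge must be > 0")
  assert_that(passband_edge < stopband_edge, "passband_edge must be below stopband_edge")
  assert_that(stopband_atten_db > 0, "attenuation must be positive")
  structure(list(order = 3, passband_edge = passband_edge,
                 stopband_edge = stopband_edge,
                 stopband_atten_db = stopband_atten_db,
                 highpass = isTRUE(highpass)),
            class = "filter_spec")
}

#' Zero-phase Chebyshev type II band filtering
#'
#' @param x Numeric signal.
#' @param spec A [filter_spec()].
#' @param sampling_hz Sampling rate in Hz.
#' @return Filtered signal, same length.
#' @export
bandpass_filter <- function(x, spec = filter_spec(), sampling_hz = 10) {
  assert_that(inherits(spec, "filter_spec"), "spec must be a filter_spec()")
  nyq <- sampling_hz / 2
  assert_that(spec$stopband_edge < nyq, "stopband edge must be below Nyquist")
  lp <- signal::cheby2(spec$order, spec$stopband_atten_db, spec$stopband_edge / nyq,
                       type = "low")
  y <- signal::filtfilt(lp, x)
  if (spec$highpass) {
    # stopband placed an octave under the passband edge
    hp_stop <- spec$passband_edge / 2
    if (hp_stop / nyq > 1e-6) {
      hp <- signal::cheby2(spec$order, spec$stopband_atten_db, hp_stop / nyq,
                           type = "high")
      y <- signal::filtfilt(hp, y)
    }
  }
  y
}

#' Full preprocessing of a recording
#'
#' Applies, per channel and species, the fixed pipeline: polynomial detrend,
#' TDDR motion correction, zero-phase Chebyshev type II band filtering. (When
#' starting from optical densities, run [od_to_hemoglobin()] first.)
#'
#' @param recording A [hemo_recording()].
#' @param detrend_order Polynomial order for detrending (default 3).
#' @param filter A [filter_spec()]; `NULL` skips filtering.
#' @param tddr Logical, run TDDR (default TRUE).
#' @return A preprocessed [hemo_recording()].
#' @export
preprocess_recording <- function(recording, detrend_order = 3,
                                 filter = filter_spec(), tddr = TRUE) {
  assert_that(inherits(recording, "hemo_recording"), "recording must be a hemo_recording")
  fs <- recording$sampling_hz
  clean1 <- function(x) {
    x <- detrend_poly(x, detrend_order)
    if (tddr) x <- tddr_correct(x, fs)
    if (!is.null(filter)) x <- bandpass_filter(x, filter, fs)
    x
  }
  hbo <- apply(recording$hbo, 2, clean1)
  hbr <- apply(recording$hbr, 2, clean1)
  hemo_recording(hbo, hbr, fs, paradigm = recording$paradigm,
                 channel_ids = recording$channel_ids, units = recording$units)
}
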