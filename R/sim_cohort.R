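#' Block-design task paradigm
#'
#' Describes the verbal-fluency-style block paradigm: a pre-task rest, a task
#' block, and a post-task rest, sampled at a fixed rate. The default 30/60/30 s
#' at 10 Hz gives 1200 samples per recording.
#'
#' @param pre_rest_s Pre-task rest duration in seconds.
#' @param task_s Task block duration in seconds.
#' @param post_rest_s Post-task rest duration in seconds.
#' @param sampling_hz Sampling rate in Hz.
#' @return An object of class `task_paradigm`.
#' @export
task_paradigm <- function(pre_rest_s = 30, task_s = 60, post_rest_s = 30,
                          sampling_hz = 10) {
  for (v in list(pre_rest_s, task_s, post_rest_s, sampling_hz)) {
    assert_that(is_number(v) && v > 0, "all paradigm durations and the sampling rate must be positive numbers")
  }
  structure(
    list(pre_rest_s = pre_rest_s, task_s = task_s, post_rest_s = post_rest_s,
         sampling_hz = sampling_hz),
    class = "task_paradigm"
  )
}

#' @export
print.task_paradigm <- function(x, ...) {
  cat(sprintf("Task paradigm: %g s rest / %g s task / %g s rest @ %g Hz (%d samples)\n",
              x$pre_rest_s, x$task_s, x$post_rest_s, x$sampling_hz, n_samples(x)))
  invisible(x)
}

#' Number of samples implied by a paradigm
#' @param paradigm A [task_paradigm()].
#' @return Integer sample count.
#' @export
n_samples <- function(paradigm) {
  as.integer(round((paradigm$pre_rest_s + paradigm$task_s + paradigm$post_rest_s) *
                     paradigm$sampling_hz))
}

#' Task-window sample indices
#'
#' Half-open window \[start, end) in samples, returned as the 1-based index
#' vector of samples falling inside the task block.
#'
#' @param paradigm A [task_paradigm()].
#' @return Integer vector of sample indices.
#' @export
task_window <- function(paradigm) {
  fs <- paradigm$sampling_hz
  start <- as.integer(round(paradigm$pre_rest_s * fs))       # 0-based start
  end <- as.integer(round((paradigm$pre_rest_s + paradigm$task_s) * fs)) # 0-based end (excl.)
  seq.int(start + 1L, end)
}

#' Physiological and instrumental noise profile
#'
#' Component amplitudes for the synthetic recording generator. Frequencies are
#' drawn per subject from the given bands: respiration 0.2-0.4 Hz and cardiac
#' pulsation 0.5-2.0 Hz, the bands the band filter is designed to suppress.
#' Amplitudes are in the same (arbitrary micromolar) units as the hemodynamic
#' response, whose group-mean peak is 1.
#'
#' @param cardiac_band Two-element Hz range for the cardiac oscillation.
#' @param cardiac_amp Cardiac amplitude.
#' @param resp_band Two-element Hz range for respiration.
#' @param resp_amp Respiration amplitude.
#' @param drift_amp Scale of the slow polynomial baseline drift (total excursion
#'   over the recording is of this order).
#' @param white_sd Standard deviation of white measurement noise.
#' @param artifact_rate Expected number of motion artifacts per recording
#'   (Poisson-placed; spikes and baseline shifts in equal proportion).
#' @param spike_amp Typical spike amplitude.
#' @param shift_amp Typical baseline-shift amplitude.
#' @return An object of class `noise_profile`.
#' @export
noise_profile <- function(cardiac_band = c(0.8, 1.5), cardiac_amp = 0.3,
                          resp_band = c(0.2, 0.4), resp_amp = 0.4,
                          drift_amp = 0.5, white_sd = 0.2,
                          artifact_rate = 2, spike_amp = 2, shift_amp = 1) {
  assert_that(length(cardiac_band) == 2 && all(cardiac_band >= 0.5) && all(cardiac_band <= 2.0),
              "cardiac_band must lie within 0.5-2.0 Hz")
  assert_that(length(resp_band) == 2 && all(resp_band >= 0.2) && all(resp_band <= 0.4),
              "resp_band must lie within 0.2-0.4 Hz")
  amps <- c(cardiac_amp, resp_amp, drift_amp, white_sd, artifact_rate, spike_amp, shift_amp)
  assert_that(all(is.finite(amps)) && all(amps >= 0), "noise amplitudes must be non-negative")
  structure(
    list(cardiac_band = cardiac_band, cardiac_amp = cardiac_amp,
         resp_band = resp_band, resp_amp = resp_amp,
         drift_amp = drift_amp, white_sd = white_sd,
         artifact_rate = artifact_rate, spike_amp = spike_amp,
         shift_amp = shift_amp),
    class = "noise_profile"
  )
}

#' Zero-noise profile (recordings equal their clean ground truth)
#' @return A `noise_profile` with every amplitude zero.
#' @export
noise_profile_zero <- function() {
  noise_profile(cardiac_amp = 0, resp_amp = 0, drift_amp = 0, white_sd = 0,
                artifact_rate = 0, spike_amp = 0, shift_amp = 0)
}

#' Synthetic cohort specification
#'
#' Defaults mirror the study population this generator emulates: 82 severe and
#' 58 mild first-episode depression patients, 18 prefrontal channels.
#' `effect_size` is the standardized difference (in units of the
#' between-subject amplitude SD) in task-evoked response amplitude between the
#' mild and severe groups; the mild group is the more activated one.
#'
#' @param n_severe,n_mild Group sizes.
#' @param n_channels Number of channels (>= 2).
#' @param effect_size Standardized mild-minus-severe amplitude difference.
#' @param base_amplitude Grand-mean peak response amplitude.
#' @param amplitude_sd Between-subject SD of the response amplitude.
#' @param channel_jitter_sd SD of the per-channel multiplicative amplitude
#'   jitter around the subject amplitude.
#' @param hbr_ratio Scaling from clean HbO to clean HbR (negative).
#' @param hbr_lag_s Lag of HbR behind HbO in seconds.
#' @param noise A [noise_profile()].
#' @param seed Integer master seed; all randomness derives from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_severe = 82, n_mild = 58, n_channels = 18,
                        effect_size = 1.0, base_amplitude = 1.0,
                        amplitude_sd = 0.3, channel_jitter_sd = 0.1,
                        hbr_ratio = -1 / 3, hbr_lag_s = 1,
                        noise = noise_profile(), seed = 1L) {
  assert_that(is_count(n_severe) && is_count(n_mild), "group sizes must be non-negative integers")
  assert_that(is_count(n_channels, min = 2L), "n_channels must be an integer >= 2")
  assert_that(is_number(effect_size), "effect_size must be a finite number")
  assert_that(is_number(base_amplitude) && base_amplitude >= 0,
              "base_amplitude must be non-negative")
  assert_that(is_number(amplitude_sd) && amplitude_sd >= 0, "amplitude_sd must be non-negative")
  assert_that(inherits(noise, "noise_profile"), "noise must be a noise_profile()")
  assert_that(is_count(seed, min = 0L), "seed must be a non-negative integer")
  structure(
    list(n_severe = n_severe, n_mild = n_mild, n_channels = n_channels,
         effect_size = effect_size, base_amplitude = base_amplitude,
         amplitude_sd = amplitude_sd, channel_jitter_sd = channel_jitter_sd,
         hbr_ratio = hbr_ratio, hbr_lag_s = hbr_lag_s, noise = noise,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style double gamma: peak near 6 s, undershoot near 16 s, undershoot
#' ratio 1/6. Used both to synthesize responses and as the task regressor of
#' the activation GLM.
#'
#' @param t Time points in seconds (>= 0).
#' @return HRF values (unnormalized).
#' @export
canonical_hrf <- function(t) {
  stopifnot(all(t >= 0))
  a1 <- 6; a2 <- 16; b <- 1; c <- 1 / 6
  stats::dgamma(t, shape = a1, rate = b) - c * stats::dgamma(t, shape = a2, rate = b)
}

#' Task regressor: boxcar convolved with the canonical HRF
#'
#' The task-block boxcar is convolved with [canonical_hrf()] and scaled to a
#' peak of 1, so a subject with response amplitude `a` has a clean response of
#' peak amplitude `a`.
#'
#' @param paradigm A [task_paradigm()].
#' @return Numeric vector of length `n_samples(paradigm)`.
#' @export
task_regressor <- function(paradigm) {
  n <- n_samples(paradigm)
  fs <- paradigm$sampling_hz
  box <- numeric(n)
  box[task_window(paradigm)] <- 1
  hrf_t <- seq(0, 32, by = 1 / fs)
  h <- canonical_hrf(hrf_t)
  reg <- stats::convolve(box, rev(h), type = "open")[seq_len(n)] / fs
  reg / max(abs(reg))
}

lag_signal <- function(x, k) {
  n <- length(x)
  if (k <= 0) return(x)
  c(rep(0, k), x[seq_len(n - k)])
}

smoothed_spike <- function(n, center, width_samples, amp) {
  t <- seq_len(n)
  amp * exp(-0.5 * ((t - center) / (width_samples / 2))^2)
}

simulate_channel_noise <- function(n, fs, np, scale = 1) {
  t <- (seq_len(n) - 1) / fs
  out <- numeric(n)
  if (np$cardiac_amp > 0) {
    f <- stats::runif(1, np$cardiac_band[1], np$cardiac_band[2])
    out <- out + scale * np$cardiac_amp * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
  }
  if (np$resp_amp > 0) {
    f <- stats::runif(1, np$resp_band[1], np$resp_band[2])
    out <- out + scale * np$resp_amp * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
  }
  if (np$drift_amp > 0) {
    u <- t / max(t)
    out <- out + scale * np$drift_amp * (stats::rnorm(1) * u + stats::rnorm(1) * u^2)
  }
  if (np$white_sd > 0) out <- out + scale * np$white_sd * stats::rnorm(n)
  if (np$artifact_rate > 0) {
    k <- stats::rpois(1, np$artifact_rate)
    if (k > 0) {
      for (i in seq_len(k)) {
        pos <- sample.int(n, 1)
        if (stats::runif(1) < 0.5 && np$spike_amp > 0) {
          amp <- scale * np$spike_amp * sample(c(-1, 1), 1) * (0.5 + abs(stats::rnorm(1)))
          out <- out + smoothed_spike(n, pos, width_samples = round(0.5 * fs), amp = amp)
        } else if (np$shift_amp > 0) {
          amp <- scale * np$shift_amp * sample(c(-1, 1), 1) * (0.5 + stats::runif(1))
          out[pos:n] <- out[pos:n] + amp
        }
      }
    }
  }
  out
}

#' Simulate one subject's recording
#'
#' Clean per-channel HbO is the task regressor scaled by a subject-level
#' amplitude (group mean shifted by `effect_size`, mild above severe) with
#' multiplicative per-channel jitter; clean HbR is a negatively scaled, lagged
#' copy. Physiological noise (cardiac, respiration with per-channel phase),
#' slow drift, white noise and Poisson-placed spike/shift motion artifacts are
#' added on top. The noise-free traces are kept as ground truth.
#'
#' @param spec A [cohort_spec()].
#' @param label `"mild"` or `"severe"`.
#' @param paradigm A [task_paradigm()].
#' @param seed Integer seed for this subject.
#' @return An object of class `synthetic_subject`: list with `label`,
#'   `recording` and `ground_truth` (both [hemo_recording()]).
#' @export
simulate_recording <- function(spec, label = c("severe", "mild"),
                               paradigm = task_paradigm(), seed = 1L) {
  label <- match.arg(label)
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec()")
  assert_that(inherits(paradigm, "task_paradigm"), "paradigm must be a task_paradigm()")
  n <- n_samples(paradigm)
  assert_that(n > 0, "paradigm implies zero samples")
  fs <- paradigm$sampling_hz
  nc <- spec$n_channels
  with_seed(seed, {
    shift <- spec$effect_size * spec$amplitude_sd / 2
    mu <- spec$base_amplitude + if (label == "mild") shift else -shift
    amp <- stats::rnorm(1, mu, spec$amplitude_sd)
    reg <- task_regressor(paradigm)
    jit <- pmax(0.05, stats::rnorm(nc, 1, spec$channel_jitter_sd))
    hbo_clean <- outer(reg, amp * jit)
    lag_k <- as.integer(round(spec$hbr_lag_s * fs))
    hbr_clean <- apply(hbo_clean, 2, lag_signal, k = lag_k) * spec$hbr_ratio
    hbo <- hbo_clean
    hbr <- hbr_clean
    for (ch in seq_len(nc)) {
      hbo[, ch] <- hbo[, ch] + simulate_channel_noise(n, fs, spec$noise, scale = 1)
      hbr[, ch] <- hbr[, ch] + simulate_channel_noise(n, fs, spec$noise,
                                                      scale = abs(spec$hbr_ratio))
    }
    ids <- sprintf("ch%02d", seq_len(nc))
    structure(
      list(label = label,
           recording = hemo_recording(hbo, hbr, fs, paradigm, channel_ids = ids),
           ground_truth = hemo_recording(hbo_clean, hbr_clean, fs, paradigm,
                                         channel_ids = ids)),
      class = "synthetic_subject"
    )
  })
}

#' Simulate a full synthetic cohort
#'
#' Generates `n_severe + n_mild` subjects (severe first), each from a sub-seed
#' derived from `spec$seed`, so the whole cohort is reproducible from one
#' integer.
#'
#' @param spec A [cohort_spec()].
#' @param paradigm A [task_paradigm()].
#' @return An object of class `fnirs_cohort`: list of `synthetic_subject`s
#'   with a `labels` attribute.
#' @export
simulate_cohort <- function(spec, paradigm = task_paradigm()) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec()")
  n_total <- spec$n_severe + spec$n_mild
  labels <- c(rep("severe", spec$n_severe), rep("mild", spec$n_mild))
  if (n_total == 0) {
    return(structure(list(), labels = character(0), class = "fnirs_cohort"))
  }
  seeds <- derive_seeds(spec$seed, n_total)
  subjects <- lapply(seq_len(n_total), function(i) {
    simulate_recording(spec, label = labels[i], paradigm = paradigm, seed = seeds[i])
  })
  structure(subjects, labels = labels, class = "fnirs_cohort")
}

#' Cohort labels
#' @param cohort An `fnirs_cohort`.
#' @return Character vector of per-subject labels.
#' @export
cohort_labels <- function(cohort) {
  attr(cohort, "labels")
}

#' @export
print.fnirs_cohort <- function(x, ...) {
  lab <- cohort_labels(x)
  cat(sprintf("Synthetic fNIRS cohort: %d subjects (%d severe, %d mild)\n",
              length(x), sum(lab == "severe"), sum(lab == "mild")))
  invisible(x)
}
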