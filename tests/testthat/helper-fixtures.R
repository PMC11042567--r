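# Shared fixture builders. Everything is generated in code at test time.

quiet_cohort <- function(n_severe = 2, n_mild = 2, n_channels = 2, seed = 1,
                         effect_size = 1, ...) {
  simulate_cohort(cohort_spec(n_severe = n_severe, n_mild = n_mild,
                              n_channels = n_channels, effect_size = effect_size,
                              seed = seed, ...))
}

# A two-class feature table with `n_signal` informative columns (group mean
# shift `delta` in SD units) and `n_noise` pure-noise columns.
planted_table <- function(n_per_class = 30, n_signal = 3, n_noise = 17,
                          delta = 2, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    y <- rep(c("mild", "severe"), each = n_per_class)
    x <- matrix(stats::rnorm(n * (n_signal + n_noise)), n)
    if (n_signal > 0) {
      x[y == "severe", seq_len(n_signal)] <- x[y == "severe", seq_len(n_signal)] + delta
    }
    colnames(x) <- c(sprintf("sig%02d", seq_len(n_signal)),
                     sprintf("noise%02d", seq_len(n_noise)))[seq_len(ncol(x))]
    feature_table(x, y)
  })
}

tone <- function(freq_hz, dur_s = 60, fs = 10, phase = 0) {
  t <- seq(1 / fs, dur_s, by = 1 / fs)
  sin(2 * pi * freq_hz * t + phase)
}
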