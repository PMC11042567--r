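test_that("Beer-Lambert conversion inverts the forward optical model", {
  # zero optical density -> zero concentrations
  opt0 <- optical_recording(matrix(0, 10, 2), matrix(0, 10, 2), 10)
  h0 <- od_to_hemoglobin(opt0)
  expect_true(all(h0$hbo == 0) && all(h0$hbr == 0))
  # identity extinction, unit pathlength: dHb == dOD
  withr::with_seed(1, {
    od_s <- matrix(rnorm(20), 10); od_l <- matrix(rnorm(20), 10)
  })
  opt <- optical_recording(od_s, od_l, 10, distance_cm = 1)
  h <- od_to_hemoglobin(opt, dpf = c(1, 1), extinction = diag(2))
  expect_equal(h$hbo, od_s, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(h$hbr, od_l, tolerance = 1e-12, ignore_attr = TRUE)
  # random system: agree with a direct 2x2 solve
  opt <- optical_recording(od_s, od_l, 10)
  h <- od_to_hemoglobin(opt)
  A <- default_extinction() * (3.0 * c(6, 5))
  ref <- solve(A, rbind(od_s[4, 2], od_l[4, 2]))
  expect_equal(unname(c(h$hbo[4, 2], h$hbr[4, 2])), as.numeric(ref),
               tolerance = 1e-12)
  expect_error(od_to_hemoglobin(opt, extinction = matrix(1, 2, 2)), "singular")
})

test_that("polynomial detrending removes trends and preserves oscillations", {
  ramp <- seq(-2, 5, length.out = 500)
  expect_lt(max(abs(detrend_poly(ramp, 1))), 1e-10)
  expect_equal(mean(detrend_poly(rep(3, 400), 0)), 0)
  t <- seq_len(8000) / 100
  sine <- sin(2 * pi * 1.3 * t)
  mixed <- sine + 0.5 * t^3 - 2 * t^2 + t
  expect_gt(cor(detrend_poly(mixed, 3), sine), 0.999)
  expect_error(detrend_poly(1:3, 5), "longer")
})

test_that("TDDR repairs steps and spikes and passes smooth signals", {
  fs <- 10
  t <- seq(1 / fs, 120, by = 1 / fs)
  clean <- sin(2 * pi * 0.02 * t)
  passed <- tddr_correct(clean, fs)
  expect_gt(cor(passed, clean), 0.97)   # shape preserved up to mild shrinkage
  expect_lt(max(abs(passed - clean)) / diff(range(clean)), 0.2)
  expect_identical(tddr_correct(rep(2, 100), fs), rep(2, 100))
  # step offset: sustained shift reduced by >= 90%
  stepped <- clean
  stepped[600:length(t)] <- stepped[600:length(t)] + 5
  rep_ <- tddr_correct(stepped, fs)
  offset <- function(x) abs(mean(x[650:800]) - mean(x[400:550]) -
                              (mean(clean[650:800]) - mean(clean[400:550])))
  expect_lt(offset(rep_), 0.1 * offset(stepped))
  # smoothed spike: amplitude reduced, correlation with clean improves
  spiky <- clean + 6 * exp(-0.5 * ((seq_along(t) - 700) / 5)^2)
  rep2 <- tddr_correct(spiky, fs)
  expect_lt(max(abs(rep2 - clean)), 0.5 * max(abs(spiky - clean)))
  expect_gt(cor(rep2, clean), cor(spiky, clean))
})

test_that("the Chebyshev-II band filter suppresses cardiac and passes task band", {
  fs <- 10
  f <- filter_spec()
  hi <- tone(1, 120, fs)
  lo <- tone(0.05, 120, fs)
  expect_lt(rms_ratio <- sd(bandpass_filter(hi, f, fs)) / sd(hi), 0.05)
  expect_gt(sd(bandpass_filter(lo, f, fs)) / sd(lo), 0.9)
  expect_equal(bandpass_filter(rep(0, 400), f, fs), rep(0, 400))
  expect_error(bandpass_filter(lo, filter_spec(stopband_edge = 6), fs), "Nyquist")
  expect_error(filter_spec(passband_edge = 0.3, stopband_edge = 0.2), "below")
})

test_that("preprocessing preserves length, and its linear stages are re-application stable", {
  sub <- quiet_cohort(1, 0, n_channels = 2, seed = 3,
                      noise = noise_profile_zero())[[1]]
  once <- preprocess_recording(sub$recording)
  expect_equal(dim(once$hbo), dim(sub$recording$hbo))
  expect_equal(dim(once$hbr), dim(sub$recording$hbr))
  # detrending is a projection: applying it twice is a no-op
  withr::with_seed(4, x <- rnorm(800))
  d1 <- detrend_poly(x, 3)
  expect_lt(max(abs(detrend_poly(d1, 3) - d1)), 1e-10)
  # the zero-phase filter re-applied to deep-in-band content changes it < 1%
  lo <- tone(0.02, 300)
  y1 <- bandpass_filter(lo, filter_spec(), 10)
  y2 <- bandpass_filter(y1, filter_spec(), 10)
  expect_lt(sd(y2 - y1) / sd(y1), 0.01)
})
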