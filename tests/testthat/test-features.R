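test_that("temporal features match closed forms on a pure sinusoid", {
  # dense phase sampling so the sampled peak reaches the true amplitude
  x <- sin(2 * pi * 1 * seq(0.01, 60, by = 0.01))
  f <- temporal_features(x, sampling_hz = 100)
  expect_equal(unname(f["peak_factor"]), sqrt(2), tolerance = 1e-3)
  expect_equal(unname(f["skewness"]), 0, tolerance = 1e-6)
  expect_equal(unname(f["mean_square_frequency"]), 1, tolerance = 1e-3)
  expect_equal(unname(f["rectified_mean"]), 2 / pi, tolerance = 1e-3)
  # bin-aligned tone: spectral mass in one bin
  expect_lt(unname(f["power_spectral_entropy"]), 0.01)
  # sinusoid trajectory matrix has two dominant equal singular values when the
  # embedding window spans whole cycles
  expect_equal(singular_spectral_entropy(tone(1, 60, 10), 50), log(2),
               tolerance = 1e-3)
})

test_that("power spectral entropy attains its closed-form extremes", {
  expect_equal(power_spectral_entropy(c(1, rep(0, 99))), log(50), tolerance = 1e-12)
  expect_error(power_spectral_entropy(rep(1, 64)), "zero spectral energy")
  # white noise approaches the log-bin-count maximum; the exact expectation is
  # log(N_bins) - (1 - gamma) ~ 0.926 * log(300) for exponential periodogram
  # ordinates, so the observed mean sits just under the ceiling
  withr::with_seed(5, {
    h <- mean(replicate(8, power_spectral_entropy(rnorm(600))))
  })
  expect_gt(h, 0.9 * log(300))
  expect_lt(h, log(300))
  # brute-force two-pass oracle on a random vector
  withr::with_seed(6, x <- rnorm(128))
  X <- fft(x); p <- Mod(X[2:65])^2
  q <- p / sum(p)
  expect_equal(power_spectral_entropy(x), -sum(q * log(q)), tolerance = 1e-12)
})

test_that("singular spectral entropy matches an independent SVD pipeline", {
  expect_equal(singular_spectral_entropy(rep(4, 100), 20), 0, tolerance = 1e-10)
  withr::with_seed(7, x <- rnorm(80))
  L <- 15; K <- 80 - L + 1
  H <- sapply(seq_len(K), function(j) x[j:(j + L - 1)])
  lam <- svd(H)$d; q <- lam / sum(lam)
  expect_equal(singular_spectral_entropy(x, L), -sum(q * log(q)), tolerance = 1e-10)
  expect_error(singular_spectral_entropy(x, 80), "embed_len")
})

test_that("correlation features hit the hand-computed Pearson values", {
  p <- task_paradigm(pre_rest_s = 1, task_s = 1, post_rest_s = 1, sampling_hz = 3)
  withr::with_seed(8, base <- rnorm(9))
  hbo <- cbind(base, base, -base)
  hbr <- cbind(base, base + rnorm(9, sd = 2), base)
  rec <- hemo_recording(hbo, hbr, 3, p)
  cf <- correlation_features(rec)
  expect_equal(unname(cf["CF.pearson.ch01-ch02.HbO"]), 1)
  expect_equal(unname(cf["CF.pearson.ch01-ch03.HbO"]), -1)
  expect_length(cf, choose(3, 2) * 2)
  expect_true(all(cf >= -1 & cf <= 1))
  # hand-evaluated coefficient
  p2 <- task_paradigm(0.1, 0.3, 0.1, 10)
  rec2 <- hemo_recording(cbind(c(0, 1, 2, 3, 0), c(0, 1, 2, 4, 0)),
                         cbind(c(0, 1, 2, 3, 0), c(0, 1, 2, 4, 0)), 10, p2)
  cf2 <- correlation_features(rec2)
  expect_equal(unname(cf2["CF.pearson.ch01-ch02.HbO"]), 0.9819805, tolerance = 1e-6)
  # zero-variance channel yields 0 with a warning
  rec3 <- hemo_recording(cbind(base, 0 * base), cbind(base, base), 3, p)
  expect_warning(cf3 <- correlation_features(rec3), "zero-variance")
  expect_equal(unname(cf3["CF.pearson.ch01-ch02.HbO"]), 0)
})

test_that("feature table counts follow the combinatorial formulas", {
  coh18 <- quiet_cohort(2, 2, n_channels = 18, seed = 40,
                        noise = noise_profile(artifact_rate = 0))
  tf <- build_feature_table(coh18, "tf")
  cf <- build_feature_table(coh18, "cf")
  expect_equal(ncol(tf$features), 324)
  expect_equal(ncol(cf$features), 306)
  coh4 <- quiet_cohort(2, 2, n_channels = 4, seed = 41)
  both <- build_feature_table(coh4)
  expect_equal(ncol(both$features), 4 * 2 * 9 + choose(4, 2) * 2)
  expect_false(anyDuplicated(colnames(both$features)) > 0)
  # deterministic order: family, kind, channel, species
  expect_equal(colnames(both$features)[1:2],
               c("TF.maximum.ch01.HbO", "TF.maximum.ch01.HbR"))
})

test_that("features are scale-covariant or scale-invariant as required", {
  withr::with_seed(9, x <- rnorm(300) + tone(0.1, 30))
  a <- temporal_features(x)
  b <- temporal_features(3.7 * x)
  for (k in c("skewness", "peak_factor", "power_spectral_entropy",
              "singular_spectral_entropy", "mean_square_frequency")) {
    expect_equal(unname(b[k]), unname(a[k]), tolerance = 1e-9, label = k)
  }
  for (k in c("maximum", "minimum", "mean", "rectified_mean")) {
    expect_equal(unname(b[k]), 3.7 * unname(a[k]), tolerance = 1e-9, label = k)
  }
})

test_that("constant segments produce the documented sentinels", {
  expect_warning(f <- temporal_features(rep(5, 100)), "sentinel")
  expect_equal(unname(f["skewness"]), 0)
  expect_equal(unname(f["peak_factor"]), 1)
})
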