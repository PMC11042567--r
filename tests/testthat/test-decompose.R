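test_that("EMD on a monotonic ramp returns no IMFs and the input as residual", {
  x <- seq(0, 1, length.out = 100)
  s <- emd_decompose(x)
  expect_equal(ncol(s$imfs), 0)
  expect_equal(s$residual, x)
})

test_that("EMD separates a two-tone mixture with exact reconstruction", {
  x <- tone(0.05, 120) + 0.5 * tone(1, 120)
  s <- emd_decompose(x)
  expect_gt(ncol(s$imfs), 1)
  expect_gt(abs(cor(s$imfs[, 1], tone(1, 120))), 0.9)
  expect_lt(max(abs(imf_reconstruct(s) - x)), 1e-8 * sqrt(mean(x^2)))
})

test_that("CEEMDAN is deterministic, complete, and rejects bad input", {
  x <- tone(0.05, 60) + 0.3 * tone(1.1, 60)
  cfg <- ceemdan_config(ensemble_size = 10, seed = 5)
  a <- ceemdan_decompose(x, cfg)
  b <- ceemdan_decompose(x, cfg)
  expect_identical(a$imfs, b$imfs)
  expect_identical(a$residual, b$residual)
  expect_lt(max(abs(imf_reconstruct(a) - x)), 1e-8 * sqrt(mean(x^2)))
  z <- ceemdan_decompose(rep(0, 100), cfg)
  expect_equal(imf_reconstruct(z), rep(0, 100))
  expect_error(ceemdan_config(ensemble_size = 1), "ensemble_size")
  expect_error(ceemdan_decompose(c(1, NA, 3, 4, 5, 6, 7, 8), cfg), "finite")
})

test_that("CEEMDAN mode mixing is no worse than plain EMD on a noisy two-tone", {
  withr::with_seed(1, {
    x <- tone(0.05, 120) + 0.5 * tone(1, 120) + 0.3 * rnorm(1200)
  })
  best_cor <- function(set, tn) max(abs(cor(set$imfs, tn)))
  ce <- ceemdan_decompose(x, ceemdan_config(ensemble_size = 50, seed = 3))
  em <- emd_decompose(x)
  expect_gte(best_cor(ce, tone(1, 120)) + 0.02, best_cor(em, tone(1, 120)))
  expect_gte(best_cor(ce, tone(0.05, 120)) + 0.02, best_cor(em, tone(0.05, 120)))
})

test_that("wavelet packet thresholding shrinks noise and keeps smooth structure", {
  cfg <- wpt_config()
  expect_equal(wpt_denoise_imf(rep(0, 160), cfg), rep(0, 160))
  withr::with_seed(8, {
    noise_var <- replicate(5, {
      w <- rnorm(600)
      var(wpt_denoise_imf(w, cfg, threshold_approx = TRUE)) / var(w)
    })
  })
  expect_lt(median(noise_var), 0.2)
  t <- seq(0, 1, length.out = 600)
  smooth <- 1 + 2 * t - 1.5 * t^2
  den <- wpt_denoise_imf(smooth, cfg)
  expect_lt(sqrt(mean((den - smooth)^2)) / sqrt(mean(smooth^2)), 0.05)
  expect_error(wpt_denoise_imf(rnorm(16), wpt_config(level = 5)), "level too deep")
})

test_that("the IMF split rule finds high- and low-frequency groups on task-like data", {
  sub <- quiet_cohort(1, 0, seed = 31)[[1]]
  res <- ceemdan_wpt_denoise(sub$recording$hbo[, 1],
                             ceemdan_config(ensemble_size = 20, seed = 2),
                             sampling_hz = 10)
  expect_gt(sum(res$high), 0)
  expect_gt(sum(!res$high), 0)
})

test_that("denoising leaves a noise-free smooth signal nearly unchanged", {
  reg <- task_regressor(task_paradigm())
  res <- ceemdan_wpt_denoise(reg, ceemdan_config(ensemble_size = 20, seed = 4),
                             sampling_hz = 10)
  expect_lt(sqrt(mean((res$signal - reg)^2)) / sqrt(mean(reg^2)), 0.05)
})

test_that("denoising improves SNR against the clean reference on a noisy mixture", {
  sub <- quiet_cohort(1, 0, seed = 17)[[1]]
  noisy <- sub$recording$hbo[, 1]
  clean <- sub$ground_truth$hbo[, 1]
  den <- ceemdan_wpt_denoise(noisy, ceemdan_config(ensemble_size = 30, seed = 6),
                             sampling_hz = 10)$signal
  expect_gt(snr(clean, den), snr(clean, noisy))
})

test_that("snr and rmse match closed forms and reject degenerate input", {
  withr::with_seed(2, x <- rnorm(100))
  expect_equal(snr(x, 0.5 * x), 10 * log10(4), tolerance = 1e-12)
  expect_equal(snr(x, numeric(100)), 0, tolerance = 1e-12)
  expect_error(snr(x, x), "identical")
  expect_error(snr(numeric(10), rnorm(10)), "zero energy")
  expect_equal(rmse(x, x), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2), tolerance = 1e-12)
  expect_equal(rmse(x, 2 * x), rmse(2 * x, x))
  # independent one-line oracles on random vectors
  withr::with_seed(3, y <- rnorm(100))
  expect_equal(snr(x, y), 10 * log10(sum(x^2) / sum((x - y)^2)), tolerance = 1e-12)
  expect_equal(rmse(x, y), sqrt(sum((x - y)^2) / 100), tolerance = 1e-12)
})

test_that("noise-free fixtures give near-zero RMSE for every method", {
  coh <- quiet_cohort(1, 1, seed = 12, noise = noise_profile_zero())
  b <- benchmark_denoisers(coh, methods = c("emd", "wavelet", "ceemdan_wpt"),
                           ceemdan = ceemdan_config(ensemble_size = 10, seed = 2))
  peak <- max(abs(coh[[1]]$ground_truth$hbo[, 1]))
  expect_lt(max(b$rmse), 0.05 * peak)
})
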