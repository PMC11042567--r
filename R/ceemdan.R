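#' CEEMDAN configuration
#'
#' @param ensemble_size Number of noise realizations I (>= 2; default 100).
#' @param noise_scale Added-noise amplitude as a fraction of the running
#'   residual's standard deviation (default 0.2).
#' @param sift_stop Standard-deviation sifting stop threshold (default 0.2).
#' @param max_sift Maximum sifting iterations per mode (default 10).
#' @param max_imfs Safety cap on the number of modes (default 16).
#' @param seed Integer seed for the noise ensemble.
#' @return An object of class `ceemdan_config`.
#' @export
ceemdan_config <- function(ensemble_size = 100, noise_scale = 0.2,
                           sift_stop = 0.2, max_sift = 10, max_imfs = 16,
                           seed = 1L) {
  assert_that(is_count(ensemble_size, min = 2L), "ensemble_size must be an integer >= 2")
  assert_that(is_number(noise_scale) && noise_scale > 0, "noise_scale must be > 0")
  structure(list(ensemble_size = as.integer(ensemble_size),
                 noise_scale = noise_scale, sift_stop = sift_stop,
                 max_sift = max_sift, max_imfs = max_imfs,
                 seed = as.integer(seed)),
            class = "ceemdan_config")
}

#' Complete ensemble EMD with adaptive noise (CEEMDAN)
#'
#' Stage-wise noise-assisted decomposition. With `E_k(.)` the k-th EMD mode
#' operator and `w_i` standard Gaussian noise realizations:
#' the first mode is the ensemble average of the first EMD mode of
#' `x + eps_0 w_i`; at stage k the next mode is the ensemble average of the
#' first EMD mode of `r_k + eps_k E_k(w_i)`, and the residual is updated by
#' subtraction, which makes the reconstruction `sum(IMFs) + residual == x`
#' exact by construction. Decomposition stops when the residual has fewer than
#' two interior extrema (or the noise modes are exhausted). Stage noise
#' amplitudes are `noise_scale * sd(r_k)`, with each noise mode normalized to
#' unit standard deviation.
#'
#' @param x Numeric signal (finite, length >= 8).
#' @param config A [ceemdan_config()].
#' @return An `imf_set` (see [imf_set()]).
#' @export
ceemdan_decompose <- function(x, config = ceemdan_config()) {
  assert_that(inherits(config, "ceemdan_config"), "config must be a ceemdan_config()")
  assert_that(all(is.finite(x)), "signal must be finite")
  assert_that(length(x) >= 8, "signal must have at least 8 samples")
  n <- length(x)
  I <- config$ensemble_size
  eps <- config$noise_scale
  with_seed(config$seed, {
    noise <- matrix(stats::rnorm(n * I), n, I)
    # Pre-decompose every noise realization once; stage k draws its k-th mode.
    noise_modes <- lapply(seq_len(I), function(i) {
      emd_decompose(noise[, i], config$sift_stop, config$max_sift, config$max_imfs)$imfs
    })
    imfs <- list()
    # Stage 1: average first mode of x + eps*sd(x)*w_i
    s0 <- stats::sd(x)
    if (s0 == 0) return(imf_set(matrix(0, n, 0), x))
    acc <- numeric(n); m <- 0L
    for (i in seq_len(I)) {
      imf1 <- extract_imf(x + eps * s0 * noise[, i], config$sift_stop, config$max_sift)
      if (!is.null(imf1)) { acc <- acc + imf1; m <- m + 1L }
    }
    if (m == 0L) return(imf_set(matrix(0, n, 0), x))
    imfs[[1]] <- acc / m
    r <- x - imfs[[1]]
    k <- 1L
    while (length(imfs) < config$max_imfs && n_interior_extrema(r) >= 2) {
      sr <- stats::sd(r)
      if (sr == 0) break
      acc <- numeric(n); m <- 0L
      for (i in seq_len(I)) {
        if (ncol(noise_modes[[i]]) < k) next
        nk <- noise_modes[[i]][, k]
        snk <- stats::sd(nk)
        if (snk == 0) next
        imf1 <- extract_imf(r + eps * sr * nk / snk, config$sift_stop, config$max_sift)
        if (!is.null(imf1)) { acc <- acc + imf1; m <- m + 1L }
      }
      if (m == 0L) {
        # noise modes exhausted: fall back to plain EMD modes of the residual
        tail_set <- emd_decompose(r, config$sift_stop, config$max_sift,
                                  config$max_imfs - length(imfs))
        if (ncol(tail_set$imfs) == 0) break
        for (j in seq_len(ncol(tail_set$imfs))) imfs[[length(imfs) + 1]] <- tail_set$imfs[, j]
        r <- tail_set$residual
        break
      }
      imfs[[length(imfs) + 1]] <- acc / m
      r <- r - imfs[[length(imfs)]]
      k <- k + 1L
    }
    imf_set(do.call(cbind, imfs), r)
  })
}
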