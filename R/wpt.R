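# Wavelet packet transform (periodized orthogonal filter bank) and
# per-node threshold denoising.

# Orthonormal scaling (reconstruction low-pass) filters, sum = sqrt(2).
wavelet_filter <- function(name) {
  h <- switch(name,
    db2 = c(0.48296291314469025, 0.836516303737469, 0.22414386804185735,
            -0.12940952255092145),
    db4 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
            -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278),
    db8 = c(0.05441584224308161, 0.3128715909144659, 0.6756307362980128,
            0.5853546836548691, -0.015829105256023893, -0.2840155429624281,
            0.00047248457399797254, 0.128747426620186, -0.01736930100202211,
            -0.04408825393106472, 0.013981027917015516, 0.008746094047015655,
            -0.00487035299301066, -0.0003917403729959771, 0.0006754494059985568,
            -0.00011747678400228192),
    stop(sprintf("unknown wavelet basis '%s' (supported: db2, db4, db8)", name),
         call. = FALSE)
  )
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)   # quadrature mirror high-pass
  list(h = h, g = g, length = L)
}

# One analysis step (correlation form); orthonormal, so the synthesis step
# below is its adjoint and exact inverse.
wpt_step_analyze <- function(x, flt) {
  N <- length(x)
  half <- N %/% 2L
  idx0 <- 2L * (seq_len(half) - 1L)
  a <- numeric(half); d <- numeric(half)
  for (m in seq_len(flt$length) - 1L) {
    xi <- x[((idx0 + m) %% N) + 1L]
    a <- a + flt$h[m + 1L] * xi
    d <- d + flt$g[m + 1L] * xi
  }
  list(a = a, d = d)
}

wpt_step_synthesize <- function(a, d, flt) {
  half <- length(a)
  N <- 2L * half
  x <- numeric(N)
  idx0 <- 2L * (seq_len(half) - 1L)
  for (m in seq_len(flt$length) - 1L) {
    pos <- ((idx0 + m) %% N) + 1L
    contrib <- flt$h[m + 1L] * a + flt$g[m + 1L] * d
    agg <- rowsum(contrib, pos)
    x[as.integer(rownames(agg))] <- x[as.integer(rownames(agg))] + agg[, 1]
  }
  x
}

# Full packet tree to `level`; returns list of 2^level terminal-node
# coefficient vectors in natural (filter-path) order: node 1 is the
# all-low-pass (approximation) path.
wpt_analyze <- function(x, level, flt) {
  nodes <- list(x)
  for (l in seq_len(level)) {
    nxt <- vector("list", 2L * length(nodes))
    for (j in seq_along(nodes)) {
      s <- wpt_step_analyze(nodes[[j]], flt)
      nxt[[2L * j - 1L]] <- s$a
      nxt[[2L * j]] <- s$d
    }
    nodes <- nxt
  }
  nodes
}

wpt_synthesize <- function(nodes, flt) {
  while (length(nodes) > 1L) {
    nxt <- vector("list", length(nodes) %/% 2L)
    for (j in seq_along(nxt)) {
      nxt[[j]] <- wpt_step_synthesize(nodes[[2L * j - 1L]], nodes[[2L * j]], flt)
    }
    nodes <- nxt
  }
  nodes[[1L]]
}

#' Wavelet-packet denoising configuration
#'
#' @param wavelet_basis Wavelet name (`"db4"` default; `"db2"`, `"db8"` also
#'   available).
#' @param level Decomposition level (default 3; requires `2^level <= n`).
#' @param threshold_rule `"soft"` (default) or `"hard"`.
#' @param threshold_scale Multiplier on the universal threshold (default 1).
#' @return An object of class `wpt_config`.
#' @export
wpt_config <- function(wavelet_basis = "db4", level = 3,
                       threshold_rule = c("soft", "hard"), threshold_scale = 1) {
  threshold_rule <- match.arg(threshold_rule)
  assert_that(is_count(level, min = 1L), "level must be an integer >= 1")
  assert_that(is_number(threshold_scale) && threshold_scale > 0,
              "threshold_scale must be positive")
  wavelet_filter(wavelet_basis) # validates the name
  structure(list(wavelet_basis = wavelet_basis, level = as.integer(level),
                 threshold_rule = threshold_rule, threshold_scale = threshold_scale),
            class = "wpt_config")
}

apply_threshold <- function(c, lambda, rule) {
  if (rule == "soft") sign(c) * pmax(abs(c) - lambda, 0) else c * (abs(c) > lambda)
}

#' Wavelet-packet threshold denoising of one signal
#'
#' Full binary wavelet-packet tree to the configured level, per-node universal
#' threshold `lambda = scale * sigma_hat * sqrt(2 log n)` with the robust noise
#' estimate `sigma_hat = median(|coef|) / 0.6745` computed per node, soft or
#' hard shrinkage, then inverse transform. By default the all-low-pass
#' (approximation) node is left untouched so smooth signal content passes
#' unchanged; when the input is a high-frequency intrinsic mode function —
#' zero-mean and free of low-frequency signal by construction — its
#' approximation-node content is noise leakage and can be thresholded too
#' (`threshold_approx = TRUE`, what [ceemdan_wpt_denoise()] uses). Signals
#' whose length is not a multiple of `2^level` are reflection-padded at the end
#' and trimmed after reconstruction.
#'
#' Used on the high-frequency intrinsic mode functions inside
#' [ceemdan_wpt_denoise()], and directly on raw signals (with the
#' approximation node exempt) as the wavelet-only denoising baseline.
#'
#' @param imf Numeric signal (an IMF, or any signal).
#' @param config A [wpt_config()].
#' @param threshold_approx Also threshold the approximation node (default
#'   FALSE; use TRUE only for inputs without low-frequency signal content).
#' @return Denoised signal, same length as the input.
#' @export
wpt_denoise_imf <- function(imf, config = wpt_config(), threshold_approx = FALSE) {
  assert_that(inherits(config, "wpt_config"), "config must be a wpt_config()")
  n <- length(imf)
  block <- 2L^config$level
  assert_that(block <= n, "decomposition level too deep for the signal length")
  flt <- wavelet_filter(config$wavelet_basis)
  pad <- (block - n %% block) %% block
  x <- if (pad > 0) c(imf, rev(imf)[seq_len(pad)]) else imf
  assert_that(length(x) / block >= flt$length,
              "decomposition level too deep for the signal length")
  nodes <- wpt_analyze(x, config$level, flt)
  ntot <- length(x)
  first <- if (threshold_approx) 1L else 2L  # node 1 = approximation path
  for (j in seq.int(first, length(nodes))) {
    co <- nodes[[j]]
    sigma <- stats::median(abs(co)) / 0.6745
    lambda <- config$threshold_scale * sigma * sqrt(2 * log(ntot))
    nodes[[j]] <- apply_threshold(co, lambda, config$threshold_rule)
  }
  y <- wpt_synthesize(nodes, flt)
  y[seq_len(n)]
}
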