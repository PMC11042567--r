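# Empirical mode decomposition by cubic-spline envelope sifting.

# Indices of local maxima and minima; flat runs contribute one turning point.
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  d <- sign(diff(x))
  nz <- which(d != 0)
  if (length(nz) < 2) return(list(max = integer(0), min = integer(0)))
  dn <- d[nz]
  turn <- which(dn[-length(dn)] != dn[-1])
  if (length(turn) == 0) return(list(max = integer(0), min = integer(0)))
  idx <- nz[turn] + 1L           # sample at (or at the start of a flat after) the turn
  kind <- dn[turn]               # +1 then -1 -> maximum
  list(max = idx[kind > 0], min = idx[kind < 0])
}

n_interior_extrema <- function(x) {
  e <- local_extrema(x)
  length(e$max) + length(e$min)
}

# Cubic-spline envelope through extrema, with extrema mirrored about the
# signal ends so the spline is anchored outside [1, n].
envelope_spline <- function(idx, val, n) {
  if (length(idx) == 1) return(rep(val, n))
  k <- min(2L, length(idx))
  left_t <- 2 * 1 - idx[seq_len(k)]
  left_v <- val[seq_len(k)]
  right_t <- 2 * n - idx[length(idx) - seq_len(k) + 1L]
  right_v <- val[length(idx) - seq_len(k) + 1L]
  ord <- order(c(left_t, idx, right_t))
  tt <- c(left_t, idx, right_t)[ord]
  vv <- c(left_v, val, right_v)[ord]
  keep <- !duplicated(tt)
  stats::spline(tt[keep], vv[keep], xout = seq_len(n), method = "fmm")$y
}

# One sifting pass: subtract the mean of the upper and lower envelopes.
# Returns NULL when there are not enough extrema to define envelopes.
sift_once <- function(h) {
  e <- local_extrema(h)
  if (length(e$max) < 2 || length(e$min) < 2) return(NULL)
  n <- length(h)
  upper <- envelope_spline(e$max, h[e$max], n)
  lower <- envelope_spline(e$min, h[e$min], n)
  h - (upper + lower) / 2
}

# Extract one IMF from x, or NULL if x has too few extrema.
extract_imf <- function(x, sift_stop = 0.2, max_sift = 10) {
  h <- sift_once(x)
  if (is.null(h)) return(NULL)
  for (i in seq_len(max_sift - 1)) {
    h_new <- sift_once(h)
    if (is.null(h_new)) break
    denom <- h^2
    denom[denom < .Machine$double.eps] <- .Machine$double.eps
    sd_crit <- sum((h - h_new)^2 / denom)
    h <- h_new
    if (sd_crit < sift_stop) break
  }
  h
}

#' Empirical mode decomposition (EMD)
#'
#' Classical EMD by cubic-spline envelope sifting: each intrinsic mode
#' function (IMF) is obtained by repeatedly subtracting the mean of the upper
#' and lower extremal envelopes until a standard-deviation sifting criterion
#' is met, then removed from the signal; decomposition stops when the residual
#' has fewer than two interior extrema. IMFs are ordered high to low
#' frequency; IMFs plus residual reconstruct the input exactly.
#'
#' @param x Numeric signal (finite, length >= 8).
#' @param sift_stop Standard-deviation sifting stop threshold (default 0.2).
#' @param max_sift Maximum sifting iterations per IMF (default 10).
#' @param max_imfs Safety cap on the number of IMFs (default 16).
#' @return An object of class `imf_set`: list with `imfs` (matrix, one column
#'   per IMF, possibly zero columns) and `residual`.
#' @export
emd_decompose <- function(x, sift_stop = 0.2, max_sift = 10, max_imfs = 16) {
  assert_that(length(x) >= 8, "signal must have at least 8 samples")
  assert_that(all(is.finite(x)), "signal must be finite")
  n <- length(x)
  imfs <- list()
  r <- x
  while (length(imfs) < max_imfs && n_interior_extrema(r) >= 2) {
    imf <- extract_imf(r, sift_stop, max_sift)
    if (is.null(imf)) break
    imfs[[length(imfs) + 1]] <- imf
    r <- r - imf
  }
  imf_set(if (length(imfs) > 0) do.call(cbind, imfs) else matrix(0, n, 0), r)
}

#' IMF set container
#' @param imfs Matrix of IMFs (samples x modes), high to low frequency.
#' @param residual Residual signal.
#' @return An object of class `imf_set`.
#' @export
imf_set <- function(imfs, residual) {
  imfs <- as.matrix(imfs)
  assert_that(nrow(imfs) == length(residual) || ncol(imfs) == 0,
              "IMFs and residual must share length")
  structure(list(imfs = imfs, residual = as.numeric(residual),
                 source_length = length(residual)),
            class = "imf_set")
}

#' Reconstruct the signal from an IMF set
#' @param set An `imf_set`.
#' @return Numeric signal: sum of all IMFs plus the residual.
#' @export
imf_reconstruct <- function(set) {
  assert_that(inherits(set, "imf_set"), "set must be an imf_set")
  if (ncol(set$imfs) == 0) return(set$residual)
  rowSums(set$imfs) + set$residual
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("IMF set: %d modes + residual, %d samples\n",
              ncol(x$imfs), x$source_length))
  invisible(x)
}
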