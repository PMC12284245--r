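# internal numeric helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
wrap_angle <- function(phi) {
  # wrap to (-pi, pi]
  out <- (phi + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

rms <- function(x) sqrt(mean(x^2))

row_norms <- function(m) sqrt(rowSums(m^2))

unit_rows <- function(m) {
  n <- row_norms(m)
  n[n == 0] <- 1
  m / n
}

#' Zero-phase "same" convolution with reflect padding
#'
#' Convolves each row of `x` with an odd-length symmetric kernel `h`,
#' compensating the group delay so the output is aligned with the input
#' (zero phase). Edges are handled by signal reflection.
#'
#' @param x numeric vector or matrix (channels x samples)
#' @param h odd-length numeric kernel
#' @return filtered object of the same shape as `x`
#' @keywords internal
#' @noRd
conv_same <- function(x, h) {
  nh <- length(h)
  stopifnot(nh %% 2L == 1L)
  half <- (nh - 1L) %/% 2L
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, 1L)
  n <- ncol(x)
  pad <- min(half, n - 1L)
  left <- if (pad > 0) x[, (pad + 1L):2L, drop = FALSE] else NULL
  right <- if (pad > 0) x[, (n - 1L):(n - pad), drop = FALSE] else NULL
  xx <- cbind(left, x, right)
  nfft <- stats::nextn(ncol(xx) + nh - 1L, 2L)
  X <- stats::mvfft(t(cbind(xx, matrix(0, nrow(x), nfft - ncol(xx)))))
  H <- stats::fft(c(h, rep(0, nfft - nh)))
  y <- t(Re(stats::mvfft(X * H, inverse = TRUE))) / nfft
  out <- y[, (pad + half + 1L):(pad + half + n), drop = FALSE]
  if (vec) as.numeric(out) else out
}

#' 1/f^alpha ("pink") noise via spectral shaping
#'
#' @param n number of samples
#' @param alpha spectral exponent (power ~ 1/f^alpha)
#' @return numeric vector with unit variance
#' @keywords internal
#' @noRd
pink_noise <- function(n, alpha = 1) {
  as.numeric(pink_noise_mat(1L, n, alpha))
}

# k independent unit-variance 1/f^alpha series (rows)
pink_noise_mat <- function(k, n, alpha = 1) {
  nfft <- stats::nextn(n, 2L)
  f <- c(1, seq_len(nfft / 2), seq(nfft / 2 - 1, 1)) # avoid f=0 blowup
  amp <- f^(-alpha / 2)
  ph <- matrix(stats::runif(nfft * k, 0, 2 * pi), nfft, k)
  spec <- amp * exp(1i * ph)
  x <- t(Re(stats::mvfft(spec, inverse = TRUE))[seq_len(n), , drop = FALSE])
  x <- x - rowMeans(x)
  x / sqrt(rowSums(x^2) / (n - 1L))
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# derive a stream of 31-bit sub-seeds from one master seed
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
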