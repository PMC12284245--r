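# Theta power and weighted phase-lag index between region time courses.

# analytic signal restricted to a band: one-sided FFT mask
band_analytic <- function(x, rate, band) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * rate
  f[f > rate / 2] <- f[f > rate / 2] - rate
  keep <- f >= band[1L] & f <= band[2L]       # positive side only
  X[!keep] <- 0
  2 * stats::fft(X, inverse = TRUE) / n
}

#' Theta-band signal power
#'
#' Mean over epochs and samples of the squared analytic-signal amplitude
#' in the band, divided by two (so a unit-amplitude sinusoid has power
#' 0.5, the variance convention).
#'
#' @param x epochs x samples matrix (or a vector, one epoch)
#' @param rate sampling rate (Hz)
#' @param band frequency band (Hz)
#' @return scalar power (amplitude^2 units of `x`)
#' @export
theta_power <- function(x, rate, band = c(4, 8)) {
  if (is.null(dim(x))) x <- matrix(x, 1L)
  mean(apply(x, 1L, function(v) mean(Mod(band_analytic(v, rate, band))^2))) / 2
}

# Morlet coefficient of each epoch at the epoch centre for each frequency
morlet_at_center <- function(x, rate, freqs, n_cycles = 3) {
  n <- ncol(x)
  ctr <- (n + 1L) %/% 2L
  out <- matrix(complex(real = 0), nrow(x), length(freqs))
  for (fi in seq_along(freqs)) {
    h <- morlet_kernel(freqs[fi], rate, n_cycles)
    half <- (length(h) - 1L) %/% 2L
    lo <- ctr - half; hi <- ctr + half
    if (lo < 1L || hi > n)
      stop("epoch too short for the ", freqs[fi], " Hz wavelet")
    seg <- x[, lo:hi, drop = FALSE]
    out[, fi] <- seg %*% Conj(rev(h))   # convolution value at the centre
  }
  out
}

#' Weighted phase-lag index between two sets of epochs
#'
#' `wPLI = |E[Im(Sxy)]| / E[|Im(Sxy)|]` with the cross-spectrum `Sxy`
#' taken per epoch from Morlet coefficients at the epoch centre, the
#' expectation across epochs, averaged over the theta frequency bins.
#' A vanishing denominator (no imaginary cross-spectral mass, e.g. zero
#' lag) returns 0 with the `undefined` flag set.
#'
#' @param x_epochs,y_epochs epochs x samples matrices (equal shapes)
#' @param rate sampling rate (Hz)
#' @param freqs frequency bins (Hz)
#' @param n_cycles Morlet cycles
#' @param debias use the debiased squared-wPLI estimator instead
#' @return scalar in `[0, 1]` with attribute `undefined`
#' @export
wpli <- function(x_epochs, y_epochs, rate, freqs = seq(4, 8, by = 0.5),
                 n_cycles = 3, debias = FALSE) {
  stopifnot(all(dim(x_epochs) == dim(y_epochs)))
  if (nrow(x_epochs) < 2L) stop("wPLI needs >= 2 epochs")
  wx <- morlet_at_center(x_epochs, rate, freqs, n_cycles)
  wy <- morlet_at_center(y_epochs, rate, freqs, n_cycles)
  im <- Im(wx * Conj(wy))                     # epochs x freqs
  undef <- FALSE
  vals <- vapply(seq_along(freqs), function(fi) {
    num <- abs(mean(im[, fi]))
    den <- mean(abs(im[, fi]))
    if (den < .Machine$double.eps * max(1, mean(Mod(wx[, fi]) * Mod(wy[, fi])))) {
      undef <<- TRUE
      return(0)
    }
    if (debias) {
      n <- nrow(im)
      s1 <- sum(im[, fi]); s2 <- sum(im[, fi]^2)
      d <- sum(abs(im[, fi]))^2 - s2
      if (abs(d) < .Machine$double.eps) { undef <<- TRUE; return(0) }
      return((s1^2 - s2) / d)
    }
    num / den
  }, numeric(1L))
  out <- mean(vals)
  attr(out, "undefined") <- undef
  out
}

#' Power and connectivity table for one session
#'
#' Computes theta power per region and wPLI for the reported
#' hippocampo-cortical pairs (left hemisphere by default; all pairs with
#' `all_pairs = TRUE`) from epoched region time courses.
#'
#' @param region_epochs named list: per region, an epochs x samples matrix
#' @param rate sampling rate
#' @param session,condition tags carried into the output
#' @param all_pairs emit every region pair instead of the default three
#' @param band theta band for power
#' @return `data.frame` (class `connectivity_result`) with columns
#'   `metric`, `name`, `value`, `session`, `condition`
#' @export
connectivity_table <- function(region_epochs, rate, session = "pre",
                               condition = "verum", all_pairs = FALSE,
                               band = c(4, 8)) {
  regions <- names(region_epochs)
  rows <- list()
  for (r in regions) {
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "power", name = r,
      value = theta_power(region_epochs[[r]], rate, band),
      session = session, condition = condition, stringsAsFactors = FALSE)
  }
  pairs <- if (all_pairs) {
    utils::combn(regions, 2L, simplify = FALSE)
  } else {
    cort <- intersect(c("superior-frontal-L", "middle-frontal-L", "temporal-L"),
                      regions)
    lapply(cort, function(c1) c("hippocampus-L", c1))
  }
  for (p in pairs) {
    if (!all(p %in% regions)) next
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "wpli", name = paste(p, collapse = "~"),
      value = as.numeric(wpli(region_epochs[[p[1L]]], region_epochs[[p[2L]]], rate)),
      session = session, condition = condition, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("connectivity_result", "data.frame")
  out
}

#' Post-minus-pre difference of connectivity results
#'
#' @param pre,post `connectivity_result` tables from the same condition
#' @return data.frame with `metric`, `name`, `condition`, `value`
#'   (post minus pre)
#' @export
pre_post_difference <- function(pre, post) {
  if (!identical(sort(paste(pre$metric, pre$name)),
                 sort(paste(post$metric, post$name))))
    stop("session mismatch: pre and post tables cover different quantities")
  if (!identical(unique(pre$condition), unique(post$condition)))
    stop("session mismatch: different conditions")
  key <- function(d) paste(d$metric, d$name)
  post_v <- post$value[match(key(pre), key(post))]
  data.frame(metric = pre$metric, name = pre$name,
             condition = pre$condition,
             value = post_v - pre$value, stringsAsFactors = FALSE)
}
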