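# Theta-burst detection: Morlet TFR on 10-s segments, frequency-averaged
# z-scored power, peak picking by topographic prominence, and
# phase-realigned +/-400 ms epochs.

# L2-normalized complex Morlet kernel (white noise then excites every
# frequency bin equally, so the frequency-averaged power is unbiased)
morlet_kernel <- function(freq, rate, n_cycles = 3) {
  sigma_t <- n_cycles / (2 * pi * freq)
  half <- ceiling(3 * sigma_t * rate)
  t <- (-half:half) / rate
  w <- exp(2i * pi * freq * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))
}

#' Morlet time-frequency representation of one segment
#'
#' Complex TFR with Morlet wavelets (3 cycles) on the theta grid
#' 4, 4.5, ..., 8 Hz. Samples within one wavelet half-length (at the
#' lowest frequency) of either segment edge are flagged invalid.
#'
#' @param x channels x samples matrix (one segment) or an `eeg_recording`
#' @param rate sampling rate (taken from the recording if given)
#' @param freqs frequency grid in Hz
#' @param n_cycles wavelet cycles
#' @return object of class `theta_tfr`: `coef` (channels x freqs x samples,
#'   complex), `freqs`, `rate`, `valid` (logical per sample)
#' @export
morlet_tfr <- function(x, rate = NULL, freqs = seq(4, 8, by = 0.5),
                       n_cycles = 3) {
  if (inherits(x, "eeg_recording")) {
    rate <- x$sfreq
    keep <- x$roles == "eeg" & !(x$labels %in% x$bad)
    x <- x$data[keep, , drop = FALSE]
  }
  if (is.null(rate)) stop("rate required")
  n_samp <- ncol(x)
  max_half <- ceiling(3 * n_cycles / (2 * pi * min(freqs)) * rate)
  if (n_samp <= 2L * max_half) stop("segment shorter than the lowest-frequency wavelet")
  coef <- array(complex(real = 0), c(nrow(x), length(freqs), n_samp))
  kernels <- lapply(freqs, morlet_kernel, rate = rate, n_cycles = n_cycles)
  nfft <- stats::nextn(n_samp + max(lengths(kernels)) - 1L, 2L)
  X <- stats::mvfft(t(cbind(x, matrix(0, nrow(x), nfft - n_samp))))
  for (fi in seq_along(freqs)) {
    h <- kernels[[fi]]
    half <- (length(h) - 1L) %/% 2L
    H <- stats::fft(c(h, rep(0, nfft - length(h))))
    y <- t(stats::mvfft(X * H, inverse = TRUE)) / nfft
    coef[, fi, ] <- y[, (half + 1L):(half + n_samp), drop = FALSE]
  }
  valid <- rep(TRUE, n_samp)
  valid[seq_len(max_half)] <- FALSE
  valid[(n_samp - max_half + 1L):n_samp] <- FALSE
  structure(list(coef = coef, freqs = freqs, rate = rate, valid = valid),
            class = "theta_tfr")
}

#' Frequency-averaged, z-scored, channel-averaged theta power
#'
#' Order of operations: power from the complex TFR, mean over frequency
#' bins, per-channel z-score along time (population SD; zero-variance
#' channels give all-zero scores), mean over channels.
#'
#' @param tfr a `theta_tfr`
#' @return numeric score per sample, with attribute `valid`
#' @export
burst_score <- function(tfr) {
  pw <- matrix(0, dim(tfr$coef)[1L], dim(tfr$coef)[3L])  # channels x time
  for (fi in seq_along(tfr$freqs)) pw <- pw + Mod(tfr$coef[, fi, ])^2
  pw <- pw / length(tfr$freqs)
  v <- tfr$valid
  z <- t(apply(pw, 1L, function(p) {
    mu <- mean(p[v])
    sdv <- sqrt(mean((p[v] - mu)^2))
    if (sdv == 0) return(rep(0, length(p)))
    (p - mu) / sdv
  }))
  score <- colMeans(z)
  attr(score, "valid") <- v
  score
}

# topographic prominence of local maxima (reference implementation of the
# standard definition: height above the higher of the two flanking minima,
# each taken down to the nearest higher sample or the signal edge)
peak_prominences <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    l <- p
    lmin <- h
    while (l > 1L) {
      l <- l - 1L
      if (x[l] > h) break
      lmin <- min(lmin, x[l])
    }
    r <- p
    rmin <- h
    while (r < length(x)) {
      r <- r + 1L
      if (x[r] > h) break
      rmin <- min(rmin, x[r])
    }
    h - max(lmin, rmin)
  }, numeric(1L))
}

#' Find theta peaks by prominence
#'
#' Local maxima of the burst score whose topographic prominence reaches
#' `prominence` (1.5 z-units). Peaks inside the invalid TFR edge are
#' excluded. An empty catalog is a valid outcome.
#'
#' @param score output of [burst_score()] (or any numeric series)
#' @param prominence threshold in score units
#' @param valid optional logical mask (defaults to the score attribute)
#' @return data.frame with `sample` and `prominence`, sorted
#' @export
find_theta_peaks <- function(score, prominence = 1.5, valid = NULL) {
  if (is.null(valid)) valid <- attr(score, "valid") %||% rep(TRUE, length(score))
  x <- as.numeric(score)
  if (any(!is.finite(x))) stop("score must be finite")
  n <- length(x)
  if (n < 3L) return(data.frame(sample = integer(0), prominence = numeric(0)))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n]) + 1L
  cand <- cand[valid[cand]]
  if (!length(cand)) return(data.frame(sample = integer(0), prominence = numeric(0)))
  prom <- peak_prominences(x, cand)
  keep <- prom >= prominence
  data.frame(sample = cand[keep], prominence = prom[keep])
}

#' Detect theta bursts in a cleaned recording
#'
#' Cuts the recording into `floor(duration/10)` segments of 10 s and
#' computes the Morlet TFR per segment. Power is averaged over frequency
#' bins, z-scored per channel along the (whole-recording) time axis,
#' averaged over channels, and prominent peaks are found in that score;
#' TFR edge samples of each segment are excluded. For each peak the
#' circular mean (over channels) of the instantaneous phase at the
#' realignment frequency is recorded.
#'
#' @param rec cleaned `eeg_recording`
#' @param prominence peak prominence threshold
#' @param freqs TFR frequency grid
#' @param n_cycles wavelet cycles
#' @param f0 realignment frequency (Hz); must be on the grid
#' @param segment_s segment length in seconds
#' @return object of class `burst_catalog`: data.frame with `time` (s),
#'   `sample` (global), `prominence`, `phase` (rad)
#' @export
find_theta_bursts <- function(rec, prominence = 1.5,
                              freqs = seq(4, 8, by = 0.5), n_cycles = 3,
                              f0 = 6, segment_s = 10) {
  keep <- rec$roles == "eeg" & !(rec$labels %in% rec$bad)
  x <- rec$data[keep, , drop = FALSE]
  rate <- rec$sfreq
  seg_len <- round(segment_s * rate)
  n_seg <- floor(ncol(x) / seg_len)
  if (n_seg < 1L) stop("recording shorter than one segment")
  fi0 <- which(abs(freqs - f0) < 1e-9)
  if (!length(fi0)) stop("f0 must be on the frequency grid")
  n_tot <- n_seg * seg_len
  pw <- matrix(0, nrow(x), n_tot)        # freq-averaged power
  ph0 <- matrix(0, nrow(x), n_tot)       # phase at f0
  valid <- rep(FALSE, n_tot)
  # each segment's TFR is computed on a window extended by the wavelet
  # half-length into the neighbouring data, so only samples near the
  # recording boundaries remain invalid
  pad <- ceiling(3 * n_cycles / (2 * pi * min(freqs)) * rate)
  for (s in seq_len(n_seg)) {
    idx <- (s - 1L) * seg_len + seq_len(seg_len)
    lo <- max(1L, idx[1L] - pad)
    hi <- min(ncol(x), idx[seg_len] + pad)
    tfr <- morlet_tfr(x[, lo:hi, drop = FALSE], rate, freqs, n_cycles)
    off <- idx - lo + 1L
    acc <- matrix(0, nrow(x), seg_len)
    for (fi in seq_along(freqs)) acc <- acc + Mod(tfr$coef[, fi, off])^2
    pw[, idx] <- acc / length(freqs)
    ph0[, idx] <- Arg(tfr$coef[, fi0, off])
    valid[idx] <- tfr$valid[off]
  }
  z <- t(apply(pw, 1L, function(p) {
    mu <- mean(p[valid])
    sdv <- sqrt(mean((p[valid] - mu)^2))
    if (sdv == 0) return(rep(0, length(p)))
    (p - mu) / sdv
  }))
  score <- colMeans(z)
  pk <- find_theta_peaks(score, prominence, valid = valid)
  ph <- vapply(pk$sample, function(p) Arg(sum(exp(1i * ph0[, p]))), numeric(1L))
  cat <- data.frame(sample = pk$sample, prominence = pk$prominence, phase = ph)
  cat$time <- cat$sample / rate
  rownames(cat) <- NULL
  structure(cat, class = c("burst_catalog", "data.frame"),
            rate = rate, f0 = f0, n_segments = n_seg)
}

#' Extract phase-realigned burst epochs
#'
#' Shifts each peak by `wrap(phi_ref - phi_peak) / (2 pi f0)` seconds
#' (nearest sample) so the realignment-frequency phase matches `phi_ref`
#' across epochs, then cuts `peak +/- win` from the continuous data.
#' Peaks too close to the recording edges are dropped (logged).
#'
#' @param rec cleaned `eeg_recording`
#' @param catalog a `burst_catalog`
#' @param f0 realignment frequency in Hz
#' @param win half-window in seconds (400 ms)
#' @param phi_ref common phase reference (0 = cosine peak)
#' @return object of class `burst_epochs`: `data`
#'   (epochs x channels x samples), `rate`, `shifts` (s), `times` (s),
#'   `labels`, `dropped`
#' @export
extract_aligned_epochs <- function(rec, catalog, f0 = attr(catalog, "f0") %||% 6,
                                   win = 0.4, phi_ref = 0) {
  keep <- rec$roles == "eeg" & !(rec$labels %in% rec$bad)
  x <- rec$data[keep, , drop = FALSE]
  rate <- rec$sfreq
  half <- round(win * rate)
  n <- ncol(x)
  epochs <- list(); shifts <- numeric(0); times <- numeric(0); dropped <- 0L
  for (i in seq_len(nrow(catalog))) {
    dphi <- wrap_angle(phi_ref - catalog$phase[i])
    dt <- dphi / (2 * pi * f0)
    centre <- catalog$sample[i] + round(dt * rate)
    if (centre - half < 1L || centre + half > n) { dropped <- dropped + 1L; next }
    epochs[[length(epochs) + 1L]] <- x[, (centre - half):(centre + half), drop = FALSE]
    shifts <- c(shifts, dt)
    times <- c(times, centre / rate)
  }
  dat <- array(0, c(length(epochs), nrow(x), 2L * half + 1L))
  for (e in seq_along(epochs)) dat[e, , ] <- epochs[[e]]
  structure(list(data = dat, rate = rate, shifts = shifts, times = times,
                 labels = rec$labels[keep], dropped = dropped,
                 f0 = f0, win = win),
            class = "burst_epochs")
}

#' @export
print.burst_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<burst_epochs> ", d[1L], " epochs x ", d[2L], " channels x ", d[3L],
      " samples @ ", x$rate, " Hz (", x$dropped, " dropped)\n", sep = "")
  invisible(x)
}
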