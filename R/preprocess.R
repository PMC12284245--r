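# Preprocessing: resampling, zero-phase FIR bandpass, bad-channel detection,
# ocular component rejection, average reference.

odd_taps <- function(tb, rate) {
  n <- as.integer(ceiling(3.3 / tb * rate))
  n + (1L - n %% 2L)
}

# Hamming-window sinc lowpass kernel, scaled to exact unity gain at DC
lowpass_kernel <- function(ntaps, fc, rate) {
  n <- seq_len(ntaps) - 1
  m <- (ntaps - 1) / 2
  ham <- 0.54 - 0.46 * cos(2 * pi * n / (ntaps - 1))
  x <- n - m
  arg <- 2 * pi * fc / rate
  h <- (2 * fc / rate) * ifelse(x == 0, 1, sin(arg * x) / (arg * x)) * ham
  h / sum(h)
}

#' Design a zero-phase Hamming-window FIR bandpass filter
#'
#' Transition bandwidths follow the rule
#' `tb_low = min(max(0.25*low, 2), low)` and
#' `tb_high = min(max(0.25*high, 2), rate/2 - high)` (Hz). Each band edge
#' gets its own Hamming-window sinc kernel whose odd length is the smallest
#' odd integer `>= 3.3/tb * rate`, centred into the overall filter whose
#' length is set by the narrower transition; the bandpass is the difference
#' of the two unity-DC lowpass kernels, giving exactly zero DC gain. The
#' symmetric (linear-phase) kernel is applied zero-phase by delay
#' compensation.
#'
#' @param low,high passband edges in Hz
#' @param rate sampling rate in Hz
#' @return object of class `filter_spec`: `low`, `high`, `rate`, `taps`,
#'   `coef`, `tb_low`, `tb_high`
#' @export
#' @examples
#' design_fir_bandpass(0.3, 30, 200)$taps # 2201
design_fir_bandpass <- function(low, high, rate) {
  if (!(0 < low && low < high && high < rate / 2))
    stop("invalid argument: need 0 < low < high < rate/2")
  tb_low <- min(max(0.25 * low, 2), low)
  tb_high <- min(max(0.25 * high, 2), rate / 2 - high)
  if (tb_high <= 0) stop("invalid argument: band infeasible")
  n_low <- odd_taps(tb_low, rate)
  n_high <- odd_taps(tb_high, rate)
  taps <- max(n_low, n_high)
  centre_pad <- function(h) {
    k <- (taps - length(h)) %/% 2L
    c(rep(0, k), h, rep(0, k))
  }
  h <- centre_pad(lowpass_kernel(n_high, high + tb_high / 2, rate)) -
    centre_pad(lowpass_kernel(n_low, low - tb_low / 2, rate))
  structure(list(low = low, high = high, rate = rate, taps = taps, coef = h,
                 tb_low = tb_low, tb_high = tb_high, window = "hamming"),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat("<filter_spec> ", x$low, "-", x$high, " Hz bandpass @ ", x$rate,
      " Hz, ", x$taps, " taps (", round(x$taps / x$rate, 3), " s), ",
      "transition ", x$tb_low, "/", x$tb_high, " Hz, Hamming window\n", sep = "")
  invisible(x)
}

#' Frequency response of an FIR filter
#'
#' @param spec a `filter_spec` (or numeric kernel with attribute rate)
#' @param n_points frequency grid size from 0 to Nyquist
#' @return data.frame with `freq` (Hz) and complex `response`
#' @export
fir_frequency_response <- function(spec, n_points = 2^16) {
  h <- spec$coef
  nfft <- 2L * n_points
  H <- stats::fft(c(h, rep(0, nfft - length(h))))
  idx <- seq_len(n_points)
  data.frame(freq = (idx - 1) / nfft * spec$rate,
             amplitude = abs(H[idx]))
}

#' Measured characteristics of an FIR bandpass design
#'
#' Measures, from the filter's own frequency response: the duration in
#' seconds; the maximum passband ripple in dB over the passband interior
#' (the nominal transition width is allowed around each edge); and the
#' minimum stopband attenuation in dB beyond the transition edges.
#'
#' @param spec a `filter_spec`
#' @return list with `duration_s`, `taps`, `ripple_db`, `attenuation_db`
#' @export
fir_design_characteristics <- function(spec) {
  fr <- fir_frequency_response(spec)
  a <- fr$amplitude
  f <- fr$freq
  pass <- f >= spec$low + spec$tb_low / 2 & f <= spec$high - spec$tb_high / 2
  stopb <- f >= spec$high + spec$tb_high
  if (spec$low - spec$tb_low > 0) stopb <- stopb | f <= spec$low - spec$tb_low
  ripple_db <- max(abs(20 * log10(a[pass])))
  attenuation_db <- -max(20 * log10(pmax(a[stopb], .Machine$double.xmin)))
  list(duration_s = spec$taps / spec$rate, taps = spec$taps,
       ripple_db = ripple_db, attenuation_db = attenuation_db)
}

#' Apply an FIR filter with zero phase
#'
#' @param rec an `eeg_recording` or numeric matrix/vector
#' @param spec a `filter_spec` designed at the recording's rate
#' @return same type as input
#' @export
apply_fir <- function(rec, spec) {
  if (inherits(rec, "eeg_recording")) {
    stopifnot(abs(rec$sfreq - spec$rate) < 1e-9)
    rec$data <- conv_same(rec$data, spec$coef)
    rec$log$stages <- c(rec$log$stages, "filter")
    rec$log$filter <- list(low = spec$low, high = spec$high, taps = spec$taps)
    rec
  } else {
    conv_same(rec, spec$coef)
  }
}

#' Resample a recording by integer decimation
#'
#' Anti-alias filters with a Hamming-window lowpass (passband edge at 80%
#' of the new Nyquist, stopband from 95%), then keeps every `rate/target`-th
#' sample. Only downsampling by an integer factor is supported.
#'
#' @param rec an `eeg_recording`
#' @param target new sampling rate in Hz
#' @return the resampled `eeg_recording`
#' @export
resample_recording <- function(rec, target) {
  if (target >= rec$sfreq) stop("invalid argument: upsampling not supported")
  q <- rec$sfreq / target
  if (abs(q - round(q)) > 1e-9)
    stop("invalid argument: rate must be an integer multiple of target")
  q <- as.integer(round(q))
  nyq <- target / 2
  tb <- 0.15 * nyq
  h <- lowpass_kernel(odd_taps(tb, rec$sfreq), (0.8 * nyq + 0.95 * nyq) / 2, rec$sfreq)
  rec$data <- conv_same(rec$data, h)[, seq(1L, ncol(rec$data), by = q), drop = FALSE]
  rec$sfreq <- target
  rec$log$stages <- c(rec$log$stages, "resample")
  rec$log$resample <- list(target = target, factor = q)
  rec
}

#' Angular k-nearest-neighbour adjacency of EEG sensors
#'
#' @param sensors a `sensor_array`
#' @param k neighbours per channel
#' @return list (per EEG channel) of neighbouring EEG channel indices
#' @export
channel_neighbors <- function(sensors, k = 6L) {
  eeg <- which(sensors$roles == "eeg")
  u <- unit_rows(sensors$positions[eeg, , drop = FALSE])
  d <- acos(pmin(pmax(u %*% t(u), -1), 1))
  lapply(seq_along(eeg), function(i) {
    order(d[i, ])[seq_len(k + 1L)][-1L]
  })
}

#' Detect bad channels by neighbour correlation
#'
#' A channel is flagged iff the maximum absolute Pearson correlation with
#' its neighbouring channels falls below `threshold` (r = 0.7). Channels
#' with zero variance are treated as r = 0 and flagged.
#'
#' @param rec an `eeg_recording` (filtered, resampled)
#' @param sensors the matching `sensor_array` (for adjacency), or pass
#'   `neighbors` directly
#' @param threshold correlation threshold
#' @param neighbors optional adjacency list over EEG channels
#' @param k neighbours when deriving adjacency from sensor positions
#' @return character vector of flagged channel labels
#' @export
detect_bad_channels <- function(rec, sensors = NULL, threshold = 0.7,
                                neighbors = NULL, k = 6L) {
  eeg <- which(rec$roles == "eeg")
  if (is.null(neighbors)) {
    if (is.null(sensors)) stop("need sensors or an explicit neighbor list")
    neighbors <- channel_neighbors(sensors, k)
  }
  x <- rec$data[eeg, , drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  cc <- suppressWarnings(stats::cor(t(x)))
  cc[!is.finite(cc)] <- 0
  flagged <- vapply(seq_along(eeg), function(i) {
    if (sds[i] == 0) return(TRUE)
    max(abs(cc[i, neighbors[[i]]])) < threshold
  }, logical(1L))
  rec$labels[eeg][flagged]
}

#' Average-reference data
#'
#' Subtracts the per-sample mean over EEG channels (excluding channels
#' marked bad). Idempotent.
#'
#' @param x an `eeg_recording`, a `burst_epochs` object, or a numeric
#'   matrix (channels x samples)
#' @return same type as input
#' @export
apply_average_reference <- function(x) {
  if (inherits(x, "eeg_recording")) {
    eeg <- which(x$roles == "eeg" & !(x$labels %in% x$bad))
    if (length(eeg) < 2L) stop("average reference needs >= 2 EEG channels")
    x$data[eeg, ] <- sweep(x$data[eeg, , drop = FALSE], 2L,
                           colMeans(x$data[eeg, , drop = FALSE]))
    x$log$stages <- c(x$log$stages, "average_reference")
    x
  } else if (inherits(x, "burst_epochs")) {
    for (e in seq_len(dim(x$data)[1L]))
      x$data[e, , ] <- sweep(x$data[e, , ], 2L, colMeans(x$data[e, , ]))
    x
  } else {
    if (nrow(x) < 2L) stop("average reference needs >= 2 channels")
    sweep(x, 2L, colMeans(x))
  }
}

#' Full preprocessing pipeline
#'
#' Runs the stages in the fixed order resample -> bandpass filter ->
#' bad-channel detection -> ICA ocular rejection, recording each stage in
#' the log. Bad channels are excluded (not interpolated) from all
#' downstream analyses.
#'
#' @param rec raw `eeg_recording`
#' @param sensors the matching `sensor_array`
#' @param target_rate resampling target (Hz)
#' @param low,high bandpass edges (Hz)
#' @param bad_r neighbour-correlation threshold for bad channels
#' @param eog_r EOG-correlation threshold for component rejection
#' @param seed seed for the ICA initialization
#' @param ica run the ocular-rejection stage (requires EOG channels)
#' @return cleaned `eeg_recording` with `bad` and `log` populated
#' @export
preprocess_recording <- function(rec, sensors, target_rate = 200,
                                 low = 0.3, high = 30,
                                 bad_r = 0.7, eog_r = 0.3, seed = 1L,
                                 ica = TRUE) {
  rec <- resample_recording(rec, target_rate)
  rec <- apply_fir(rec, design_fir_bandpass(low, high, rec$sfreq))
  rec$bad <- detect_bad_channels(rec, sensors, threshold = bad_r)
  rec$log$stages <- c(rec$log$stages, "bad_channels")
  rec$log$bad_channels <- rec$bad
  if (ica) rec <- reject_ocular_components(rec, threshold = eog_r, seed = seed)
  rec
}
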