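#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study conditions: 62-channel scalp EEG plus 2 EOG channels sampled at
#' 1000 Hz, 6-minute resting blocks, theta bursts at 6 bursts/min carried by
#' a 6 Hz sinusoid under a 500 ms Hanning envelope, pink (1/f) background
#' activity, blink artifacts, and a 20-participant two-condition crossover
#' with a built-in condition-by-memory interaction.
#'
#' @param seed integer master seed; every generator output is a
#'   deterministic function of it
#' @param duration recording length in seconds
#' @param sfreq sampling rate in Hz
#' @param snr_db sensor-space signal-to-noise ratio (dB) over burst windows
#' @param burst_rate theta bursts per minute
#' @param burst_freq carrier frequency in Hz
#' @param burst_dur Hanning envelope length in seconds
#' @param blink_rate blinks per minute
#' @param noise_exponent alpha of the 1/f^alpha background
#' @param n_noise_sources cortical dipoles carrying background activity
#' @param white_noise_ratio fraction of noise power that is white sensor noise
#' @param amp_cortical,amp_hippocampal burst dipole moments (A m)
#' @param n_participants crossover sample size (even, for counterbalancing)
#' @param beta effects of the study-table generator: named list with
#'   `intercept`, `condition`, `memory`, `interaction`, `baseline`,
#'   `order`, `visit`
#' @param sigma_u,sigma_e random-intercept and residual SDs of the outcome
#' @return an object of class `simulation_config`
#' @export
simulation_config <- function(seed = 1L,
                              duration = 360,
                              sfreq = 1000,
                              snr_db = 0,
                              burst_rate = 6,
                              burst_freq = 6,
                              burst_dur = 0.5,
                              blink_rate = 10,
                              noise_exponent = 1,
                              n_noise_sources = 100L,
                              white_noise_ratio = 0.1,
                              amp_cortical = 2e-8,
                              amp_hippocampal = 2e-8,
                              n_participants = 20L,
                              beta = list(intercept = 0, condition = 0.3,
                                          memory = 0.02, interaction = 0.06,
                                          baseline = 0.02, order = 0,
                                          visit = 0.1),
                              sigma_u = 0.5, sigma_e = 1) {
  stopifnot(burst_rate >= 0, blink_rate >= 0, duration > 0, sfreq > 0)
  structure(as.list(environment()), class = "simulation_config")
}

#' Ground-truth theta-burst source activity
#'
#' Selects the default active sources (superior-frontal and temporal, left
#' and right, plus the central grid point of each hippocampus) or a caller-
#' supplied set, draws Poisson burst times with a 1.2 s minimum separation,
#' and builds source waveforms: a `burst_freq` sinusoid under a Hanning
#' envelope of `burst_dur` seconds, with a per-source phase offset.
#'
#' @param space a `source_space`
#' @param cfg a [simulation_config()]
#' @param active_regions regions to activate (one source each); default
#'   covers 4 cortical + 2 hippocampal sources
#' @param phase_offsets radians per active source. The default assigns
#'   distinct inter-regional lags (cortical sources alternate 0 and pi/2
#'   within a hemisphere, right-hemisphere sources add pi/4, hippocampal
#'   sources lag their hemisphere's cortex by 2pi/3): regions whose lag is
#'   exactly 0 or pi would have no imaginary cross-spectrum, leaving the
#'   phase-lag index downstream undefined, and fully coherent sources bias
#'   sparse localization toward their common centroid
#' @return object of class `ground_truth`: `active_indices`, `moments`
#'   (3 x k unit orientations), `waveforms` (k x samples, A m),
#'   `burst_times` (s), `burst_freq`
#' @export
make_ground_truth <- function(space, cfg,
                              active_regions = c("superior-frontal-L",
                                                 "temporal-L",
                                                 "superior-frontal-R",
                                                 "temporal-R",
                                                 "hippocampus-L",
                                                 "hippocampus-R"),
                              phase_offsets = NULL) {
  set.seed(cfg$seed)
  n_samp <- round(cfg$duration * cfg$sfreq)
  pick <- integer(0)
  for (reg in active_regions) {
    members <- which(space$region == reg)
    if (!length(members)) stop("no sources in region ", reg)
    ctr <- colMeans(space$pos[members, , drop = FALSE])
    pick <- c(pick, members[which.min(colSums((t(space$pos[members, , drop = FALSE]) - ctr)^2))])
  }
  k <- length(pick)
  if (is.null(phase_offsets)) {
    hip <- grepl("hippocampus", active_regions)
    base <- numeric(k)
    base[!hip] <- rep_len(c(0, pi / 2), sum(!hip))
    base[hip] <- -2 * pi / 3
    phase_offsets <- base + ifelse(grepl("-R$", active_regions), pi / 4, 0)
  }
  phase_offsets <- rep_len(phase_offsets, k)

  n_burst <- stats::rpois(1L, cfg$burst_rate * cfg$duration / 60)
  margin <- cfg$burst_dur / 2 + 0.5
  times <- numeric(0)
  guard <- 0L
  while (length(times) < n_burst && guard < 10000L) {
    cand <- stats::runif(1L, margin, cfg$duration - margin)
    if (!length(times) || min(abs(times - cand)) > 1.2) times <- c(times, cand)
    guard <- guard + 1L
  }
  times <- sort(times)

  env_len <- round(cfg$burst_dur * cfg$sfreq)
  env <- hann_window(env_len)
  tt <- (seq_len(env_len) - (env_len + 1) / 2) / cfg$sfreq
  wav <- matrix(0, k, n_samp)
  amp <- ifelse(space$kind[pick] == "cortical", cfg$amp_cortical, cfg$amp_hippocampal)
  for (b in times) {
    c0 <- round(b * cfg$sfreq)
    idx <- c0 + seq_len(env_len) - round(env_len / 2)
    ok <- idx >= 1L & idx <= n_samp
    for (j in seq_len(k)) {
      wav[j, idx[ok]] <- wav[j, idx[ok]] +
        amp[j] * env[ok] * cos(2 * pi * cfg$burst_freq * tt[ok] + phase_offsets[j])
    }
  }
  moments <- matrix(0, 3L, k)
  for (j in seq_len(k)) {
    s <- pick[j]
    moments[, j] <- if (space$kind[s] == "cortical") space$ori[s, ] else {
      o <- c(0.4, 0.5, 0.768); o / sqrt(sum(o^2))
    }
  }
  structure(list(active_indices = pick, moments = moments, waveforms = wav,
                 burst_times = times, burst_freq = cfg$burst_freq,
                 regions = active_regions, sfreq = cfg$sfreq),
            class = "ground_truth")
}

# sensor topographies (rows of a gain matrix) for ground-truth sources
truth_topographies <- function(leadfield, truth, gain = leadfield$gain) {
  k <- length(truth$active_indices)
  topo <- matrix(0, nrow(gain), k)
  for (j in seq_len(k)) {
    cols <- which(leadfield$col_source == truth$active_indices[j])
    if (length(cols) == 1L) {
      topo[, j] <- gain[, cols]
    } else {
      topo[, j] <- gain[, cols, drop = FALSE] %*%
        as.numeric(t(leadfield$col_moment[, cols]) %*% truth$moments[, j])
    }
  }
  topo
}

#' Simulate a multichannel resting EEG recording
#'
#' Sensor data are `gain x waveforms` plus source-projected 1/f background
#' activity, white sensor noise, and blink artifacts projected through a
#' frontal topography. EOG channels carry the blink signal. The noise is
#' scaled so that the sensor-space SNR over burst windows equals
#' `cfg$snr_db`; the realized scaling is recorded in the log.
#'
#' @param leadfield a [compute_leadfield()] result
#' @param truth a [make_ground_truth()] result (or NULL for noise only)
#' @param cfg a [simulation_config()]
#' @return object of class `eeg_recording`: `data` (channels x samples, V),
#'   `sfreq`, `labels`, `roles`, `bad`, `log`
#' @export
simulate_recording <- function(leadfield, truth, cfg) {
  set.seed(cfg$seed + 1L)
  sensors <- leadfield$sensors
  space <- leadfield$space
  n_samp <- round(cfg$duration * cfg$sfreq)
  n_eeg <- sum(sensors$roles == "eeg")

  n_eog <- sum(sensors$roles != "eeg")
  signal <- matrix(0, n_eeg, n_samp)
  signal_eog <- matrix(0, n_eog, n_samp)
  burst_mask <- rep(FALSE, n_samp)
  if (!is.null(truth)) {
    stopifnot(ncol(truth$waveforms) == n_samp)
    signal <- truth_topographies(leadfield, truth) %*% truth$waveforms
    if (n_eog > 0)
      signal_eog <- truth_topographies(leadfield, truth,
                                       leadfield$gain_eog) %*% truth$waveforms
    half <- round(cfg$burst_dur * cfg$sfreq / 2)
    for (b in truth$burst_times) {
      c0 <- round(b * cfg$sfreq)
      burst_mask[max(1L, c0 - half):min(n_samp, c0 + half)] <- TRUE
    }
  }

  # background: pink time courses on random cortical sources (projected to
  # scalp and EOG sites alike)
  noise <- matrix(0, n_eeg, n_samp)
  noise_eog <- matrix(0, n_eog, n_samp)
  cand <- setdiff(which(space$kind == "cortical"),
                  if (is.null(truth)) integer(0) else truth$active_indices)
  n_noise <- min(cfg$n_noise_sources, length(cand))
  if (n_noise > 0 && cfg$snr_db < Inf) {
    src <- sample(cand, n_noise)
    cols <- match(src, leadfield$col_source)  # cortical: one column each
    tc <- pink_noise_mat(n_noise, n_samp, cfg$noise_exponent) *
      cfg$amp_cortical * 0.3
    noise <- leadfield$gain[, cols, drop = FALSE] %*% tc
    if (n_eog > 0)
      noise_eog <- leadfield$gain_eog[, cols, drop = FALSE] %*% tc
  }
  white <- matrix(stats::rnorm(n_eeg * n_samp), n_eeg, n_samp)
  white_eog <- matrix(stats::rnorm(n_eog * n_samp), n_eog, n_samp)

  noise_scale <- 0
  if (!is.null(truth) && any(burst_mask) && is.finite(cfg$snr_db)) {
    p_sig <- mean(signal[, burst_mask]^2)
    if (p_sig > 0) {
      p_target <- p_sig / 10^(cfg$snr_db / 10)
      p_brain <- mean(noise[, burst_mask]^2)
      brain_scale <- if (p_brain > 0)
        sqrt(p_target * (1 - cfg$white_noise_ratio) / p_brain) else 0
      white_scale <- sqrt(p_target * cfg$white_noise_ratio)
      noise <- noise * brain_scale + white * white_scale
      noise_eog <- noise_eog * brain_scale + white_eog * white_scale
      noise_scale <- brain_scale
    }
  } else if (is.null(truth)) {
    # noise-only recording: keep natural scale plus proportional white noise
    w <- sqrt(cfg$white_noise_ratio * mean(noise^2))
    noise <- noise + white * w
    noise_eog <- noise_eog + white_eog * w
  }
  data_eeg <- signal + noise
  data_eog <- signal_eog + noise_eog

  # blink artifacts through a fixed frontal topography
  eeg_pos <- sensors$positions[sensors$roles == "eeg", , drop = FALSE]
  eye_dir <- c(0, 0.95, 0.31) / sqrt(sum(c(0, 0.95, 0.31)^2))
  w_blink <- pmax(0, unit_rows(eeg_pos) %*% eye_dir)^3
  n_blink <- stats::rpois(1L, cfg$blink_rate * cfg$duration / 60)
  blink_tc <- numeric(n_samp)
  if (n_blink > 0) {
    bt <- sort(stats::runif(n_blink, 1, cfg$duration - 1))
    sd_s <- 0.06 * cfg$sfreq
    for (b in bt) {
      c0 <- round(b * cfg$sfreq)
      idx <- max(1L, c0 - round(3 * sd_s)):min(n_samp, c0 + round(3 * sd_s))
      blink_tc[idx] <- blink_tc[idx] + exp(-(idx - c0)^2 / (2 * sd_s^2))
    }
  } else bt <- numeric(0)
  blink_amp <- 100e-6
  data_eeg <- data_eeg + (w_blink * blink_amp) %*% t(blink_tc)

  # EOG channels: the scalp field at the EOG site plus a strong blink
  # (vertical) or small blink spill (horizontal)
  data <- matrix(0, length(sensors$labels), n_samp)
  data[sensors$roles == "eeg", ] <- data_eeg
  eog_roles <- sensors$roles[sensors$roles != "eeg"]
  for (j in seq_len(n_eog)) {
    bg <- if (eog_roles[j] == "eog_v") 4 else 0.3
    data[which(sensors$roles != "eeg")[j], ] <-
      data_eog[j, ] + bg * blink_amp * blink_tc
  }

  structure(list(data = data, sfreq = cfg$sfreq, labels = sensors$labels,
                 roles = sensors$roles, bad = character(0),
                 log = list(stages = "simulate",
                            n_bursts = if (is.null(truth)) 0L else length(truth$burst_times),
                            n_blinks = n_blink, blink_times = bt,
                            snr_db = cfg$snr_db, brain_noise_scale = noise_scale,
                            seed = cfg$seed)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$sfreq, " Hz (",
      round(ncol(x$data) / x$sfreq, 1), " s); stages: ",
      paste(x$log$stages, collapse = " -> "), "\n", sep = "")
  invisible(x)
}
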