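make_rec <- function(data, rate, roles = NULL) {
  structure(list(data = data, sfreq = rate,
                 labels = sprintf("EEG%03d", seq_len(nrow(data))),
                 roles = roles %||% rep("eeg", nrow(data)),
                 bad = character(0), log = list(stages = "test")),
            class = "eeg_recording")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("resampling preserves duration, passband tones, and rejects aliases", {
  t <- seq(0, 60 - 1e-3, by = 1e-3)                 # 60 s at 1000 Hz
  x <- rbind(sin(2 * pi * 5 * t), sin(2 * pi * 95 * t))
  rec <- resample_recording(make_rec(x, 1000), 200)
  expect_equal(rec$sfreq, 200)
  expect_equal(ncol(rec$data), 60 * 200)            # duration preserved
  mid <- 2000:10000
  amp5 <- max(abs(rec$data[1, mid]))
  expect_lt(abs(amp5 - 1), 0.01)                    # 5 Hz passthrough
  att95 <- 20 * log10(max(abs(rec$data[2, mid])))
  expect_lt(att95, -40)                             # >= 40 dB attenuation
  expect_error(resample_recording(make_rec(x, 1000), 1000), "upsampling")
  expect_error(resample_recording(make_rec(x, 1000), 300), "integer")
})

test_that("FIR bandpass design follows the stated transition/length rules", {
  fs <- design_fir_bandpass(0.3, 30, 200)
  expect_identical(fs$taps, 2201L)
  expect_equal(fs$tb_low, 0.3)
  expect_equal(fs$tb_high, 7.5)
  # second design worked by hand from the rule: tb_low = 1 Hz -> 661 taps
  fs2 <- design_fir_bandpass(1, 30, 200)
  expect_equal(fs2$tb_low, 1)
  expect_identical(fs2$taps, 661L)
  # linear phase: palindromic coefficients
  expect_equal(fs$coef, rev(fs$coef), tolerance = 1e-15)
  expect_error(design_fir_bandpass(30, 0.3, 200), "invalid argument")
})

test_that("the 0.3-30 Hz design is zero-phase with strong DC/Nyquist rejection", {
  fs <- design_fir_bandpass(0.3, 30, 200)
  fr <- fir_frequency_response(fs)
  expect_lt(20 * log10(fr$amplitude[1] + 1e-300), -50)             # DC
  expect_lt(20 * log10(fr$amplitude[nrow(fr)] + 1e-300), -50)      # ~Nyquist
  # zero phase: cross-correlation of filtered vs raw in-band tone peaks at 0
  t <- seq(0, 30 - 1 / 200, by = 1 / 200)
  x <- sin(2 * pi * 6 * t)
  y <- apply_fir(x, fs)
  cc <- ccf(y[1000:5000], x[1000:5000], lag.max = 8, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_lt(abs(max(abs(y[1000:5000])) - 1), 0.01)  # passband gain ~ 1
})

test_that("bad channels are flagged by the neighbour-correlation rule", {
  s <- small_setup()
  n_eeg <- sum(s$sensors$roles == "eeg")
  nb <- channel_neighbors(s$sensors)
  flagged_noise <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    base <- matrix(rnorm(5000), 1)
    # correlated recording: shared signal + small channel noise
    x <- matrix(rep(base, n_eeg), n_eeg, byrow = TRUE) +
      0.2 * matrix(rnorm(n_eeg * 5000), n_eeg)
    bad_ch <- 5L
    x[bad_ch, ] <- rnorm(5000)                      # independent noise
    rec <- make_rec(x, 200)
    bad <- detect_bad_channels(rec, neighbors = nb)
    if (sprintf("EEG%03d", bad_ch) %in% bad) flagged_noise <- flagged_noise + 1L
    # a channel duplicated from its neighbour is never flagged
    x2 <- x
    x2[bad_ch, ] <- x2[nb[[bad_ch]][1L], ]
    expect_false(sprintf("EEG%03d", bad_ch) %in%
                   detect_bad_channels(make_rec(x2, 200), neighbors = nb))
  }
  expect_equal(flagged_noise, 20L)
  # boundary: threshold 0 flags only zero-variance channels
  set.seed(1)
  x <- matrix(rnorm(24 * 1000), 24)
  x[3, ] <- 0
  bad0 <- detect_bad_channels(make_rec(x, 200), neighbors = nb, threshold = 0)
  expect_identical(bad0, "EEG003")
})

test_that("ICA rejection removes blink components and spares clean data", {
  s <- study_setup()
  cfg <- simulation_config(seed = 21L, sfreq = 200, duration = 40,
                           snr_db = 0, blink_rate = 12)
  truth <- make_ground_truth(s$space, cfg)
  rec <- simulate_recording(s$leadfield, truth, cfg)
  cfg0 <- cfg
  cfg0$blink_rate <- 0
  rec0 <- simulate_recording(s$leadfield, truth, cfg0)  # same seed, no blinks
  clean <- reject_ocular_components(rec, s$sensors, seed = 1L)
  expect_gte(length(clean$log$ica$rejected), 1L)
  # frontal blink residual reduced by >= 80% relative to the artifact
  eeg_pos <- s$sensors$positions[s$sensors$roles == "eeg", ]
  frontal <- which.max(eeg_pos[, 2])
  art_before <- rec$data[frontal, ] - rec0$data[frontal, ]
  art_after <- clean$data[frontal, ] - rec0$data[frontal, ]
  expect_lte(sqrt(mean(art_after^2)), 0.2 * sqrt(mean(art_before^2)))

  # threshold 1 rejects nothing
  none <- reject_ocular_components(rec, s$sensors, threshold = 1, seed = 1L)
  expect_length(none$log$ica$rejected, 0L)
  expect_error(reject_ocular_components(make_rec(rec$data[1:5, ], 200)),
               "EOG")
})

test_that("clean recordings yield no rejected components in most runs", {
  s <- study_setup()
  rejected <- vapply(1:10, function(seed) {
    cfg <- simulation_config(seed = 100L + seed, sfreq = 200, duration = 30,
                             snr_db = 0, blink_rate = 0)
    truth <- make_ground_truth(s$space, cfg)
    rec <- simulate_recording(s$leadfield, truth, cfg)
    length(reject_ocular_components(rec, s$sensors,
                                    seed = seed)$log$ica$rejected)
  }, numeric(1L))
  expect_gte(mean(rejected == 0L), 0.9)
})

test_that("average reference zeroes the sensor mean and is idempotent", {
  set.seed(2)
  x <- matrix(rnorm(12 * 500), 12)
  rec <- apply_average_reference(make_rec(x, 200))
  expect_lt(max(abs(colMeans(rec$data))), 1e-12)
  rec2 <- apply_average_reference(rec)
  expect_equal(rec2$data, rec$data, tolerance = 1e-14)
  expect_error(apply_average_reference(make_rec(x[1, , drop = FALSE], 200)),
               ">= 2")
})

test_that("the preprocessing pipeline runs its stages in the stated order", {
  s <- small_setup()
  cfg <- simulation_config(seed = 31L, sfreq = 1000, duration = 30,
                           snr_db = 0, blink_rate = 8)
  truth <- make_ground_truth(s$space, cfg)
  rec <- simulate_recording(s$leadfield, truth, cfg)
  clean <- preprocess_recording(rec, s$sensors, seed = 1L)
  stages <- clean$log$stages
  expect_equal(stages[stages %in% c("resample", "filter", "bad_channels",
                                    "ica_rejection")],
               c("resample", "filter", "bad_channels", "ica_rejection"))
  expect_equal(clean$sfreq, 200)
})
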