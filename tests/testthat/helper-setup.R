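# memoized geometry/leadfields shared across test files (built in code,
# no stored fixtures)

.ts_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.ts_cache[[key]])) .ts_cache[[key]] <- force(expr)
  .ts_cache[[key]]
}

study_setup <- function() {
  cached("study", {
    hm <- head_model()
    g <- build_geometry(62L, 3L, head = hm)
    list(head = hm, sensors = g$sensors, space = g$space,
         leadfield = compute_leadfield(hm, g$sensors, g$space))
  })
}

small_setup <- function() {
  cached("small", {
    hm <- head_model()
    g <- build_geometry(24L, 2L, head = hm)
    list(head = hm, sensors = g$sensors, space = g$space,
         leadfield = compute_leadfield(hm, g$sensors, g$space))
  })
}

# short test recording with planted bursts (shared by several files)
test_recording <- function(seed = 1L, snr_db = 10, duration = 120,
                           blink_rate = 0, key = NULL) {
  build <- function() {
    s <- study_setup()
    cfg <- simulation_config(seed = seed, sfreq = 200, duration = duration,
                             snr_db = snr_db, blink_rate = blink_rate)
    truth <- make_ground_truth(s$space, cfg)
    rec <- simulate_recording(s$leadfield, truth, cfg)
    rec <- apply_fir(rec, design_fir_bandpass(0.3, 30, rec$sfreq))
    list(rec = rec, truth = truth, cfg = cfg)
  }
  if (is.null(key)) build() else cached(key, build())
}
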