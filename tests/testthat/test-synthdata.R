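test_that("icosahedral subdivision vertex counts follow 10*4^L + 2", {
  for (lev in 0:3) {
    ic <- icosphere(lev)
    expect_equal(nrow(ic$vertices), 10 * 4^lev + 2)
    expect_equal(unname(sqrt(rowSums(ic$vertices^2))),
                 rep(1, nrow(ic$vertices)), tolerance = 1e-12)
  }
})

test_that("geometry: per-hemisphere vertex counts, hippocampal grids, errors", {
  g <- build_geometry(32L, 1L)
  cort <- g$space$kind == "cortical"
  expect_equal(sum(cort & g$space$hemisphere == "L"), 42)
  expect_equal(sum(cort & g$space$hemisphere == "R"), 42)
  g2 <- build_geometry(32L, 2L)
  expect_equal(sum(g2$space$kind == "cortical"), 2 * 162)

  # hippocampal grid: 5 x 3 x 3 = 45 candidate points per structure at
  # 5-mm spacing (direct counting oracle: expand.grid dimensions)
  for (h in c("L", "R")) {
    idx <- g$space$region == paste0("hippocampus-", h)
    expect_equal(sum(idx), 45)
    pts <- g$space$pos[idx, ]
    d <- as.matrix(dist(pts))
    nn <- apply(d + diag(Inf, nrow(d)), 1L, min)
    expect_equal(unname(nn), rep(0.005, 45), tolerance = 1e-9)
    expect_true(all(sqrt(rowSums(pts^2)) <
                      thetasource:::cortex_radius(head_model())))
  }
  # mirrored placement (as point sets)
  pl <- g$space$pos[g$space$region == "hippocampus-L", ]
  pr <- g$space$pos[g$space$region == "hippocampus-R", ]
  mirr <- pr %*% diag(c(-1, 1, 1))
  ord <- function(m) unname(m[order(m[, 1], m[, 2], m[, 3]), ])
  expect_equal(ord(pl), ord(mirr), tolerance = 1e-12)

  expect_equal(sum(table(g$space$region[cort])), sum(cort)) # one label each
  expect_error(build_geometry(32L, 0L), "ico_level")
  expect_error(build_geometry(8L, 1L), "n_eeg")
  expect_error(build_geometry(9999L, 1L), "capacity")
})

test_that("dipole potential: zero moment, central-dipole symmetry, geometry errors", {
  hm <- head_model()
  el <- icosphere(1)$vertices * 0.09
  expect_equal(dipole_potential(hm, c(0.02, 0, 0.01), c(0, 0, 0), el),
               rep(0, nrow(el)))
  # radial dipole on the z-axis: sensors equidistant from the axis get
  # equal potentials
  theta <- pi / 3
  ring <- cbind(0.09 * sin(theta) * cos(seq(0, 2 * pi, length.out = 7)[-7]),
                0.09 * sin(theta) * sin(seq(0, 2 * pi, length.out = 7)[-7]),
                0.09 * cos(theta))
  v <- dipole_potential(hm, c(0, 0, 0.03), c(0, 0, 1e-8), ring)
  expect_lt(diff(range(v)) / max(abs(v)), 1e-10)
  # dipole at the centre: classical 3 q cos(gamma) / (4 pi sigma R^2)
  vc <- dipole_potential(hm, c(0, 0, 0), c(0, 0, 1e-8), ring)
  expect_equal(vc, rep(3 * 1e-8 * cos(theta) / (4 * pi * 0.33 * 0.09^2), 6),
               tolerance = 1e-10)
  expect_error(dipole_potential(hm, c(0, 0, 0.095), c(0, 0, 1e-8), ring),
               "invalid geometry")
})

test_that("analytic dipole potential matches a boundary-integral oracle", {
  hm <- head_model()
  for (mom in list(c(0, 0, 1e-8), c(1e-8, 0, 0))) {  # radial and tangential
    b <- bem_surface_potential(hm, c(0, 0, 0.045), mom, level = 3)
    vs <- dipole_potential(hm, c(0, 0, 0.045), mom, b$points)
    vs <- vs - mean(vs)
    expect_lt(sqrt(sum((b$V - vs)^2) / sum(vs^2)), 0.01)
  }
})

test_that("three-shell leadfield reduces to the homogeneous one when shells match", {
  hm3 <- head_model(radii = c(0.07, 0.08, 0.09),
                    conductivities = c(0.33, 0.33, 0.33))
  hm1 <- head_model()
  el <- icosphere(1)$vertices * 0.09
  v3 <- dipole_potential(hm3, c(0.01, 0.02, 0.03), c(1e-8, -2e-8, 5e-9), el)
  v1 <- dipole_potential(hm1, c(0.01, 0.02, 0.03), c(1e-8, -2e-8, 5e-9), el)
  expect_equal(v3, v1, tolerance = 1e-8)
  # a resistive skull attenuates the scalp potential
  v_skull <- dipole_potential(head_model("three"), c(0, 0, 0.04),
                              c(0, 0, 1e-8), el)
  v_open <- dipole_potential(head_model(radii = 0.09, conductivities = 0.33),
                             c(0, 0, 0.04), c(0, 0, 1e-8), el)
  expect_lt(max(abs(v_skull)), max(abs(v_open)))
})

test_that("leadfield columns are average-referenced and mapped per source", {
  s <- small_setup()
  lf <- s$leadfield
  expect_equal(nrow(lf$gain), sum(s$sensors$roles == "eeg"))
  expect_lt(max(abs(colMeans(lf$gain))), 1e-12 * max(abs(lf$gain)))
  expect_equal(sum(lf$orientation_mode == "fixed"),
               sum(s$space$kind == "cortical"))
  n_sub <- sum(s$space$kind == "subcortical")
  expect_equal(ncol(lf$gain), sum(s$space$kind == "cortical") + 3L * n_sub)
})

test_that("simulated recordings: exactness without noise, determinism, linearity", {
  s <- small_setup()
  cfg <- simulation_config(seed = 3L, sfreq = 200, duration = 20,
                           snr_db = Inf, blink_rate = 0)
  truth <- make_ground_truth(s$space, cfg)
  rec <- simulate_recording(s$leadfield, truth, cfg)
  eeg <- rec$roles == "eeg"
  expected <- thetasource:::truth_topographies(s$leadfield, truth) %*% truth$waveforms
  expect_equal(rec$data[eeg, ], expected, tolerance = 1e-12)
  # average-reference property of noise-free data
  expect_lt(max(abs(colMeans(rec$data[eeg, ]))), 1e-12 * max(abs(rec$data)))
  # seeded determinism
  rec2 <- simulate_recording(s$leadfield, truth, cfg)
  expect_identical(rec$data, rec2$data)
  # leadfield linearity: doubling the waveforms doubles the recording
  truth2 <- truth
  truth2$waveforms <- 2 * truth$waveforms
  rec3 <- simulate_recording(s$leadfield, truth2, cfg)
  expect_equal(rec3$data[eeg, ], 2 * rec$data[eeg, ], tolerance = 1e-12)
})

test_that("burst counts are Poisson at the configured rate", {
  s <- small_setup()
  counts <- vapply(1:100, function(sd) {
    cfg <- simulation_config(seed = sd, sfreq = 200, duration = 360)
    length(make_ground_truth(s$space, cfg)$burst_times)
  }, numeric(1L))
  lam <- 100 * 6 * 6   # 100 seeds x 6/min x 6 min
  ci <- qpois(c(0.005, 0.995), lam)
  expect_gte(sum(counts), ci[1L])
  expect_lte(sum(counts), ci[2L])
})

test_that("study tables: counterbalancing and effect recovery by least squares", {
  cfg <- simulation_config(seed = 5L)
  tab <- simulate_study_table(cfg)
  expect_equal(nrow(tab), 40)
  cfg_odd <- cfg
  cfg_odd$n_participants <- 19L
  expect_error(simulate_study_table(cfg_odd), "even")
  expect_equal(unname(table(tab$order)["stim-sham"]) / 2, 10)
  expect_true(all(table(tab$participant, tab$condition) == 1))
  expect_true(all(tab$memory >= 0 & tab$memory <= 100))

  # interaction recovery: closed-form least-squares oracle on a large study
  cfg2 <- simulation_config(seed = 7L, n_participants = 200L,
                            beta = list(intercept = 0, condition = 0.2,
                                        memory = 0, interaction = 0.5,
                                        baseline = 0, order = 0, visit = 0),
                            sigma_u = 0.05, sigma_e = 0.05)
  tab2 <- simulate_study_table(cfg2)
  cc <- ifelse(tab2$condition == "verum", 0.5, -0.5)
  mem <- tab2$memory - 75
  fit <- lm(outcome ~ cc + mem + cc:mem, data = data.frame(tab2, cc, mem))
  expect_lt(abs(coef(fit)[["cc:mem"]] - 0.5), 0.05)

  # all-zero effects with no participant variance: i.i.d. noise
  cfg3 <- simulation_config(seed = 11L, n_participants = 100L,
                            beta = list(intercept = 0, condition = 0,
                                        memory = 0, interaction = 0,
                                        baseline = 0, order = 0, visit = 0),
                            sigma_u = 0, sigma_e = 1)
  tab3 <- simulate_study_table(cfg3)
  cc3 <- ifelse(tab3$condition == "verum", 0.5, -0.5)
  fit3 <- summary(lm(tab3$outcome ~ cc3))
  expect_lt(abs(fit3$coefficients["cc3", "t value"]), 3)
})
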