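#' Spherical head model
#'
#' A concentric-shell conductor model standing in for subject-specific
#' boundary element models. The default is a single homogeneous sphere
#' (scalp radius 9 cm, conductivity 0.33 S/m); a three-shell
#' brain/skull/scalp model is available via `shells = "three"`.
#'
#' @param shells `"single"` or `"three"`, or ignored when `radii` given
#' @param radii shell radii in metres, innermost to outermost
#' @param conductivities conductivity in S/m for each shell
#' @param center head centre (3-vector, metres)
#' @return an object of class `head_model`
#' @export
#' @examples
#' head_model()
#' head_model("three")
head_model <- function(shells = c("single", "three"), radii = NULL,
                       conductivities = NULL, center = c(0, 0, 0)) {
  if (is.null(radii)) {
    shells <- match.arg(shells)
    if (shells == "single") {
      radii <- 0.09
      conductivities <- 0.33
    } else {
      radii <- c(0.08, 0.085, 0.09)
      conductivities <- c(0.33, 0.0042, 0.33)
    }
  }
  stopifnot(length(radii) >= 1L, length(radii) == length(conductivities))
  if (any(diff(radii) <= 0)) stop("shell radii must be strictly increasing")
  if (any(conductivities <= 0)) stop("conductivities must be > 0")
  structure(list(shell_radii = radii, conductivities = conductivities,
                 center = center),
            class = "head_model")
}

# radius of the surface on which cortical structures are anchored
cortex_radius <- function(head) 0.78 * head$shell_radii[1L]

#' Icosahedral sphere subdivision
#'
#' Recursively subdivides an icosahedron `level` times and projects the
#' vertices onto the unit sphere, yielding `10 * 4^level + 2` vertices.
#'
#' @param level subdivision level (0 = icosahedron)
#' @return list with `vertices` (n x 3, unit norm) and `faces` (m x 3 indices)
#' @export
icosphere <- function(level = 1L) {
  stopifnot(level >= 0L)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- unit_rows(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    mid_cache <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- mid_cache[[key]]
      if (!is.null(idx)) return(idx)
      m <- (verts[i, ] + verts[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      mid_cache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c_ <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[(k - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                           c(c_, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- newf
  }
  list(vertices = v, faces = f)
}

# anatomical labels for a hemisphere icosphere in local unit coordinates
# (+y anterior, +z superior, lateral = away from the midline). "temporal"
# is the lateral band (superior/middle temporal surface); the ventral
# surface gets its own label. Every vertex gets exactly one label.
hemi_region <- function(u, hemi) {
  lx <- u[, 1] * if (hemi == "L") -1 else 1   # >0 lateral
  lab <- rep("parietal", nrow(u))
  lab[u[, 2] > 0.35 & u[, 3] > 0.2] <- "superior-frontal"
  lab[u[, 2] > 0.35 & u[, 3] <= 0.2] <- "middle-frontal"
  lab[u[, 2] < -0.5 & lab == "parietal"] <- "occipital"
  lab[u[, 2] <= 0.35 & u[, 2] >= -0.5 & lx > 0.55 & u[, 3] < 0.3] <- "temporal"
  lab[u[, 3] < -0.55 & lab != "temporal"] <- "ventral"
  paste0(lab, "-", hemi)
}

#' Build sensor and source geometry on a spherical head
#'
#' Places `n_eeg` EEG electrodes quasi-uniformly on the scalp shell (plus a
#' vertical and a horizontal EOG electrode when `eog = TRUE`), models each
#' cortical hemisphere as a closed level-`ico_level` icosahedral surface with
#' outward-normal source orientations, and adds one volumetric hippocampal
#' grid per hemisphere (20 x 10 x 10 mm box, 5-mm spacing, 45 candidate
#' points before inside-shell masking) at 60% of the cortex-shell radius.
#'
#' @param n_eeg number of scalp EEG electrodes (>= 16)
#' @param ico_level icosahedral subdivision level of the dense cortical
#'   surfaces (>= 1); each hemisphere gets `10 * 4^ico_level + 2` vertices
#' @param head a [head_model()]
#' @param eog add EOG channels (default TRUE)
#' @param hemi_radius_frac radius of each hemispheric surface as a
#'   fraction of the cortex-shell radius
#' @param hemi_z_frac vertical offset of the hemisphere centres (fraction
#'   of the cortex-shell radius); raising the hemispheres leaves a ventral
#'   gap for the subcortical structures
#' @param hippo_dir direction (right hemisphere) of the hippocampal
#'   cluster centre, placed at 60% of the cortex-shell radius
#' @return list with elements `sensors` (class `sensor_array`) and
#'   `space` (class `source_space`)
#' @export
#' @examples
#' g <- build_geometry(32, 1)
#' sum(g$space$kind == "cortical") # 2 * 42
build_geometry <- function(n_eeg = 62L, ico_level = 3L, head = head_model(),
                           eog = TRUE, hemi_radius_frac = 0.40,
                           hemi_z_frac = 0.10,
                           hippo_dir = c(0.62, -0.45, -0.64)) {
  if (ico_level < 1L) stop("invalid argument: ico_level must be >= 1")
  if (n_eeg < 16L) stop("invalid argument: n_eeg must be >= 16")
  R <- head$shell_radii[length(head$shell_radii)]
  if (n_eeg > 256L) stop("invalid argument: n_eeg exceeds layout capacity")

  # Fibonacci spiral on a spherical cap; coverage extends well below the
  # equator (inferior temporal / mastoid-level sites), which is what gives
  # scalp EEG its sensitivity to deep sources
  i <- seq_len(n_eeg)
  t <- (i - 0.5) / n_eeg
  z <- R * (1 - 1.55 * t)          # from vertex down to z = -0.55 R
  rho <- sqrt(pmax(R^2 - z^2, 0))
  golden <- pi * (3 - sqrt(5))
  az <- golden * i
  pos <- cbind(rho * cos(az), rho * sin(az), z)
  labels <- sprintf("EEG%03d", i)
  roles <- rep("eeg", n_eeg)
  if (eog) {
    veog <- R * c(-0.30, 0.87, -0.39) / sqrt(sum(c(0.30, 0.87, 0.39)^2))
    heog <- R * c(0.74, 0.62, -0.26) / sqrt(sum(c(0.74, 0.62, 0.26)^2))
    pos <- rbind(pos, veog, heog)
    labels <- c(labels, "VEOG", "HEOG")
    roles <- c(roles, "eog_v", "eog_h")
  }
  rownames(pos) <- NULL
  sensors <- structure(list(positions = pos, labels = labels, roles = roles,
                            scalp_radius = R),
                       class = "sensor_array")

  # per-hemisphere closed cortical surfaces, raised so the ventral gap
  # leaves room for the subcortical structures below
  Rc <- cortex_radius(head)
  rh <- hemi_radius_frac * Rc
  ctr <- list(L = c(-0.50 * Rc, 0, hemi_z_frac * Rc),
              R = c(0.50 * Rc, 0, hemi_z_frac * Rc))
  ico <- icosphere(ico_level)
  u <- ico$vertices
  cort_pos <- NULL; cort_ori <- NULL; cort_reg <- NULL; cort_hemi <- NULL
  for (h in c("L", "R")) {
    cort_pos <- rbind(cort_pos, sweep(u * rh, 2L, ctr[[h]], `+`))
    cort_ori <- rbind(cort_ori, u)
    cort_reg <- c(cort_reg, hemi_region(u, h))
    cort_hemi <- c(cort_hemi, rep(h, nrow(u)))
  }

  # hippocampal volumetric grids: 20 x 10 x 10 mm box, 5-mm spacing,
  # mirrored deep clusters at 60% of the cortex-shell radius
  hdir <- hippo_dir / sqrt(sum(hippo_dir^2))
  spacing <- 0.005
  gx <- seq(-0.005, 0.005, by = spacing)
  gy <- seq(-0.010, 0.010, by = spacing)
  gz <- seq(-0.005, 0.005, by = spacing)
  box <- as.matrix(expand.grid(x = gx, y = gy, z = gz))[, c("x", "y", "z")]
  sub_pos <- NULL; sub_hemi <- NULL
  for (h in c("L", "R")) {
    d <- hdir * c(if (h == "L") -1 else 1, 1, 1)
    centre <- 0.6 * Rc * d
    pts <- sweep(box, 2L, centre, `+`)
    keep <- row_norms(pts) < Rc          # inside-shell masking
    sub_pos <- rbind(sub_pos, pts[keep, , drop = FALSE])
    sub_hemi <- c(sub_hemi, rep(h, sum(keep)))
  }
  n_c <- nrow(cort_pos); n_s <- nrow(sub_pos)
  space <- structure(list(
    pos = rbind(cort_pos, sub_pos),
    ori = rbind(cort_ori, matrix(NA_real_, n_s, 3L)),
    kind = c(rep("cortical", n_c), rep("subcortical", n_s)),
    hemisphere = c(cort_hemi, sub_hemi),
    region = c(cort_reg, paste0("hippocampus-", sub_hemi)),
    ico_level = ico_level,
    hemi_centers = ctr, hemi_radius = rh,
    grid_spacing = spacing, cortex_radius = Rc),
    class = "source_space")
  rownames(space$pos) <- NULL
  list(sensors = sensors, space = space)
}

#' @export
print.source_space <- function(x, ...) {
  cat("<source_space> ", sum(x$kind == "cortical"), " cortical (ico",
      x$ico_level, " per hemisphere), ", sum(x$kind == "subcortical"),
      " subcortical grid points\n", sep = "")
  invisible(x)
}

#' @export
print.sensor_array <- function(x, ...) {
  cat("<sensor_array> ", sum(x$roles == "eeg"), " EEG + ",
      sum(x$roles != "eeg"), " EOG sensors on R = ", x$scalp_radius, " m\n",
      sep = "")
  invisible(x)
}
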