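# Analytic forward model: current dipole in a concentric spherical conductor.
#
# The surface potential is computed from the Legendre series
#   V = (1/(4*pi*sigma1)) * sum_n r0^(n-1) v_n [ n q_r P_n(x) + Q_n(x) (e.t) ]
# with x = cos(angle between source and electrode directions), Q_n = P_n',
# q_r the radial moment, t the tangential moment vector, and v_n the
# per-degree shell transfer coefficient. For a homogeneous sphere
# v_n = (2n+1)/(n R^(n+1)); for multi-shell models v_n is obtained by
# solving the interface conditions (potential and radial current continuous,
# zero radial current at the scalp) degree by degree.

# per-degree transfer coefficients v_n for a head model
shell_coefficients <- function(head, n_terms) {
  R <- head$shell_radii
  sig <- head$conductivities
  K <- length(R)
  v <- numeric(n_terms)
  if (K == 1L) {
    n <- seq_len(n_terms)
    v <- (2 * n + 1) / (n * R^(n + 1))
    return(v)
  }
  for (n in seq_len(n_terms)) {
    # unknowns: a_1, then (a_k, b_k) for k = 2..K ; source term b_1.
    # Columns are scaled (a_k by its shell's outer radius, b_k by its
    # inner interface radius) and the source by R_1^(n+1), so all matrix
    # entries are O(n) and the solve stays well conditioned at high n.
    p <- 2L * (K - 1L) + 1L
    A <- matrix(0, p, p)
    rhs <- numeric(p)
    idx_a <- function(k) if (k == 1L) 1L else 2L * (k - 1L)
    idx_b <- function(k) 2L * (k - 1L) + 1L   # k >= 2
    row <- 0L
    for (k in seq_len(K - 1L)) {
      r <- R[k]
      # continuity of V at interface k/k+1 (row scaled by 1)
      row <- row + 1L
      A[row, idx_a(k)] <- (r / R[k])^n                      # = 1
      if (k > 1L) A[row, idx_b(k)] <- (R[k - 1L] / r)^(n + 1)
      A[row, idx_a(k + 1L)] <- -(r / R[k + 1L])^n
      A[row, idx_b(k + 1L)] <- -(R[k] / r)^(n + 1)          # = -1
      if (k == 1L) rhs[row] <- -(R[1L] / r)^(n + 1)         # = -1
      # continuity of sigma dV/dr (row scaled by r)
      row <- row + 1L
      A[row, idx_a(k)] <- sig[k] * n * (r / R[k])^n
      if (k > 1L) A[row, idx_b(k)] <- -sig[k] * (n + 1) * (R[k - 1L] / r)^(n + 1)
      A[row, idx_a(k + 1L)] <- -sig[k + 1L] * n * (r / R[k + 1L])^n
      A[row, idx_b(k + 1L)] <- sig[k + 1L] * (n + 1) * (R[k] / r)^(n + 1)
      if (k == 1L) rhs[row] <- sig[1L] * (n + 1) * (R[1L] / r)^(n + 1)
    }
    # insulating outer boundary at R_K (row scaled by R_K)
    row <- row + 1L
    A[row, idx_a(K)] <- n
    A[row, idx_b(K)] <- -(n + 1) * (R[K - 1L] / R[K])^(n + 1)
    sol <- solve(A, rhs)
    # unscale: a_K true = sol_aK / R_K^n, b_K true = sol_bK * R_{K-1}^(n+1);
    # source unscale multiplies by R_1^-(n+1)
    v[n] <- (sol[idx_a(K)] + sol[idx_b(K)] * (R[K - 1L] / R[K])^(n + 1)) /
      R[1L]^(n + 1)
  }
  v
}

#' Surface potential of a current dipole in a spherical head
#'
#' Evaluates the analytic Legendre-series solution for the electric
#' potential generated on the scalp by a current dipole inside a
#' single- or multi-shell concentric spherical conductor with an
#' insulating outer boundary.
#'
#' @param head a [head_model()]
#' @param pos dipole position (3-vector, metres, head-centred)
#' @param moment dipole moment (3-vector, A m)
#' @param electrodes matrix of electrode positions on the scalp (n x 3)
#' @param n_terms series truncation (default 100)
#' @return potential in volts at each electrode (not referenced)
#' @export
#' @examples
#' hm <- head_model()
#' el <- diag(3) * 0.09
#' dipole_potential(hm, c(0, 0, 0.03), c(0, 0, 1e-8), el)
dipole_potential <- function(head, pos, moment, electrodes, n_terms = 100L) {
  pos <- as.numeric(pos) - head$center
  r0 <- sqrt(sum(pos^2))
  if (r0 >= head$shell_radii[1L]) stop("invalid geometry: source outside innermost shell")
  if (all(moment == 0)) return(rep(0, nrow(electrodes)))
  v <- shell_coefficients(head, n_terms)
  s_hat <- if (r0 < 1e-12) c(0, 0, 1) else pos / r0
  E <- sweep(electrodes, 2L, head$center)
  e_hat <- unit_rows(E)
  x <- as.numeric(e_hat %*% s_hat)
  x <- pmin(pmax(x, -1), 1)
  # accumulate S1 = sum r0^(n-1) v_n n P_n, S2 = sum r0^(n-1) v_n Q_n
  Pm1 <- rep(1, length(x)); P <- x       # P_0, P_1
  Qm1 <- rep(0, length(x)); Q <- rep(1, length(x)) # P_0', P_1'
  S1 <- v[1L] * 1 * P
  S2 <- v[1L] * Q
  rn <- 1
  for (n in 2:n_terms) {
    rn <- rn * r0
    if (rn == 0) break
    Pp1 <- ((2 * n - 1) * x * P - (n - 1) * Pm1) / n
    Qp1 <- Qm1 + (2 * n - 1) * P
    Pm1 <- P; P <- Pp1
    Qm1 <- Q; Q <- Qp1
    S1 <- S1 + rn * v[n] * n * P
    S2 <- S2 + rn * v[n] * Q
  }
  qr <- sum(moment * s_hat)
  tvec <- moment - qr * s_hat
  et <- as.numeric(e_hat %*% tvec)
  (qr * S1 + et * S2) / (4 * pi * head$conductivities[1L])
}

#' Compute the leadfield matrix for a source space
#'
#' One column per source orientation: cortical sources contribute a single
#' column along their fixed surface-normal orientation, subcortical grid
#' points contribute three columns (free orientation). Columns are
#' mean-centred across EEG sensors (average reference).
#'
#' @param head a [head_model()]
#' @param sensors a `sensor_array` from [build_geometry()]
#' @param space a `source_space` from [build_geometry()]
#' @param n_terms Legendre series truncation
#' @return an object of class `leadfield` with fields `gain`
#'   (EEG sensors x columns, V per A m), `col_source` (source index per
#'   column), `col_moment` (3 x columns unit moments), `space`, `sensors`
#' @export
compute_leadfield <- function(head, sensors, space, n_terms = 100L) {
  eeg <- sensors$roles == "eeg"
  el <- sensors$positions           # all sensors incl. EOG sites
  R <- head$shell_radii[length(head$shell_radii)]
  if (any(abs(row_norms(sweep(el[eeg, , drop = FALSE], 2L, head$center)) - R) > 1e-6))
    stop("invalid geometry: EEG sensors not on the scalp shell")
  r0 <- row_norms(sweep(space$pos, 2L, head$center, `-`))
  if (any(r0 >= head$shell_radii[1L]))
    stop("invalid geometry: source outside innermost shell")

  v <- shell_coefficients(head, n_terms)
  sig1 <- head$conductivities[1L]
  e_hat <- unit_rows(sweep(el, 2L, head$center))
  n_src <- nrow(space$pos)
  ncol_per <- ifelse(space$kind == "cortical", 1L, 3L)
  col_source <- rep(seq_len(n_src), ncol_per)
  gain_all <- matrix(0, nrow(el), sum(ncol_per))
  col_moment <- matrix(0, 3L, sum(ncol_per))
  col <- 0L
  for (s in seq_len(n_src)) {
    pos <- space$pos[s, ] - head$center
    rs <- r0[s]
    s_hat <- if (rs < 1e-12) c(0, 0, 1) else pos / rs
    x <- pmin(pmax(as.numeric(e_hat %*% s_hat), -1), 1)
    Pm1 <- rep(1, length(x)); P <- x
    Qm1 <- rep(0, length(x)); Q <- rep(1, length(x))
    S1 <- v[1L] * P
    S2 <- v[1L] * Q
    rn <- 1
    for (n in 2:n_terms) {
      rn <- rn * rs
      if (rn == 0) break
      Pp1 <- ((2 * n - 1) * x * P - (n - 1) * Pm1) / n
      Qp1 <- Qm1 + (2 * n - 1) * P
      Pm1 <- P; P <- Pp1
      Qm1 <- Q; Q <- Qp1
      S1 <- S1 + rn * v[n] * n * P
      S2 <- S2 + rn * v[n] * Q
    }
    moms <- if (space$kind[s] == "cortical") matrix(space$ori[s, ], 1L) else diag(3)
    for (m in seq_len(nrow(moms))) {
      q <- moms[m, ]
      qr <- sum(q * s_hat)
      tvec <- q - qr * s_hat
      pot <- (qr * S1 + as.numeric(e_hat %*% tvec) * S2) / (4 * pi * sig1)
      col <- col + 1L
      gain_all[, col] <- pot - mean(pot[eeg])   # average reference (EEG mean)
      col_moment[, col] <- q
    }
  }
  structure(list(gain = gain_all[eeg, , drop = FALSE],
                 gain_eog = gain_all[!eeg, , drop = FALSE],
                 col_source = col_source, col_moment = col_moment,
                 space = space, sensors = sensors, head = head,
                 orientation_mode = ifelse(space$kind == "cortical", "fixed", "free")),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat("<leadfield> ", nrow(x$gain), " sensors x ", ncol(x$gain), " columns (",
      sum(x$space$kind == "cortical"), " fixed cortical, ",
      sum(x$space$kind == "subcortical"), " free subcortical sources)\n", sep = "")
  invisible(x)
}
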