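# independent numeric oracles used by the tests

# Constant-element collocation BEM for a homogeneous spherical conductor
# with insulating boundary: V = 2 V_inf + (1/2pi) sum_j Omega_ij V_j,
# solid angles by van Oosterom & Strackee, diagonal from the
# closed-surface property, deflation to remove the constant null space.
bem_surface_potential <- function(head, pos, mom, level = 3) {
  R <- head$shell_radii[1L]
  sig <- head$conductivities[1L]
  ic <- icosphere(level)
  v <- ic$vertices * R
  f <- ic$faces
  ctr <- (v[f[, 1L], ] + v[f[, 2L], ] + v[f[, 3L], ]) / 3
  n <- nrow(f)
  solid_angle <- function(obs, p1, p2, p3) {
    r1 <- sweep(obs, 2L, p1, function(a, b) b - a)
    r2 <- sweep(obs, 2L, p2, function(a, b) b - a)
    r3 <- sweep(obs, 2L, p3, function(a, b) b - a)
    n1 <- sqrt(rowSums(r1^2)); n2 <- sqrt(rowSums(r2^2)); n3 <- sqrt(rowSums(r3^2))
    num <- r1[, 1] * (r2[, 2] * r3[, 3] - r2[, 3] * r3[, 2]) -
      r1[, 2] * (r2[, 1] * r3[, 3] - r2[, 3] * r3[, 1]) +
      r1[, 3] * (r2[, 1] * r3[, 2] - r2[, 2] * r3[, 1])
    den <- n1 * n2 * n3 + rowSums(r1 * r2) * n3 +
      rowSums(r1 * r3) * n2 + rowSums(r2 * r3) * n1
    2 * atan2(num, den)
  }
  A <- matrix(0, n, n)
  for (j in seq_len(n))
    A[, j] <- solid_angle(ctr, v[f[j, 1L], ], v[f[j, 2L], ], v[f[j, 3L], ])
  diag(A) <- 0
  diag(A) <- 2 * pi - rowSums(A)
  d <- sweep(ctr, 2L, pos)
  vinf <- as.numeric((d %*% mom) / (4 * pi * sig * rowSums(d^2)^1.5))
  M <- diag(n) - A / (2 * pi) + matrix(1 / n, n, n)
  V <- solve(M, 2 * vinf)
  list(points = ctr, V = V - mean(V))
}

# brute-force topographic prominence of every strict local maximum
prominence_bruteforce <- function(x) {
  n <- length(x)
  peaks <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  prom <- vapply(peaks, function(p) {
    higher_l <- which(x[seq_len(p - 1L)] > x[p])
    lo <- if (length(higher_l)) max(higher_l) + 1L else 1L
    higher_r <- which(x[(p + 1L):n] > x[p]) + p
    hi <- if (length(higher_r)) min(higher_r) - 1L else n
    x[p] - max(min(x[lo:p]), min(x[p:hi]))
  }, numeric(1L))
  data.frame(sample = peaks, prominence = prom)
}

# exhaustive best s-subset least-squares fit under a pairwise coherence cap
exhaustive_support <- function(cols, y, s, mu) {
  n <- ncol(cols)
  nc <- sweep(cols, 2L, sqrt(colSums(cols^2)), `/`)
  coh <- abs(crossprod(nc)); diag(coh) <- 0
  best <- NULL; best_rn <- Inf
  for (set in utils::combn(n, s, simplify = FALSE)) {
    if (s > 1L && max(coh[set, set]) > mu) next
    fit <- stats::lm.fit(cols[, set, drop = FALSE], y)
    rn <- sqrt(sum(fit$residuals^2))
    if (rn < best_rn) { best_rn <- rn; best <- set }
  }
  list(support = best, residual = best_rn)
}

# phase-locking value across epochs at one sample (Morlet at f0)
plv_at_center <- function(epochs, rate, f0 = 6) {
  k <- thetasource:::morlet_kernel(f0, rate, 3)
  half <- (length(k) - 1L) %/% 2L
  ctrs <- (dim(epochs$data)[3L] + 1L) %/% 2L
  ph <- apply(epochs$data, 1L, function(e) {
    seg <- e[, (ctrs - half):(ctrs + half)]
    Arg(seg %*% Conj(rev(k)))
  })
  mean(Mod(colMeans(exp(1i * t(ph)))))
}
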