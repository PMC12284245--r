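# Hierarchical sparse source localization: SVD-reduced patch leadfields,
# whitened minimum-norm inversion, coherence-constrained greedy selection,
# iterative subspace pursuit, two cortical stages then a combined
# cortical + subcortical stage.

#' Selection configuration for hierarchical localization
#'
#' @param s1,s2,s3 sparsity of the three stages (4, 4, 6)
#' @param mu mutual-coherence ceiling for any selected pair (0.5)
#' @param svd_variance per-patch retained variance fraction (0.90)
#' @param lambda2 minimum-norm regularization in whitened coordinates
#'   (1/9, the SNR = 3 convention)
#' @param max_iter,tol subspace-pursuit iteration controls
#' @param level1,level2 icosahedral patch levels of the two cortical stages
#' @return a `selection_config` list
#' @export
selection_config <- function(s1 = 4L, s2 = 4L, s3 = 6L, mu = 0.5,
                             svd_variance = 0.90, lambda2 = 1 / 9,
                             max_iter = 30L, tol = 1e-6,
                             level1 = 1L, level2 = 2L) {
  stopifnot(s1 >= 1L, s2 >= 1L, s3 >= 1L, mu > 0, mu <= 1,
            svd_variance > 0, svd_variance <= 1)
  structure(as.list(environment()), class = "selection_config")
}

#' Partition the cortical surfaces into icosahedral patches
#'
#' Patch seeds are the vertices of the level-`level` icosahedral
#' subdivision of each hemispheric surface (`10*4^level + 2` per surface);
#' every dense cortical source is assigned to its nearest seed. Empty
#' patches are dropped (recorded in the `dropped` attribute).
#'
#' @param space a `source_space`
#' @param level icosahedral patch level
#' @return object of class `patch_decomposition`: `members` (list of
#'   cortical source indices), `ids`, `centers`, `region` (majority label),
#'   `hemisphere`, `level`, `n_per_surface`
#' @export
make_patches <- function(space, level = 1L) {
  cort <- which(space$kind == "cortical")
  if (!length(cort)) stop("no cortical sources")
  seeds_u <- icosphere(level)$vertices
  members <- list(); ids <- character(0); centers <- NULL
  hemi_v <- character(0); region <- character(0); dropped <- character(0)
  for (h in c("L", "R")) {
    ctr <- space$hemi_centers[[h]]
    seeds <- sweep(seeds_u * space$hemi_radius, 2L, ctr, `+`)
    idx <- cort[space$hemisphere[cort] == h]
    pos <- space$pos[idx, , drop = FALSE]
    nearest <- max.col(-(outer(rowSums(pos^2), rep(1, nrow(seeds))) -
                           2 * pos %*% t(seeds) +
                           outer(rep(1, nrow(pos)), rowSums(seeds^2))),
                       ties.method = "first")
    for (p in seq_len(nrow(seeds))) {
      m <- idx[nearest == p]
      id <- sprintf("ico%d-%s-%03d", level, h, p)
      if (!length(m)) { dropped <- c(dropped, id); next }
      members[[length(members) + 1L]] <- m
      ids <- c(ids, id)
      centers <- rbind(centers, seeds[p, ])
      hemi_v <- c(hemi_v, h)
      reg <- table(space$region[m])
      region <- c(region, names(reg)[which.max(reg)])
    }
  }
  structure(list(members = members, ids = ids, centers = centers,
                 region = region, hemisphere = hemi_v, level = level,
                 n_per_surface = 10L * 4L^level + 2L, dropped = dropped),
            class = "patch_decomposition")
}

#' SVD-reduce grouped leadfield columns
#'
#' Per group (cortical patch or subcortical structure), keeps the smallest
#' number of left singular vectors whose cumulative squared singular
#' values reach `var` of the total, scaled by their singular values.
#'
#' @param gain sensors x columns matrix (possibly whitened)
#' @param groups list of column-index vectors
#' @param var retained variance fraction (0.90)
#' @param ids,region,kind optional per-group annotations
#' @return object of class `reduced_leadfield`: `comps` (sensors x K),
#'   `group` (group index per component column), `ids`, `k`,
#'   `var_explained`, `region`, `kind`
#' @export
reduce_patch_leadfield <- function(gain, groups, var = 0.90, ids = NULL,
                                   region = NULL, kind = NULL) {
  if (var <= 0 || var > 1) stop("invalid argument: var must be in (0, 1]")
  comps <- NULL; gidx <- integer(0); kvec <- integer(0); vexp <- numeric(0)
  keep <- logical(length(groups))
  for (g in seq_along(groups)) {
    m <- gain[, groups[[g]], drop = FALSE]
    if (!any(m != 0)) { warning("zero patch leadfield, skipped"); next }
    s <- svd(m)
    d2 <- s$d^2
    tolr <- max(d2) * 1e-12
    cum <- cumsum(d2) / sum(d2)
    k <- which(cum >= var - 1e-12)[1L]
    k <- min(k, sum(d2 > tolr))
    comps <- cbind(comps, s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k))
    gidx <- c(gidx, rep(g, k))
    kvec <- c(kvec, k)
    vexp <- c(vexp, cum[k])
    keep[g] <- TRUE
  }
  gmap <- cumsum(keep)
  structure(list(comps = comps, group = gmap[gidx],
                 ids = (ids %||% as.character(seq_along(groups)))[keep],
                 k = kvec, var_explained = vexp,
                 region = if (!is.null(region)) region[keep],
                 kind = if (!is.null(kind)) kind[keep]),
            class = "reduced_leadfield")
}

#' Noise covariance from burst epochs
#'
#' Empirical sensor covariance of the full epochs with the sample mean
#' (the across-epoch average, i.e. the phase-locked response) subtracted,
#' pooled over epochs and samples, with diagonal loading `eps * trace/n`.
#' Subtracting the mean response leaves the non-phase-locked background,
#' which is the noise the whitener should equalize. Also returns the
#' (pseudo-inverse square-root) whitener.
#'
#' @param epochs a `burst_epochs` object, or an epochs x channels x samples
#'   array
#' @param eps diagonal loading factor
#' @return object of class `noise_covariance`: `cov`, `whitener`, `loading`
#' @export
compute_noise_covariance <- function(epochs, eps = 0.01) {
  dat <- if (inherits(epochs, "burst_epochs")) epochs$data else epochs
  ne <- dim(dat)[1L]
  if (ne < 2L) stop("need >= 2 epochs for a noise covariance")
  nc <- dim(dat)[2L]; nt <- dim(dat)[3L]
  erp <- apply(dat, c(2L, 3L), mean)
  cv <- matrix(0, nc, nc)
  for (e in seq_len(ne)) {
    x <- dat[e, , ] - erp
    cv <- cv + tcrossprod(x)
  }
  cv <- cv / ((ne - 1L) * nt)
  load <- eps * sum(diag(cv)) / nc
  cvl <- cv + diag(load, nc)
  eg <- eigen(cvl, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  wh <- eg$vectors[, pos, drop = FALSE] %*%
    diag(1 / sqrt(eg$values[pos]), sum(pos)) %*% t(eg$vectors[, pos, drop = FALSE])
  structure(list(cov = cvl, whitener = wh, loading = load,
                 rank = sum(pos)), class = "noise_covariance")
}

#' Average epochs into a phase-locked ERP
#'
#' @param epochs a `burst_epochs` object or epochs x channels x samples array
#' @return channels x samples matrix
#' @export
average_erp <- function(epochs) {
  dat <- if (inherits(epochs, "burst_epochs")) epochs$data else epochs
  apply(dat, c(2L, 3L), mean)
}

#' Minimum norm estimate
#'
#' `x = G' (G G' + lambda2 I)^{-1} y` computed via the SVD of `G`;
#' with `whitener` given, `G` and `y` are whitened first (equivalent to
#' using `lambda2 C` as the regularizer). `lambda2 = 0` gives the
#' pseudo-inverse (exact-inverse limit).
#'
#' @param gain sensors x components matrix
#' @param y sensors x time data
#' @param lambda2 regularization
#' @param whitener optional sensors x sensors whitening matrix
#' @return components x time activation matrix
#' @export
minimum_norm_estimate <- function(gain, y, lambda2 = 1 / 9, whitener = NULL) {
  y <- as.matrix(y)
  if (!is.null(whitener)) {
    gain <- whitener %*% gain
    y <- whitener %*% y
  }
  s <- svd(gain)
  d <- s$d
  if (lambda2 == 0) {
    inv <- ifelse(d > max(d) * 1e-10, 1 / d, 0)
  } else {
    inv <- d / (d^2 + lambda2)
  }
  s$v %*% (inv * (t(s$u) %*% y))
}

#' Mutual coherence of leadfield columns
#'
#' Largest absolute normalized inner product between any column of `a`
#' and any column of `b` (or among columns of `a` when `b` missing).
#'
#' @param a,b sensors x k matrices
#' @return scalar in `[0, 1]`
#' @export
mutual_coherence <- function(a, b = NULL) {
  na <- sweep(a, 2L, pmax(sqrt(colSums(a^2)), .Machine$double.xmin), `/`)
  if (is.null(b)) {
    m <- abs(crossprod(na))
    diag(m) <- 0
    return(max(m, 0))
  }
  nb <- sweep(b, 2L, pmax(sqrt(colSums(b^2)), .Machine$double.xmin), `/`)
  max(abs(crossprod(na, nb)))
}

# pairwise group coherence matrix (max over component pairs)
group_coherence <- function(reduced) {
  ng <- max(reduced$group)
  m <- matrix(0, ng, ng)
  for (i in seq_len(ng - 1L)) for (j in (i + 1L):ng) {
    m[i, j] <- m[j, i] <- mutual_coherence(
      reduced$comps[, reduced$group == i, drop = FALSE],
      reduced$comps[, reduced$group == j, drop = FALSE])
  }
  m
}

# greedy selection of up to s groups by decreasing score under the
# pairwise coherence ceiling; ties broken by lower group index
greedy_coherent <- function(scores, coh, s, mu) {
  ord <- order(-scores, seq_along(scores))
  sel <- integer(0)
  for (g in ord) {
    if (length(sel) >= s) break
    if (!length(sel) || all(coh[g, sel] <= mu)) sel <- c(sel, g)
  }
  sort(sel)
}

#' Coherence-constrained subspace pursuit over grouped components
#'
#' Initialization: full minimum-norm estimate, greedy top-`s` groups by
#' activation norm under the pairwise mutual-coherence ceiling `mu`.
#' Each iteration correlates the residual with all candidate components,
#' takes the top-`s` coherence-feasible groups, unions them with the
#' current support, refits a restricted minimum-norm estimate, prunes back
#' to `s` groups by time-course norm (coherence-feasible), and accepts the
#' iteration only if the residual norm decreases by more than `tol`
#' (relative).
#'
#' @param reduced a `reduced_leadfield` (columns already whitened if a
#'   noise covariance is in play)
#' @param y sensors x time data (same space as `reduced$comps`)
#' @param s target number of groups
#' @param mu mutual-coherence ceiling
#' @param lambda2 minimum-norm regularization for the restricted fits
#' @param max_iter,tol iteration controls
#' @return object of class `sparse_estimate`: `selected` (group indices),
#'   `ids`, `timecourses` (component rows), `tc_group` (group per row),
#'   `group_norms`, `effective_support`, `residual_trace`,
#'   `coherence_max`, `iterations`, `converged`
#' @export
subspace_pursuit <- function(reduced, y, s, mu = 0.5, lambda2 = 1 / 9,
                             max_iter = 30L, tol = 1e-6) {
  y <- as.matrix(y)
  ng <- max(reduced$group)
  if (s > ng) stop("s exceeds the number of candidate groups")
  coh <- group_coherence(reduced)
  cols_of <- function(gs) which(reduced$group %in% gs)
  nrm <- sqrt(colSums(reduced$comps^2))
  ncomps <- sweep(reduced$comps, 2L, pmax(nrm, .Machine$double.xmin), `/`)

  # group strength = norm of the group's fitted contribution to the
  # (whitened) measurement, not of its coefficients: coefficient norms are
  # biased by per-column sensitivity, which whitening redistributes
  fit <- function(sel) {
    cols <- cols_of(sel)
    x <- minimum_norm_estimate(reduced$comps[, cols, drop = FALSE], y, lambda2)
    resid <- y - reduced$comps[, cols, drop = FALSE] %*% x
    gn <- vapply(sel, function(g) {
      rows <- reduced$group[cols] == g
      sqrt(sum((reduced$comps[, cols[rows], drop = FALSE] %*%
                  x[rows, , drop = FALSE])^2))
    }, numeric(1L))
    list(x = x, resid = resid, rn = sqrt(sum(resid^2)), group_norms = gn,
         cols = cols)
  }
  group_score <- function(colscore) {
    vapply(seq_len(ng), function(g)
      sqrt(sum(colscore[reduced$group == g]^2)), numeric(1L))
  }

  x0 <- minimum_norm_estimate(reduced$comps, y, lambda2)
  contrib0 <- vapply(seq_len(ncol(reduced$comps)), function(j)
    nrm[j] * sqrt(sum(x0[j, ]^2)), numeric(1L))
  sel <- greedy_coherent(group_score(contrib0), coh, s, mu)
  if (length(sel) < s)
    warning("coherence constraint feasible for only ", length(sel), " groups")
  cur <- fit(sel)
  trace <- cur$rn
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    proxy <- group_score(sqrt(colSums((t(ncomps) %*% cur$resid)^2)))
    cand <- greedy_coherent(proxy, coh, s, mu)
    uni <- sort(union(sel, cand))
    ufit <- fit(uni)
    scores <- rep(-Inf, ng)
    scores[uni] <- ufit$group_norms
    keep <- greedy_coherent(scores, coh, s, mu)
    nfit <- fit(keep)
    if (cur$rn - nfit$rn > tol * max(cur$rn, .Machine$double.eps)) {
      sel <- keep
      cur <- nfit
      trace <- c(trace, cur$rn)
    } else {
      converged <- TRUE
      break
    }
  }
  yscale <- sqrt(sum(y^2))
  eff <- sel[cur$group_norms > 1e-8 * max(yscale, .Machine$double.eps)]
  structure(list(selected = sel, ids = reduced$ids[sel],
                 timecourses = cur$x, tc_group = reduced$group[cur$cols],
                 group_norms = cur$group_norms, effective_support = eff,
                 residual_trace = trace,
                 coherence_max = if (length(sel) > 1L)
                   max(coh[sel, sel][upper.tri(coh[sel, sel])]) else 0,
                 iterations = it, converged = converged),
            class = "sparse_estimate")
}

#' Hierarchical cortical + subcortical localization
#'
#' Stage 1 runs subspace pursuit on the ico-level-1 SVD-reduced cortical
#' patch leadfield (s1 patches). Stage 2 repeats on the ico-level-2 patches
#' that strictly overlap the stage-1 winners (no bordering patches). Stage 3
#' combines the stage-2 cortical components with the SVD-reduced
#' subcortical (hippocampal) leadfields and selects s3 sources. All stages
#' operate on noise-whitened data (covariance from the epochs themselves).
#'
#' @param leadfield a [compute_leadfield()] result
#' @param epochs a `burst_epochs` object (average-referenced internally)
#' @param cfg a [selection_config()]
#' @return object of class `hierarchical_fit` with `stage1`, `stage2`,
#'   `stage3` (`sparse_estimate`s), patch decompositions, the stage-3
#'   group annotations (`regions3`, `kind3`), `noise_cov`, `erp`
#' @export
hierarchical_localize <- function(leadfield, epochs, cfg = selection_config()) {
  space <- leadfield$space
  epochs <- apply_average_reference(epochs)
  C <- compute_noise_covariance(epochs)
  erp <- average_erp(epochs)
  W <- C$whitener
  Gw <- W %*% leadfield$gain
  yw <- W %*% erp

  cort_src <- which(space$kind == "cortical")
  src_col <- match(cort_src, leadfield$col_source)   # 1 column per cortical source

  p1 <- make_patches(space, cfg$level1)
  g1 <- lapply(p1$members, function(m) src_col[match(m, cort_src)])
  r1 <- reduce_patch_leadfield(Gw, g1, cfg$svd_variance, ids = p1$ids,
                               region = p1$region)
  est1 <- subspace_pursuit(r1, yw, cfg$s1, cfg$mu, cfg$lambda2,
                           cfg$max_iter, cfg$tol)
  if (!length(est1$selected)) stop("stage 1 selected no patches")

  sel_members <- unlist(p1$members[match(est1$ids, p1$ids)])
  p2 <- make_patches(space, cfg$level2)
  overlap <- vapply(p2$members, function(m) any(m %in% sel_members), logical(1L))
  if (!any(overlap)) stop("stage 2 has no overlapping patches")
  p2keep <- which(overlap)
  g2 <- lapply(p2$members[p2keep], function(m) src_col[match(m, cort_src)])
  r2 <- reduce_patch_leadfield(Gw, g2, cfg$svd_variance, ids = p2$ids[p2keep],
                               region = p2$region[p2keep])
  est2 <- subspace_pursuit(r2, yw, min(cfg$s2, max(r2$group)), cfg$mu,
                           cfg$lambda2, cfg$max_iter, cfg$tol)
  if (!length(est2$selected)) stop("stage 2 selected no patches")

  # stage 3: selected cortical patches + SVD-reduced subcortical structures
  comps3 <- NULL; group3 <- integer(0); ids3 <- character(0)
  region3 <- character(0); kind3 <- character(0)
  g <- 0L
  for (gi in est2$selected) {
    g <- g + 1L
    comps3 <- cbind(comps3, r2$comps[, r2$group == gi, drop = FALSE])
    group3 <- c(group3, rep(g, sum(r2$group == gi)))
    ids3 <- c(ids3, r2$ids[gi])
    region3 <- c(region3, r2$region[gi])
    kind3 <- c(kind3, "cortical")
  }
  structs <- unique(space$region[space$kind == "subcortical"])
  for (st in structs) {
    src <- which(space$kind == "subcortical" & space$region == st)
    cols <- which(leadfield$col_source %in% src)
    rsub <- reduce_patch_leadfield(Gw, list(cols), cfg$svd_variance, ids = st)
    g <- g + 1L
    comps3 <- cbind(comps3, rsub$comps)
    group3 <- c(group3, rep(g, ncol(rsub$comps)))
    ids3 <- c(ids3, st)
    region3 <- c(region3, st)
    kind3 <- c(kind3, "subcortical")
  }
  r3 <- structure(list(comps = comps3, group = group3, ids = ids3,
                       region = region3, kind = kind3),
                  class = "reduced_leadfield")
  est3 <- subspace_pursuit(r3, yw, min(cfg$s3, max(group3)), cfg$mu,
                           cfg$lambda2, cfg$max_iter, cfg$tol)
  if (!length(est3$selected)) stop("stage 3 selected no sources")

  structure(list(stage1 = est1, stage2 = est2, stage3 = est3,
                 patches1 = p1, patches2 = p2, reduced3 = r3,
                 regions3 = region3, kind3 = kind3,
                 noise_cov = C, erp = erp, cfg = cfg),
            class = "hierarchical_fit")
}

#' Extract the eight region time courses
#'
#' For each of the eight canonical regions (superior-frontal,
#' middle-frontal, temporal, hippocampus; left and right), takes the
#' stage-3 selected source in that region with the highest time-course
#' RMS. Regions with no selected source are flagged absent (NA rows).
#'
#' @param fit a `hierarchical_fit`
#' @param regions region names to extract
#' @return object of class `region_timecourses`: `timecourses`
#'   (regions x time, NA when absent), `present`, `source_ids`
#' @export
extract_region_timecourses <- function(fit,
    regions = c("superior-frontal-L", "middle-frontal-L", "temporal-L",
                "hippocampus-L", "superior-frontal-R", "middle-frontal-R",
                "temporal-R", "hippocampus-R")) {
  est <- fit$stage3
  nt <- ncol(est$timecourses)
  tc <- matrix(NA_real_, length(regions), nt,
               dimnames = list(regions, NULL))
  present <- setNames(rep(FALSE, length(regions)), regions)
  src_ids <- setNames(rep(NA_character_, length(regions)), regions)
  for (ri in seq_along(regions)) {
    cand <- which(fit$regions3[est$selected] == regions[ri])
    if (!length(cand)) next
    best_rms <- -Inf; best_row <- NULL; best_id <- NA_character_
    for (ci in cand) {
      gsel <- est$selected[ci]
      rows <- which(est$tc_group == gsel)
      rr <- vapply(rows, function(r) rms(est$timecourses[r, ]), numeric(1L))
      if (max(rr) > best_rms) {
        best_rms <- max(rr)
        best_row <- rows[which.max(rr)]
        best_id <- fit$reduced3$ids[gsel]
      }
    }
    tc[ri, ] <- est$timecourses[best_row, ]
    present[ri] <- TRUE
    src_ids[ri] <- best_id
  }
  structure(list(timecourses = tc, present = present, source_ids = src_ids),
            class = "region_timecourses")
}

#' @export
print.sparse_estimate <- function(x, ...) {
  cat("<sparse_estimate> ", length(x$selected), " groups [",
      paste(x$ids, collapse = ", "), "], max coherence ",
      round(x$coherence_max, 3), ", ", x$iterations, " iterations\n", sep = "")
  invisible(x)
}
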