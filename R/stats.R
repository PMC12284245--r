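# Bayesian random-intercept linear mixed models for the crossover design
# (conjugate Gibbs sampler with half-Cauchy variance priors via their
# inverse-gamma scale-mixture representation), percentile conditional
# effects, semi-partial R2 effect sizes, and Spearman correlation with an
# exact permutation p-value at small n.

rinvgamma1 <- function(shape, rate) 1 / stats::rgamma(1L, shape = shape, rate = rate)

# design matrix for: outcome ~ condition + memory + condition:memory +
#   baseline + order + visit, condition/order effect-coded (+/-0.5),
#   memory/baseline centred, visit centred
lmm_design <- function(table, outcome = "outcome") {
  y <- table[[outcome]]
  cc <- ifelse(table$condition == "verum", 0.5, -0.5)
  oc <- ifelse(table$order == "stim-sham", 0.5, -0.5)
  mem_center <- mean(table$memory)
  base_center <- mean(table$baseline)
  X <- cbind(`(Intercept)` = 1, condition = cc,
             memory = table$memory - mem_center,
             `condition:memory` = cc * (table$memory - mem_center),
             baseline = table$baseline - base_center,
             order = oc, visit = table$visit - mean(table$visit))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("non-identifiable design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  pid <- match(table$participant, unique(table$participant))
  list(X = X, y = y, pid = pid, n_part = max(pid),
       mem_center = mem_center, base_center = base_center)
}

split_rhat <- function(draws_by_chain) {
  halves <- unlist(lapply(draws_by_chain, function(d) {
    n <- length(d) %/% 2L
    list(d[seq_len(n)], d[(n + 1L):(2L * n)])
  }), recursive = FALSE)
  n <- length(halves[[1L]])
  means <- vapply(halves, mean, numeric(1L))
  vars <- vapply(halves, stats::var, numeric(1L))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_basic <- function(draws_by_chain) {
  tot <- 0
  for (d in draws_by_chain) {
    n <- length(d)
    if (stats::var(d) == 0) { tot <- tot + n; next }
    rho <- stats::acf(d, lag.max = min(100L, n - 2L), plot = FALSE)$acf[-1L]
    s <- 0
    for (k in seq(1L, length(rho) - 1L, by = 2L)) {
      pair <- rho[k] + rho[k + 1L]
      if (is.na(pair) || pair < 0) break
      s <- s + pair
    }
    tot <- tot + n / (1 + 2 * s)
  }
  tot
}

#' Fit a Bayesian random-intercept linear mixed model
#'
#' Crossover model `outcome ~ condition + memory + condition:memory +
#' baseline + order + visit + (1 | participant)` with condition and order
#' effect-coded (+/- 0.5, so the condition coefficient is the verum-sham
#' difference), memory centred at its grand mean. Priors: Normal(0,
#' (10 sd(y))^2) on fixed effects, half-Cauchy(sd(y)) on both standard
#' deviations (inverse-gamma scale mixture), sampled by a conjugate Gibbs
#' sampler.
#'
#' @param table a `study_table` (or data.frame with the same columns)
#' @param outcome name of the outcome column
#' @param seed integer seed (chain seeds are derived from it)
#' @param chains,iter,warmup MCMC layout; `iter` draws are kept per chain
#'   after `warmup`
#' @return object of class `lmm_posterior`: `draws` (kept draws x
#'   parameters, fixed effects then `sigma_u`, `sigma_e`), `chain` id per
#'   draw, `summary` (mean, 80% interval, semi-partial R2, Rhat, ESS),
#'   `u_mean`, `design`, `table`
#' @export
fit_bayesian_lmm <- function(table, outcome = "outcome", seed = 1L,
                             chains = 4L, iter = 2000L, warmup = 1000L) {
  des <- lmm_design(table, outcome)
  X <- des$X; y <- des$y; pid <- des$pid
  p <- ncol(X); N <- length(y); m <- des$n_part
  sd_y <- stats::sd(y)
  if (sd_y == 0) sd_y <- 1
  s_b2 <- (10 * sd_y)^2
  A2 <- sd_y^2
  XtX <- crossprod(X)
  chain_seeds <- derive_seeds(seed, chains)
  n_keep <- iter
  draws <- matrix(0, chains * n_keep, p + 2L,
                  dimnames = list(NULL, c(colnames(X), "sigma_u", "sigma_e")))
  chain_id <- rep(seq_len(chains), each = n_keep)
  u_sum <- numeric(m)
  n_i <- tabulate(pid, m)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    beta <- stats::rnorm(p, 0, 0.1 * sd_y)
    u <- numeric(m)
    s_u2 <- stats::runif(1L, 0.1, 1) * A2
    s_e2 <- stats::runif(1L, 0.1, 1) * A2
    a_u <- A2; a_e <- A2
    total <- warmup + n_keep
    for (it in seq_len(total)) {
      # random intercepts
      r <- y - X %*% beta
      ru <- rowsum(as.numeric(r), pid)[, 1L]
      prec <- n_i / s_e2 + 1 / s_u2
      u <- stats::rnorm(m, (ru / s_e2) / prec, sqrt(1 / prec))
      # fixed effects
      V <- chol2inv(chol(XtX / s_e2 + diag(1 / s_b2, p)))
      mu <- V %*% crossprod(X, y - u[pid]) / s_e2
      beta <- as.numeric(mu + t(chol(V)) %*% stats::rnorm(p))
      # variances (half-Cauchy via inverse-gamma mixture)
      s_u2 <- rinvgamma1((m + 1) / 2, 1 / a_u + sum(u^2) / 2)
      a_u <- rinvgamma1(1, 1 / A2 + 1 / s_u2)
      resid <- y - X %*% beta - u[pid]
      s_e2 <- rinvgamma1((N + 1) / 2, 1 / a_e + sum(resid^2) / 2)
      a_e <- rinvgamma1(1, 1 / A2 + 1 / s_e2)
      if (it > warmup) {
        k <- (ch - 1L) * n_keep + (it - warmup)
        draws[k, ] <- c(beta, sqrt(s_u2), sqrt(s_e2))
        u_sum <- u_sum + u
      }
    }
  }
  u_mean <- u_sum / (chains * n_keep)
  by_chain <- function(j) lapply(seq_len(chains), function(ch)
    draws[chain_id == ch, j])
  summ <- data.frame(
    term = colnames(draws),
    mean = colMeans(draws),
    lower80 = apply(draws, 2L, stats::quantile, 0.1),
    upper80 = apply(draws, 2L, stats::quantile, 0.9),
    rhat = vapply(seq_len(ncol(draws)), function(j) split_rhat(by_chain(j)),
                  numeric(1L)),
    ess = vapply(seq_len(ncol(draws)), function(j) ess_basic(by_chain(j)),
                 numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- structure(list(draws = draws, chain = chain_id, summary = summ,
                        u_mean = u_mean, design = des, table = table,
                        outcome = outcome, chains = chains, iter = iter,
                        warmup = warmup),
                   class = "lmm_posterior")
  sp <- vapply(setdiff(colnames(X), "(Intercept)"),
               function(tm) semi_partial_r2(out, tm), numeric(1L))
  out$summary$semi_partial_r2 <- c(NA_real_, sp,
                                   rep(NA_real_, 2L))[seq_len(nrow(summ))]
  out
}

#' @export
print.lmm_posterior <- function(x, ...) {
  cat("<lmm_posterior> ", x$chains, " chains x ", x$iter, " draws\n", sep = "")
  tab <- cbind(round(x$summary[, c("mean", "lower80", "upper80")], 4),
               semi_partial_r2 = round(x$summary$semi_partial_r2, 3),
               rhat = round(x$summary$rhat, 3))
  rownames(tab) <- x$summary$term
  print(tab)
  invisible(x)
}

#' Conditional stimulation effects at memory percentiles
#'
#' Effect of condition at the given percentiles of memory performance,
#' `beta_condition + beta_interaction * (q_p - memory centre)`, summarised
#' draw-wise from the joint posterior with 80% intervals.
#'
#' @param post an `lmm_posterior`
#' @param percentiles memory percentiles (in (0, 100))
#' @return data.frame with `percentile`, `memory`, `effect`, `lower80`,
#'   `upper80`
#' @export
conditional_effects <- function(post, percentiles = c(25, 75)) {
  if (any(percentiles <= 0 | percentiles >= 100))
    stop("invalid argument: percentiles must lie in (0, 100)")
  if (!"condition:memory" %in% colnames(post$draws))
    stop("model has no condition:memory interaction")
  q <- stats::quantile(post$table$memory, percentiles / 100)
  out <- lapply(seq_along(percentiles), function(i) {
    eff <- post$draws[, "condition"] +
      post$draws[, "condition:memory"] * (q[i] - post$design$mem_center)
    data.frame(percentile = percentiles[i], memory = as.numeric(q[i]),
               effect = mean(eff),
               lower80 = as.numeric(stats::quantile(eff, 0.1)),
               upper80 = as.numeric(stats::quantile(eff, 0.9)))
  })
  do.call(rbind, out)
}

#' Semi-partial R-squared of a model term
#'
#' Residual-sum-of-squares reduction attributable to the term, evaluated
#' at the posterior-mean coefficients with the random intercepts profiled
#' out: `(SS_res(without term) - SS_res(full)) / SS_total`. The
#' `"vp"` variant instead reports the variance of the term's contribution
#' over the total outcome variance.
#'
#' @param post an `lmm_posterior`
#' @param term fixed-effect name (e.g. `"condition:memory"`)
#' @param method `"rss"` (default) or `"vp"`
#' @return scalar in `[0, 1]`
#' @export
semi_partial_r2 <- function(post, term, method = c("rss", "vp")) {
  method <- match.arg(method)
  X <- post$design$X
  if (!term %in% colnames(X)) stop("term not in model: ", term)
  beta <- post$summary$mean[match(colnames(X), post$summary$term)]
  ystar <- post$design$y - post$u_mean[post$design$pid]
  if (method == "vp") {
    contrib <- X[, term] * beta[match(term, colnames(X))]
    return(min(1, stats::var(contrib) / stats::var(ystar)))
  }
  ss_full <- sum((ystar - X %*% beta)^2)
  Xr <- X[, setdiff(colnames(X), term), drop = FALSE]
  fit_r <- stats::lm.fit(Xr, ystar)
  ss_red <- sum(fit_r$residuals^2)
  ss_tot <- sum((ystar - mean(ystar))^2)
  min(1, max(0, (ss_red - ss_full) / ss_tot))
}

# all permutations of 1..n as a matrix (n! rows)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    if (pos > 1L) block[, seq_len(pos - 1L)] <- sub[, seq_len(pos - 1L)]
    block[, pos] <- n
    if (pos < n) block[, (pos + 1L):n] <- sub[, pos:(n - 1L)]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation with permutation p-value
#'
#' Midranks for ties; the two-sided p-value is exact (full enumeration of
#' rank permutations) for n <= 9 and uses the t approximation above.
#'
#' @param x,y numeric vectors (n >= 4, non-constant)
#' @return list with `rho`, `p`, `method`
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 4L) stop("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9L) {
    perms <- all_permutations(n)
    rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2) * sum((ry - mean(ry))^2))
    stat <- abs(as.numeric((matrix(ry[perms], nrow(perms), n) %*% rxc) / denom))
    p <- mean(stat >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = p, method = method)
}
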