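#' Simulate a two-condition crossover study table
#'
#' Generates one row per participant and condition (verum, sham) with
#' counterbalanced condition order (participant parity under the seed),
#' a baseline memory score, memory performance during stimulation in
#' percent correct, and an outcome generated as
#' `b0 + b_cond*cond + b_mem*mem + b_int*cond*mem + b_base*baseline +
#' b_order*order + b_visit*visit + u_participant + e`
#' with condition and order effect-coded (+/- 0.5), visit centred, and
#' memory/baseline centred at their generating means.
#'
#' @param cfg a [simulation_config()]; uses `n_participants`, `beta`,
#'   `sigma_u`, `sigma_e`, `seed`
#' @return a `data.frame` of class `study_table` with columns
#'   `participant`, `condition`, `visit`, `order`, `baseline`, `memory`,
#'   `outcome`
#' @export
#' @examples
#' tab <- simulate_study_table(simulation_config(seed = 2))
#' table(tab$order) / 2
simulate_study_table <- function(cfg) {
  n <- cfg$n_participants
  if (n %% 2L != 0L) stop("n_participants must be even for counterbalancing")
  set.seed(cfg$seed + 2L)
  b <- cfg$beta
  ability <- stats::rnorm(n, 75, 8)
  baseline <- pmin(pmax(ability + stats::rnorm(n, 0, 4), 60), 100)
  order <- ifelse(seq_len(n) %% 2L == 1L, "stim-sham", "sham-stim")
  u <- stats::rnorm(n, 0, cfg$sigma_u)

  rows <- vector("list", 2L * n)
  k <- 0L
  for (i in seq_len(n)) {
    for (visit in 1:2) {
      condition <- if (order[i] == "stim-sham") {
        if (visit == 1L) "verum" else "sham"
      } else {
        if (visit == 1L) "sham" else "verum"
      }
      memory <- pmin(pmax(ability[i] + stats::rnorm(1L, 0, 3), 0), 100)
      cc <- if (condition == "verum") 0.5 else -0.5
      oc <- if (order[i] == "stim-sham") 0.5 else -0.5
      vc <- visit - 1.5
      outcome <- b$intercept + b$condition * cc + b$memory * (memory - 75) +
        b$interaction * cc * (memory - 75) + b$baseline * (baseline[i] - 75) +
        b$order * oc + b$visit * vc + u[i] + stats::rnorm(1L, 0, cfg$sigma_e)
      k <- k + 1L
      rows[[k]] <- data.frame(participant = sprintf("P%02d", i),
                              condition = condition, visit = visit,
                              order = order[i], baseline = baseline[i],
                              memory = memory, outcome = outcome,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("study_table", "data.frame")
  out
}
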