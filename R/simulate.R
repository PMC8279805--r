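# Event-level Monte Carlo cohort simulator. Deliberately an independent
# code path from the tree builders (it shares only outcome-label strings):
# each patient is pushed through the pathway event by event, so agreement
# with the analytic expected cost is a genuine structural cross-check,
# not a tautology.
#
# One RNG stream per cohort; every patient owns a fixed block of uniform
# draws, one per event slot in a fixed order, so results do not depend on
# patient processing order and an event's draw is the same whether or not
# earlier optional events occurred:
#   1 disease status            (P)
#   2 initial-test failure      (E for LIII, J for LII; PSG never fails)
#   3 initial LIII result       (F given disease, 1-G given no disease)
#   4 fallback LII failure      (the LII of the LII-first sub-algorithm
#                                entered after a LIII technical failure)
#   5 CPAP response             (A = nonresponse)
#   6 follow-up need            (B or H, whichever the pathway uses)
#   7 follow-up LII failure     (J, LIII->LII strategy only)
.sim_n_events <- 7L

#' Simulate a patient cohort through a diagnostic strategy
#'
#' Samples `n` patient trajectories event by event (disease status, test
#' failures, test results given disease, CPAP response, follow-up needs),
#' accumulating study and CPAP-trial costs per event. Serves as an
#' independent verification oracle for [expected_cost()]: the mean
#' simulated cost converges on the analytic expectation and the empirical
#' terminal-state frequencies on the analytic path probabilities.
#'
#' @param algorithm one of [algorithm_ids()].
#' @param scenario an [scenario()] object.
#' @param n cohort size (>= 1).
#' @param seed integer seed; identical inputs give identical results.
#' @param keep_patients if `TRUE`, attach a per-patient data frame
#'   (`patient_id`, `outcome`, `cost`).
#' @return an `osa_simulation` object: list with `algorithm`, `n`,
#'   `mean_cost`, `std_error` (sample sd / sqrt(n)), `terminal_counts`
#'   (named integer vector summing to `n`), `seed`, and optionally
#'   `patients`.
#' @examples
#' sim <- simulate_cohort("l2_first", scenario(pretest_prob = 0.5),
#'                        n = 10000, seed = 1)
#' sim$mean_cost  # ~416.6
#' @export
simulate_cohort <- function(algorithm, scenario, n, seed = 1L,
                            keep_patients = FALSE) {
  algorithm <- match_algorithm(algorithm)
  if (!inherits(scenario, "osa_scenario")) {
    stop("'scenario' must be created with scenario()", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  set.seed(as.integer(seed))
  u <- matrix(stats::runif(n * .sim_n_events), nrow = n,
              ncol = .sim_n_events)
  sim <- switch(algorithm,
                psg_first = sim_psg_first(u, scenario),
                l2_first = sim_l2_first(u, scenario),
                l3_then_psg = sim_l3_then_psg(u, scenario),
                l3_then_l2 = sim_l3_then_l2(u, scenario))
  counts <- table(sim$outcome)
  res <- list(algorithm = algorithm, n = n,
              mean_cost = mean(sim$cost),
              std_error = stats::sd(sim$cost) / sqrt(n),
              terminal_counts = stats::setNames(as.integer(counts),
                                                names(counts)),
              seed = as.integer(seed))
  if (keep_patients) {
    res$patients <- data.frame(patient_id = seq_len(n),
                               outcome = sim$outcome, cost = sim$cost,
                               stringsAsFactors = FALSE)
  }
  structure(res, class = "osa_simulation")
}

#' @export
print.osa_simulation <- function(x, ...) {
  cat(sprintf("Cohort simulation: %s, n = %d, seed = %d\n",
              algorithm_label(x$algorithm), x$n, x$seed))
  cat(sprintf("  mean cost %.2f (se %.3f)\n", x$mean_cost, x$std_error))
  cat("  terminal states:\n")
  for (nm in names(x$terminal_counts)) {
    cat(sprintf("    %7d  %s\n", x$terminal_counts[[nm]], nm))
  }
  invisible(x)
}

# -- per-strategy event walks (vectorized over patients) ----------------

# PSG-first pathway given the patient already holds a sunk cost `base`
# and possibly a label prefix: used directly and as the fallback after a
# failed home study.
walk_psg <- function(u, pr, disease, base, prefix = "") {
  cost <- rep(base + pr$psg_cost, length.out = length(disease))
  outcome <- rep(paste0(prefix, .lbl$neg), length(disease))
  cost[disease] <- cost[disease] + pr$cpap_trial_cost
  nonresp <- disease & u[, 5L] < pr$cpap_nonresponse_frac
  outcome[disease & !nonresp] <- paste0(prefix, .lbl$resp)
  rep_ <- nonresp & u[, 6L] < pr$repeat_psg_frac
  cost[rep_] <- cost[rep_] + pr$psg_cost
  outcome[rep_] <- paste0(prefix, .lbl$rep)
  outcome[nonresp & !rep_] <- paste0(prefix, .lbl$norep)
  list(cost = cost, outcome = outcome)
}

sim_psg_first <- function(u, scenario) {
  pr <- scenario$params
  disease <- u[, 1L] < scenario$pretest_prob
  walk_psg(u, pr, disease, base = 0)
}

# LII-first pathway with sunk cost `base`; uses `fail_col` for the LII
# technical-failure draw (slot 2 when LII is the initial test, slot 4 when
# entered as the fallback sub-algorithm of a failed LIII).
walk_l2 <- function(u, pr, disease, base, fail_col, prefix = "") {
  fail <- u[, fail_col] < pr$l2_failure_rate
  out <- list(cost = numeric(length(disease)),
              outcome = character(length(disease)))
  if (any(fail)) {
    w <- walk_psg(u[fail, , drop = FALSE], pr, disease[fail],
                  base = base + pr$l2_cost,
                  prefix = paste0(prefix, .lbl$l2_fail))
    out$cost[fail] <- w$cost
    out$outcome[fail] <- w$outcome
  }
  if (any(!fail)) {
    ok <- !fail
    cost <- rep(base + pr$l2_cost, sum(ok))
    outcome <- rep(paste0(prefix, .lbl$neg), sum(ok))
    dis <- disease[ok]
    cost[dis] <- cost[dis] + pr$cpap_trial_cost
    nonresp <- dis & u[ok, 5L] < pr$cpap_nonresponse_frac
    outcome[dis & !nonresp] <- paste0(prefix, .lbl$resp)
    rep_ <- nonresp & u[ok, 6L] < pr$repeat_psg_frac  # repeat study is a PSG
    cost[rep_] <- cost[rep_] + pr$psg_cost
    outcome[rep_] <- paste0(prefix, .lbl$rep)
    outcome[nonresp & !rep_] <- paste0(prefix, .lbl$norep)
    out$cost[ok] <- cost
    out$outcome[ok] <- outcome
  }
  out
}

sim_l2_first <- function(u, scenario) {
  pr <- scenario$params
  disease <- u[, 1L] < scenario$pretest_prob
  walk_l2(u, pr, disease, base = 0, fail_col = 2L)
}

# Initial LIII: returns disease/test-positive masks for the successful
# studies; failures handled by the caller via the fallback pathway.
l3_result <- function(u, pr, disease) {
  ifelse(disease, u[, 3L] < pr$l3_sensitivity,
         u[, 3L] < 1 - pr$l3_specificity)
}

sim_l3_then_psg <- function(u, scenario) {
  pr <- scenario$params
  n <- nrow(u)
  disease <- u[, 1L] < scenario$pretest_prob
  fail <- u[, 2L] < pr$l3_failure_rate
  cost <- numeric(n)
  outcome <- character(n)
  if (any(fail)) {
    w <- walk_psg(u[fail, , drop = FALSE], pr, disease[fail],
                  base = pr$l3_cost, prefix = .lbl$l3_fail)
    cost[fail] <- w$cost
    outcome[fail] <- w$outcome
  }
  ok <- !fail
  pos <- ok & l3_result(u, pr, disease)
  nonresp <- u[, 5L] < pr$cpap_nonresponse_frac

  tp <- pos & disease
  cost[tp] <- pr$l3_cost + pr$cpap_trial_cost
  outcome[tp & !nonresp] <- .lbl$tp_resp
  one <- tp & nonresp & u[, 6L] < pr$single_followup_frac
  two <- tp & nonresp & !(u[, 6L] < pr$single_followup_frac)
  cost[one] <- cost[one] + pr$psg_cost
  outcome[one] <- .lbl$tp_one
  cost[two] <- cost[two] + 2 * pr$psg_cost
  outcome[two] <- .lbl$tp_two

  fp <- pos & !disease  # CPAP trial fails, one confirmatory PSG
  cost[fp] <- pr$l3_cost + pr$cpap_trial_cost + pr$psg_cost
  outcome[fp] <- .lbl$fp

  fn <- ok & !pos & disease  # confirmatory PSG positive, CPAP started
  cost[fn] <- pr$l3_cost + pr$psg_cost + pr$cpap_trial_cost
  outcome[fn & !nonresp] <- .lbl$fn_resp
  tit <- fn & nonresp & u[, 6L] < pr$repeat_psg_frac
  cost[tit] <- cost[tit] + pr$psg_cost
  outcome[tit] <- .lbl$fn_rep
  outcome[fn & nonresp & !(u[, 6L] < pr$repeat_psg_frac)] <- .lbl$fn_norep

  tn <- ok & !pos & !disease
  cost[tn] <- pr$l3_cost + pr$psg_cost
  outcome[tn] <- .lbl$tn

  list(cost = cost, outcome = outcome)
}

sim_l3_then_l2 <- function(u, scenario) {
  pr <- scenario$params
  n <- nrow(u)
  disease <- u[, 1L] < scenario$pretest_prob
  fail <- u[, 2L] < pr$l3_failure_rate
  cost <- numeric(n)
  outcome <- character(n)
  if (any(fail)) {
    w <- walk_l2(u[fail, , drop = FALSE], pr, disease[fail],
                 base = pr$l3_cost, fail_col = 4L, prefix = .lbl$l3_fail)
    cost[fail] <- w$cost
    outcome[fail] <- w$outcome
  }
  ok <- !fail
  pos <- ok & l3_result(u, pr, disease)
  nonresp <- u[, 5L] < pr$cpap_nonresponse_frac
  # first follow-up study is an LII; on failure a PSG is added
  fu_fail <- u[, 7L] < pr$l2_failure_rate
  fu_cost <- pr$l2_cost + ifelse(fu_fail, pr$psg_cost, 0)
  sfx <- ifelse(fu_fail, .lbl$fu_fail, .lbl$fu_ok)

  tp <- pos & disease
  cost[tp] <- pr$l3_cost + pr$cpap_trial_cost
  outcome[tp & !nonresp] <- .lbl$tp_resp
  one <- tp & nonresp & u[, 6L] < pr$single_followup_frac
  two <- tp & nonresp & !(u[, 6L] < pr$single_followup_frac)
  cost[one] <- cost[one] + fu_cost[one]
  outcome[one] <- paste0(.lbl$tp_one, sfx[one])
  cost[two] <- cost[two] + fu_cost[two] + pr$psg_cost
  outcome[two] <- paste0(.lbl$tp_two, sfx[two])

  fp <- pos & !disease
  cost[fp] <- pr$l3_cost + pr$cpap_trial_cost + fu_cost[fp]
  outcome[fp] <- paste0(.lbl$fp, sfx[fp])

  fn <- ok & !pos & disease  # confirmatory LII positive, CPAP started
  cost[fn] <- pr$l3_cost + fu_cost[fn] + pr$cpap_trial_cost
  outcome[fn & !nonresp] <- paste0(.lbl$fn_resp, sfx[fn & !nonresp])
  tit <- fn & nonresp & u[, 6L] < pr$repeat_psg_frac  # titration stays a PSG
  cost[tit] <- cost[tit] + pr$psg_cost
  outcome[tit] <- paste0(.lbl$fn_rep, sfx[tit])
  noti <- fn & nonresp & !(u[, 6L] < pr$repeat_psg_frac)
  outcome[noti] <- paste0(.lbl$fn_norep, sfx[noti])

  tn <- ok & !pos & !disease
  cost[tn] <- pr$l3_cost + fu_cost[tn]
  outcome[tn] <- paste0(.lbl$tn, sfx[tn])

  list(cost = cost, outcome = outcome)
}
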