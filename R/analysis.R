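# Scenario sweeps, least-cost frontiers, crossover / break-even solvers.
# All cost curves are affine in the pretest probability (every path
# probability contains P to at most the first power), so bracketed
# root-finding with stats::uniroot is exact to solver tolerance.

algorithm_trees <- function(params) {
  stats::setNames(lapply(.algorithm_ids, build_algorithm, params = params),
                  .algorithm_ids)
}

algorithm_costs <- function(params, pretest_prob, trees = NULL) {
  trees <- trees %||% algorithm_trees(params)
  sc <- scenario(params, pretest_prob)
  vapply(trees, expected_cost, numeric(1), scenario = sc)
}

#' Sweep expected costs over a pretest-probability grid
#'
#' Evaluates all four strategies at each grid point and marks the
#' least-cost strategy (ties broken by the fixed [algorithm_ids()] order).
#'
#' @param params an `osa_parameters` object.
#' @param p_grid strictly increasing probabilities in \[0, 1\]; default a
#'   0.01-step grid over \[0, 1\].
#' @return a data frame with columns `pretest_prob`, `cost_psg_first`,
#'   `cost_l2_first`, `cost_l3_then_psg`, `cost_l3_then_l2`, `cheapest`.
#' @examples
#' sw <- sweep_costs(default_parameters(), seq(0, 1, 0.1))
#' @export
sweep_costs <- function(params = default_parameters(),
                        p_grid = seq(0, 1, by = 0.01)) {
  stop_if_invalid(params)
  if (length(p_grid) == 0L) stop("'p_grid' must be nonempty", call. = FALSE)
  if (any(!is.finite(p_grid)) || any(p_grid < 0) || any(p_grid > 1)) {
    stop("'p_grid' values must lie in [0, 1]", call. = FALSE)
  }
  if (is.unsorted(p_grid, strictly = TRUE)) {
    stop("'p_grid' must be strictly increasing", call. = FALSE)
  }
  trees <- algorithm_trees(params)
  costs <- t(vapply(p_grid, function(P) algorithm_costs(params, P, trees),
                    numeric(length(.algorithm_ids))))
  cheapest <- .algorithm_ids[apply(costs, 1L, which.min)]
  out <- data.frame(pretest_prob = p_grid, costs, cheapest = cheapest,
                    stringsAsFactors = FALSE)
  names(out) <- c("pretest_prob", paste0("cost_", .algorithm_ids), "cheapest")
  out
}

#' Crossover pretest probability of two strategies
#'
#' Finds the pretest probability at which the two expected-cost curves
#' intersect, by bracketed root-finding (Brent) on their difference to an
#' absolute tolerance of 1e-6 in P. If the difference does not change sign
#' over the bracket the crossover is reported as absent (`NA`), not an
#' error: parallel or non-crossing curves are a legitimate outcome.
#'
#' @param a,b distinct algorithm ids.
#' @param params an `osa_parameters` object.
#' @param bracket length-2 interval within \[0, 1\].
#' @return an `osa_crossover` object: list with `algorithm_a`,
#'   `algorithm_b`, `crossover_prob` (`NA` if none), `bracket`,
#'   `cost_at_crossover`.
#' @examples
#' crossover_probability("psg_first", "l3_then_psg")  # ~0.562
#' @export
crossover_probability <- function(a, b, params = default_parameters(),
                                  bracket = c(0, 1)) {
  a <- match_algorithm(a)
  b <- match_algorithm(b)
  if (a == b) stop("'a' and 'b' must be different algorithms", call. = FALSE)
  stop_if_invalid(params)
  check_bracket(bracket, 0, 1)
  ta <- build_algorithm(a, params)
  tb <- build_algorithm(b, params)
  f <- function(P) {
    sc <- scenario(params, P)
    expected_cost(ta, sc) - expected_cost(tb, sc)
  }
  root <- bracketed_root(f, bracket)
  structure(list(algorithm_a = a, algorithm_b = b,
                 crossover_prob = root, bracket = bracket,
                 cost_at_crossover = if (is.na(root)) NA_real_ else {
                   expected_cost(ta, scenario(params, root))
                 }),
            class = "osa_crossover")
}

#' @export
print.osa_crossover <- function(x, ...) {
  cat(sprintf("Crossover of %s vs %s on [%g, %g]: ",
              algorithm_label(x$algorithm_a), algorithm_label(x$algorithm_b),
              x$bracket[1], x$bracket[2]))
  if (is.na(x$crossover_prob)) {
    cat("none (no sign change in bracket)\n")
  } else {
    cat(sprintf("P = %.6f (%.3f), cost %.2f\n", x$crossover_prob,
                x$crossover_prob, x$cost_at_crossover))
  }
  invisible(x)
}

#' Break-even value of a model parameter
#'
#' Solves for the value of one parameter at which two strategies have
#' equal expected cost at the scenario's pretest probability, all other
#' parameters held fixed. Bracketed root-finding to 1e-6 in the unknown.
#' If the cost difference does not change sign over the bracket, the
#' result carries `value = NA` and `note = "no break-even in bracket"`.
#'
#' @param field a parameter field (long name or A-K alias).
#' @param a,b distinct algorithm ids.
#' @param scenario an [scenario()] object (supplies P and the fixed
#'   parameter values).
#' @param bracket length-2 search interval within the field's valid range.
#' @return an `osa_breakeven` object: list with `field`, `algorithm_a`,
#'   `algorithm_b`, `value` (exact root or `NA`), `value_nearest_10`
#'   (money fields are conventionally reported to the nearest $10),
#'   `bracket`, `note`.
#' @examples
#' be <- breakeven_parameter("l2_cost", "psg_first", "l2_first",
#'                           scenario(pretest_prob = 0.5), c(0, 1000))
#' be$value             # 471.75
#' be$value_nearest_10  # 470
#' @export
breakeven_parameter <- function(field, a, b, scenario,
                                bracket) {
  if (!inherits(scenario, "osa_scenario")) {
    stop("'scenario' must be created with scenario()", call. = FALSE)
  }
  field <- canonical_field(field)
  a <- match_algorithm(a)
  b <- match_algorithm(b)
  if (a == b) stop("'a' and 'b' must be different algorithms", call. = FALSE)
  kind <- .param_table$kind[match(field, .param_table$field)]
  check_bracket(bracket, 0, if (kind == "proportion") 1 else Inf)
  f <- function(v) {
    p2 <- scenario$params
    p2[[field]] <- v
    sc <- scenario(p2, scenario$pretest_prob)
    expected_cost(build_algorithm(a, p2), sc) -
      expected_cost(build_algorithm(b, p2), sc)
  }
  root <- bracketed_root(f, bracket)
  structure(list(field = field, algorithm_a = a, algorithm_b = b,
                 value = root,
                 value_nearest_10 = if (is.na(root)) NA_real_ else {
                   round_nearest(root, 10)
                 },
                 bracket = bracket,
                 note = if (is.na(root)) "no break-even in bracket" else ""),
            class = "osa_breakeven")
}

#' @export
print.osa_breakeven <- function(x, ...) {
  cat(sprintf("Break-even %s equating %s and %s: ", x$field,
              algorithm_label(x$algorithm_a), algorithm_label(x$algorithm_b)))
  if (is.na(x$value)) {
    cat(x$note, "\n")
  } else {
    cat(sprintf("%.4f (nearest $10: %g)\n", x$value, x$value_nearest_10))
  }
  invisible(x)
}

#' Cohort-level cost difference between two strategies
#'
#' `(cost_a - cost_b) * n_patients`. Under the
#' `"per-patient-nearest-dollar"` policy each per-patient cost is rounded
#' to the nearest dollar before differencing (the convention behind
#' headline cohort-savings figures); `"exact"` uses unrounded costs.
#'
#' @param a,b algorithm ids.
#' @param scenario an [scenario()] object.
#' @param n_patients cohort size (>= 1).
#' @param rounding `"per-patient-nearest-dollar"` or `"exact"`.
#' @return the cohort saving (positive when `b` is cheaper).
#' @examples
#' cohort_savings("psg_first", "l2_first",
#'                scenario(pretest_prob = 0.5), 1000)  # 171000
#' @export
cohort_savings <- function(a, b, scenario, n_patients,
                           rounding = c("per-patient-nearest-dollar",
                                        "exact")) {
  rounding <- match.arg(rounding)
  if (!inherits(scenario, "osa_scenario")) {
    stop("'scenario' must be created with scenario()", call. = FALSE)
  }
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1) {
    stop("'n_patients' must be a positive integer", call. = FALSE)
  }
  ca <- expected_cost(build_algorithm(a, scenario$params), scenario)
  cb <- expected_cost(build_algorithm(b, scenario$params), scenario)
  if (rounding == "per-patient-nearest-dollar") {
    ca <- round_dollar(ca)
    cb <- round_dollar(cb)
  }
  (ca - cb) * n_patients
}

#' One-way sensitivity analysis
#'
#' Re-evaluates all four strategies while one parameter moves across a set
#' of values, all others fixed at the scenario's values. Suitable for
#' tornado-style reporting.
#'
#' @param field parameter field (long name or A-K alias).
#' @param values ordered values within the field's valid range.
#' @param scenario an [scenario()] object.
#' @return a data frame with columns `value` and `cost_<algorithm>` for
#'   each strategy.
#' @export
one_way_sensitivity <- function(field, values, scenario) {
  if (!inherits(scenario, "osa_scenario")) {
    stop("'scenario' must be created with scenario()", call. = FALSE)
  }
  field <- canonical_field(field)
  if (length(values) == 0L) stop("'values' must be nonempty", call. = FALSE)
  costs <- t(vapply(values, function(v) {
    p2 <- scenario$params
    p2[[field]] <- v
    stop_if_invalid(p2)
    algorithm_costs(p2, scenario$pretest_prob)
  }, numeric(length(.algorithm_ids))))
  out <- data.frame(value = values, costs, stringsAsFactors = FALSE)
  names(out) <- c("value", paste0("cost_", .algorithm_ids))
  out
}

check_bracket <- function(bracket, lo, hi) {
  if (!is.numeric(bracket) || length(bracket) != 2L ||
      any(!is.finite(bracket)) || bracket[1] >= bracket[2] ||
      bracket[1] < lo || bracket[2] > hi) {
    stop("'bracket' must be an increasing interval within [", lo, ", ",
         if (is.finite(hi)) hi else "Inf", "]", call. = FALSE)
  }
  invisible(bracket)
}

# Brent root-finding on a bracket; NA if no sign change.
bracketed_root <- function(f, bracket, tol = 1e-9) {
  fa <- f(bracket[1])
  fb <- f(bracket[2])
  if (fa == 0) return(bracket[1])
  if (fb == 0) return(bracket[2])
  if (sign(fa) == sign(fb)) return(NA_real_)
  stats::uniroot(f, interval = bracket, f.lower = fa, f.upper = fb,
                 tol = tol)$root
}
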