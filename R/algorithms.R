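# The four diagnostic strategies, each built as a pure chance tree.
#
# Shared modelling conventions (see the methods vignette for rationale):
#  * PSG is the gold standard: 100% sensitive/specific, never fails
#    technically; a Level II study is equally accurate but fails with
#    probability J, after which the patient gets a PSG.
#  * A Level III study fails with probability E; on failure the patient
#    enters the strategy's fallback modality as a complete sub-algorithm
#    (PSG-first tree, or LII-first tree in the LIII->LII strategy).
#  * Every LIII-negative patient (true or false negative) receives a
#    confirmatory study; false positives fail their CPAP trial and get one
#    confirmatory study, then exit without OSA.
#  * The CPAP trial cost D is charged exactly once on every path where
#    CPAP is started, never on disease-negative non-CPAP paths.
#  * Nonresponder follow-up: H / (1-H) governs paths diagnosed directly by
#    a positive LIII; B governs paths diagnosed by PSG or LII (including
#    LIII false negatives).

.algorithm_ids <- c("psg_first", "l2_first", "l3_then_psg", "l3_then_l2")
.algorithm_labels <- c(psg_first = "Initial PSG",
                       l2_first = "Initial LII",
                       l3_then_psg = "Initial LIII→PSG",
                       l3_then_l2 = "Initial LIII→LII")

# Outcome-label vocabulary, shared with the event-level simulator so that
# empirical terminal-state frequencies can be matched against analytic
# path probabilities. Only the strings are shared; all probability and
# cost logic is independent.
.lbl <- list(
  neg     = "no OSA",
  resp    = "OSA, CPAP responder",
  norep   = "OSA, CPAP nonresponder, no repeat study",
  rep     = "OSA, CPAP nonresponder, repeat PSG",
  l2_fail = "LII technical failure: ",
  l3_fail = "LIII technical failure: ",
  tp_resp  = "true positive, CPAP responder",
  tp_one   = "true positive, CPAP nonresponder, one follow-up study",
  tp_two   = "true positive, CPAP nonresponder, follow-up study + titration PSG",
  fp       = "false positive, CPAP trial failed, confirmed no OSA",
  fn_resp  = "false negative, confirmed OSA, CPAP responder",
  fn_rep   = "false negative, confirmed OSA, CPAP nonresponder, titration PSG",
  fn_norep = "false negative, confirmed OSA, CPAP nonresponder, no titration PSG",
  tn       = "true negative, confirmed no OSA",
  fu_ok    = " [follow-up LII ok]",
  fu_fail  = " [follow-up LII failed, PSG done]"
)

# scenario accessors used as branch-probability closures
.P  <- function(s) s$pretest_prob
.Q  <- function(s) 1 - s$pretest_prob
.pv  <- function(field) {
  force(field)
  function(s) s$params[[field]]
}
.pvc <- function(field) {
  force(field)
  function(s) 1 - s$params[[field]]
}

#' Algorithm identifiers
#'
#' The four diagnostic strategies, in their stable display order.
#'
#' @return character vector `c("psg_first", "l2_first", "l3_then_psg",
#'   "l3_then_l2")`.
#' @export
algorithm_ids <- function() .algorithm_ids

#' @rdname algorithm_ids
#' @param algorithm an algorithm id.
#' @return for `algorithm_label()`, the human-readable strategy name.
#' @export
algorithm_label <- function(algorithm) {
  unname(.algorithm_labels[[match_algorithm(algorithm)]])
}

match_algorithm <- function(algorithm) {
  if (!is.character(algorithm) || length(algorithm) != 1L) {
    stop("'algorithm' must be a single id string", call. = FALSE)
  }
  id <- tolower(algorithm)
  if (!id %in% .algorithm_ids) {
    stop("unknown algorithm '", algorithm, "'; expected one of: ",
         paste(.algorithm_ids, collapse = ", "), call. = FALSE)
  }
  id
}

# Common core of the PSG-first strategy and of the successful-LII subtree:
# one diagnostic study (cost field `study`), CPAP on diagnosis, and a
# repeat PSG for the fraction B of nonresponders.
diagnostic_core <- function(study) {
  st <- function(p) p[[study]]
  chance_node(
    tree_branch("OSA present", .P, chance_node(
      tree_branch("responds to CPAP", .pvc("cpap_nonresponse_frac"),
        terminal_node(.lbl$resp,
                      function(p) st(p) + p$cpap_trial_cost)),
      tree_branch("does not respond to CPAP", .pv("cpap_nonresponse_frac"),
        chance_node(
          tree_branch("repeat PSG needed", .pv("repeat_psg_frac"),
            terminal_node(.lbl$rep,
                          function(p) st(p) + p$psg_cost + p$cpap_trial_cost)),
          tree_branch("no repeat study", .pvc("repeat_psg_frac"),
            terminal_node(.lbl$norep,
                          function(p) st(p) + p$cpap_trial_cost)))))),
    tree_branch("no OSA", .Q, terminal_node(.lbl$neg, st)))
}

#' Build the initial-PSG strategy tree
#'
#' Everyone gets one in-laboratory PSG. Positives start CPAP; a fraction A
#' do not respond, of whom a fraction B need a repeat (titration) PSG.
#' Four terminal states.
#'
#' @param params an `osa_parameters` object.
#' @return an `osa_tree`.
#' @examples
#' expected_cost(build_psg_first(), scenario(pretest_prob = 0.5))  # 588.30
#' @export
build_psg_first <- function(params = default_parameters()) {
  stop_if_invalid(params)
  new_tree("psg_first", diagnostic_core("psg_cost"))
}

#' Build the initial-Level-II strategy tree
#'
#' Everyone starts with a home Level II polysomnogram (cost K), as
#' accurate as PSG but nondiagnostic with probability J, in which case the
#' patient proceeds through the complete PSG-first pathway (having sunk
#' the LII cost). On a successful LII the pathway mirrors the PSG-first
#' structure, with the nonresponder repeat study remaining an
#' in-laboratory PSG. Eight terminal states.
#'
#' @inheritParams build_psg_first
#' @return an `osa_tree`.
#' @export
build_l2_first <- function(params = default_parameters()) {
  stop_if_invalid(params)
  success <- diagnostic_core("l2_cost")
  failure <- graft(diagnostic_core("psg_cost"),
                   function(p) p$l2_cost, prefix = .lbl$l2_fail)
  new_tree("l2_first", chance_node(
    tree_branch("LII diagnostic", .pvc("l2_failure_rate"), success),
    tree_branch("LII technical failure", .pv("l2_failure_rate"), failure)))
}

# Success subtree of an initial Level III study, split truth x test.
# `followup` builds the node that administers the first follow-up study:
# followup(make_leaf) where make_leaf(fu_cost, suffix) returns the subtree
# downstream of that study, with fu_cost(params) the study's accumulated
# cost and suffix appended to outcome labels.
l3_success_split <- function(followup) {
  I_ <- function(p) p$l3_cost
  tp <- chance_node(
    tree_branch("responds to CPAP", .pvc("cpap_nonresponse_frac"),
      terminal_node(.lbl$tp_resp,
                    function(p) I_(p) + p$cpap_trial_cost)),
    tree_branch("does not respond to CPAP", .pv("cpap_nonresponse_frac"),
      chance_node(
        tree_branch("one follow-up study", .pv("single_followup_frac"),
          followup(function(fu, sfx) {
            terminal_node(paste0(.lbl$tp_one, sfx),
                          function(p) I_(p) + p$cpap_trial_cost + fu(p))
          })),
        tree_branch("follow-up study + titration PSG",
                    .pvc("single_followup_frac"),
          followup(function(fu, sfx) {
            terminal_node(paste0(.lbl$tp_two, sfx),
                          function(p) I_(p) + p$cpap_trial_cost + fu(p) +
                            p$psg_cost)
          })))))
  fp <- followup(function(fu, sfx) {
    terminal_node(paste0(.lbl$fp, sfx),
                  function(p) I_(p) + p$cpap_trial_cost + fu(p))
  })
  fn <- followup(function(fu, sfx) {
    chance_node(
      tree_branch("responds to CPAP", .pvc("cpap_nonresponse_frac"),
        terminal_node(paste0(.lbl$fn_resp, sfx),
                      function(p) I_(p) + fu(p) + p$cpap_trial_cost)),
      tree_branch("does not respond to CPAP", .pv("cpap_nonresponse_frac"),
        chance_node(
          tree_branch("titration PSG needed", .pv("repeat_psg_frac"),
            terminal_node(paste0(.lbl$fn_rep, sfx),
                          function(p) I_(p) + fu(p) + p$cpap_trial_cost +
                            p$psg_cost)),
          tree_branch("no titration study", .pvc("repeat_psg_frac"),
            terminal_node(paste0(.lbl$fn_norep, sfx),
                          function(p) I_(p) + fu(p) + p$cpap_trial_cost)))))
  })
  tn <- followup(function(fu, sfx) {
    terminal_node(paste0(.lbl$tn, sfx), function(p) I_(p) + fu(p))
  })
  # truth x test split; probabilities use sensitivity F / specificity G
  chance_node(
    tree_branch("LIII positive, OSA present",
                function(s) s$pretest_prob * s$params$l3_sensitivity, tp),
    tree_branch("LIII positive, no OSA",
                function(s) (1 - s$pretest_prob) *
                  (1 - s$params$l3_specificity), fp),
    tree_branch("LIII negative, OSA present",
                function(s) s$pretest_prob *
                  (1 - s$params$l3_sensitivity), fn),
    tree_branch("LIII negative, no OSA",
                function(s) (1 - s$pretest_prob) * s$params$l3_specificity,
                tn))
}

#' Build the initial-Level-III-then-PSG strategy tree
#'
#' Everyone starts with a limited-channel Level III home study (cost I,
#' sensitivity F, specificity G, failure rate E). A technical failure
#' routes through the complete PSG-first pathway. Positives start CPAP:
#' responders exit; nonresponders need one follow-up PSG with probability
#' H, two (diagnostic + titration) with probability 1 - H. All negatives
#' receive a confirmatory PSG: false negatives then start CPAP (a
#' fraction B of their nonresponders needing a further titration PSG);
#' true negatives exit. False positives fail their CPAP trial, receive one
#' confirmatory PSG, and exit.
#'
#' @inheritParams build_psg_first
#' @return an `osa_tree`.
#' @export
build_l3_then_psg <- function(params = default_parameters()) {
  stop_if_invalid(params)
  followup_psg <- function(make_leaf) make_leaf(function(p) p$psg_cost, "")
  success <- l3_success_split(followup_psg)
  failure <- graft(diagnostic_core("psg_cost"),
                   function(p) p$l3_cost, prefix = .lbl$l3_fail)
  new_tree("l3_then_psg", chance_node(
    tree_branch("LIII diagnostic", .pvc("l3_failure_rate"), success),
    tree_branch("LIII technical failure", .pv("l3_failure_rate"), failure)))
}

#' Build the initial-Level-III-then-Level-II strategy tree
#'
#' Structurally the LIII-then-PSG strategy with every *first* follow-up
#' study replaced by a Level II home study: with probability 1 - J it
#' costs K, with probability J it fails and a PSG is added (K + C). Any
#' *additional* titration study remains an in-laboratory PSG. A Level III
#' technical failure routes through the complete LII-first pathway.
#'
#' @inheritParams build_psg_first
#' @return an `osa_tree`.
#' @export
build_l3_then_l2 <- function(params = default_parameters()) {
  stop_if_invalid(params)
  followup_l2 <- function(make_leaf) {
    chance_node(
      tree_branch("follow-up LII diagnostic", .pvc("l2_failure_rate"),
                  make_leaf(function(p) p$l2_cost, .lbl$fu_ok)),
      tree_branch("follow-up LII technical failure", .pv("l2_failure_rate"),
                  make_leaf(function(p) p$l2_cost + p$psg_cost,
                            .lbl$fu_fail)))
  }
  success <- l3_success_split(followup_l2)
  failure <- graft(build_l2_first(params)$root,
                   function(p) p$l3_cost, prefix = .lbl$l3_fail)
  new_tree("l3_then_l2", chance_node(
    tree_branch("LIII diagnostic", .pvc("l3_failure_rate"), success),
    tree_branch("LIII technical failure", .pv("l3_failure_rate"), failure)))
}

#' Build a strategy tree by id
#'
#' @param algorithm one of [algorithm_ids()].
#' @param params an `osa_parameters` object.
#' @return an `osa_tree`.
#' @export
build_algorithm <- function(algorithm, params = default_parameters()) {
  switch(match_algorithm(algorithm),
         psg_first = build_psg_first(params),
         l2_first = build_l2_first(params),
         l3_then_psg = build_l3_then_psg(params),
         l3_then_l2 = build_l3_then_l2(params))
}

#' Closed-form expected cost of the initial-PSG strategy
#'
#' The four-term sum over terminal states,
#' \deqn{C(1-P) + (C+D)P(1-A) + (C+D)PA(1-B) + (2C+D)PAB,}
#' equal (to rounding) to `expected_cost(build_psg_first(params), scenario)`.
#' Used as an algebraic cross-check of the tree engine.
#'
#' @param scenario an [scenario()] object.
#' @return expected cost (scalar).
#' @export
closed_form_psg_cost <- function(scenario) {
  if (!inherits(scenario, "osa_scenario")) {
    stop("'scenario' must be created with scenario()")
  }
  p <- scenario$params
  P <- scenario$pretest_prob
  A <- p$cpap_nonresponse_frac
  B <- p$repeat_psg_frac
  C <- p$psg_cost
  D <- p$cpap_trial_cost
  C * (1 - P) + (C + D) * P * (1 - A) + (C + D) * P * A * (1 - B) +
    (2 * C + D) * P * A * B
}
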