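# Generic chance-tree machinery. Branch probabilities are functions of a
# scenario and terminal costs are functions of the parameter set, so a
# single built tree serves every parameter value -- this is what makes
# break-even solving in an arbitrary parameter possible.

#' Tree branch
#'
#' One labelled branch of a chance node.
#'
#' @param label short branch label.
#' @param probability a function of an `osa_scenario` returning a
#'   probability, or a constant.
#' @param child the child node ([chance_node()] or [terminal_node()]).
#' @return an `osa_branch` object.
#' @export
tree_branch <- function(label, probability, child) {
  stopifnot(is.character(label), length(label) == 1L,
            inherits(child, "osa_node"))
  structure(list(label = label, probability = as_prob_fn(probability),
                 child = child),
            class = "osa_branch")
}

#' Chance node
#'
#' An internal node whose branch probabilities must sum to 1 (within 1e-9)
#' for every valid scenario; violations are errors at evaluation time, not
#' warnings.
#'
#' @param ... `osa_branch` objects, or a single list of them.
#' @return an `osa_node` of subclass `chance_node`.
#' @export
chance_node <- function(...) {
  branches <- list(...)
  if (length(branches) == 1L && !inherits(branches[[1L]], "osa_branch") &&
      is.list(branches[[1L]])) {
    branches <- branches[[1L]]
  }
  ok <- vapply(branches, inherits, logical(1), what = "osa_branch")
  if (!all(ok)) stop("all arguments must be tree_branch objects")
  structure(list(branches = branches), class = c("chance_node", "osa_node"))
}

#' Terminal node
#'
#' A leaf of the tree: a complete patient outcome with an accumulated cost.
#'
#' @param outcome_label outcome label, unique within a tree.
#' @param cost a function of an `osa_parameters` returning a nonnegative
#'   cost, or a constant.
#' @return an `osa_node` of subclass `terminal_node`.
#' @export
terminal_node <- function(outcome_label, cost) {
  stopifnot(is.character(outcome_label), length(outcome_label) == 1L)
  structure(list(outcome_label = outcome_label, cost = as_cost_fn(cost)),
            class = c("terminal_node", "osa_node"))
}

# Wrap a subtree so that every terminal accrues an extra cost (e.g. the
# sunk cost of a failed home study before falling back to a complete
# sub-algorithm) and outcome labels gain a prefix for uniqueness.
graft <- function(node, extra, prefix = "") {
  extra <- as_cost_fn(extra)
  if (inherits(node, "terminal_node")) {
    base <- node$cost
    terminal_node(paste0(prefix, node$outcome_label),
                  function(params) base(params) + extra(params))
  } else {
    chance_node(lapply(node$branches, function(b) {
      tree_branch(b$label, b$probability, graft(b$child, extra, prefix))
    }))
  }
}

new_tree <- function(algorithm, root) {
  structure(list(algorithm = algorithm, root = root), class = "osa_tree")
}

#' Enumerate terminal paths of a decision tree
#'
#' Walks the tree depth-first (branches in declared order) and returns one
#' row per leaf with the root-to-leaf label sequence, the path probability
#' (product of branch probabilities along the path), and the terminal
#' cost. Path probabilities of a well-formed tree sum to 1; each chance
#' node's branch probabilities are checked to sum to 1 within 1e-9 and a
#' violation is an error.
#'
#' @param tree an `osa_tree` (from the algorithm builders) or a bare node.
#' @param scenario an [scenario()] object.
#' @return a data frame with columns `path`, `outcome`, `probability`,
#'   `cost`.
#' @examples
#' paths <- enumerate_paths(build_psg_first(), scenario(pretest_prob = 0.5))
#' sum(paths$probability)  # 1
#' @export
enumerate_paths <- function(tree, scenario) {
  node <- if (inherits(tree, "osa_tree")) tree$root else tree
  if (!inherits(node, "osa_node")) stop("'tree' is not a decision tree")
  if (!inherits(scenario, "osa_scenario")) {
    stop("'scenario' must be created with scenario()")
  }
  acc <- new.env(parent = emptyenv())
  acc$rows <- vector("list", 64L)
  acc$n <- 0L
  walk <- function(node, labels, prob) {
    if (inherits(node, "terminal_node")) {
      acc$n <- acc$n + 1L
      if (acc$n > length(acc$rows)) length(acc$rows) <- 2L * length(acc$rows)
      acc$rows[[acc$n]] <- list(
        path = paste(labels, collapse = " > "),
        outcome = node$outcome_label,
        probability = prob,
        cost = node$cost(scenario$params))
    } else if (inherits(node, "chance_node")) {
      if (length(node$branches) == 0L) {
        stop("malformed tree: chance node with zero branches")
      }
      ps <- vapply(node$branches, function(b) b$probability(scenario),
                   numeric(1))
      if (any(ps < -1e-12 | ps > 1 + 1e-12)) {
        stop("branch probability outside [0, 1]")
      }
      if (abs(sum(ps) - 1) > 1e-9) {
        stop(sprintf("branch probabilities sum to %.12g, not 1", sum(ps)))
      }
      for (i in seq_along(node$branches)) {
        b <- node$branches[[i]]
        walk(b$child, c(labels, b$label), prob * ps[[i]])
      }
    } else {
      stop("malformed tree: unknown node type")
    }
  }
  walk(node, character(0), 1)
  rows <- acc$rows[seq_len(acc$n)]
  data.frame(
    path = vapply(rows, `[[`, character(1), "path"),
    outcome = vapply(rows, `[[`, character(1), "outcome"),
    probability = vapply(rows, `[[`, numeric(1), "probability"),
    cost = vapply(rows, `[[`, numeric(1), "cost"),
    stringsAsFactors = FALSE)
}

#' Expected cost per patient of a decision tree
#'
#' The model's sole outcome measure: the sum over terminal states of path
#' probability times accumulated cost.
#'
#' @inheritParams enumerate_paths
#' @return expected cost (scalar).
#' @examples
#' expected_cost(build_l2_first(), scenario(pretest_prob = 0.5))
#' @export
expected_cost <- function(tree, scenario) {
  paths <- enumerate_paths(tree, scenario)
  sum(paths$probability * paths$cost)
}

#' @export
print.osa_tree <- function(x, ...) {
  cat("Decision tree:", algorithm_label(x$algorithm),
      sprintf("(%s)\n", x$algorithm))
  cat("  terminal states:", n_terminals(x$root), "\n")
  invisible(x)
}

n_terminals <- function(node) {
  if (inherits(node, "terminal_node")) return(1L)
  sum(vapply(node$branches, function(b) n_terminals(b$child), integer(1)))
}
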