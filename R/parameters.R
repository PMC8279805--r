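# Model parameter set: 11 scalars describing the diagnostic pathways.
# Long names are canonical; the single letters A-K are accepted aliases
# (the lettering used throughout the model's worksheets and figures).
.param_table <- data.frame(
  field = c("cpap_nonresponse_frac", "repeat_psg_frac", "psg_cost",
            "cpap_trial_cost", "l3_failure_rate", "l3_sensitivity",
            "l3_specificity", "single_followup_frac", "l3_cost",
            "l2_failure_rate", "l2_cost"),
  alias = c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K"),
  kind  = c("proportion", "proportion", "cost", "cost", "proportion",
            "proportion", "proportion", "proportion", "cost",
            "proportion", "cost"),
  default = c(0.3, 0.4, 555, 0, 0.1, 0.85, 0.85, 0.6, 167, 0.15, 300),
  stringsAsFactors = FALSE
)

# Map user-supplied names (long names or A-K aliases, any case for the
# aliases) to canonical field names; unknown names are an error.
canonical_field <- function(nm) {
  vapply(nm, function(x) {
    if (x %in% .param_table$field) return(x)
    hit <- match(toupper(x), .param_table$alias)
    if (!is.na(hit) && nchar(x) == 1L) return(.param_table$field[hit])
    stop("unknown parameter field: '", x, "'", call. = FALSE)
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a model parameter set
#'
#' Creates the 11-scalar parameter set driving the diagnostic-pathway cost
#' model. Unspecified fields take the British Columbia base-case defaults
#' (costs in Canadian dollars; currency is treated as a unitless
#' nonnegative number by the engine, "CAD" is display metadata only).
#'
#' Fields (alias in parentheses):
#' \describe{
#'   \item{cpap_nonresponse_frac (A)}{proportion of OSA patients who do not
#'     tolerate or improve on CPAP; default 0.3.}
#'   \item{repeat_psg_frac (B)}{proportion of CPAP nonresponders needing a
#'     repeat PSG after an initial PSG/Level II diagnosis; default 0.4.}
#'   \item{psg_cost (C)}{cost of in-laboratory polysomnography; default 555.}
#'   \item{cpap_trial_cost (D)}{cost of an auto-PAP trial; default 0.}
#'   \item{l3_failure_rate (E)}{nondiagnostic (technical failure) rate of a
#'     Level III home study; default 0.1.}
#'   \item{l3_sensitivity (F)}{Level III sensitivity; default 0.85.}
#'   \item{l3_specificity (G)}{Level III specificity; default 0.85.}
#'   \item{single_followup_frac (H)}{proportion of CPAP nonresponders after a
#'     positive initial Level III study needing only one follow-up study;
#'     the remaining 1 - H need an additional titration PSG; default 0.6.}
#'   \item{l3_cost (I)}{cost of a Level III study; default 167.}
#'   \item{l2_failure_rate (J)}{nondiagnostic rate of a Level II home
#'     polysomnogram; default 0.15.}
#'   \item{l2_cost (K)}{cost of a Level II study; default 300.}
#' }
#'
#' @param ... named scalar overrides, by long field name or A-K alias. A
#'   single named list may be supplied instead.
#' @return an object of class `osa_parameters` (a named list of the 11
#'   scalars under their long names).
#' @examples
#' model_parameters()               # base-case defaults
#' model_parameters(K = 470)        # probe a dearer Level II study
#' model_parameters(l2_cost = 470)  # same thing
#' @seealso [default_parameters()], [validate_parameters()],
#'   [load_parameters()]
#' @export
model_parameters <- function(...) {
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1L]])) {
    overrides <- overrides[[1L]]
  }
  vals <- as.list(stats::setNames(.param_table$default, .param_table$field))
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(!nzchar(nm))) {
      stop("parameter overrides must be named", call. = FALSE)
    }
    canon <- canonical_field(nm)
    if (anyDuplicated(canon)) {
      stop("duplicate parameter field: '",
           canon[duplicated(canon)][1L], "'", call. = FALSE)
    }
    for (i in seq_along(overrides)) {
      v <- overrides[[i]]
      if (!is.numeric(v) || length(v) != 1L) {
        stop("parameter '", nm[i], "' must be a single number", call. = FALSE)
      }
      vals[[canon[i]]] <- as.numeric(v)
    }
  }
  structure(vals, class = "osa_parameters", currency = "CAD")
}

#' Base-case model parameters
#'
#' The British Columbia base-case values used throughout the worked
#' examples (see [model_parameters()] for field meanings).
#'
#' @return an `osa_parameters` object.
#' @export
default_parameters <- function() model_parameters()

#' Validate a model parameter set
#'
#' Checks every field: present, a single finite number; proportions in the
#' closed interval \[0, 1\]; costs nonnegative. Validation failures are
#' reported as data, not raised as conditions.
#'
#' @param params an `osa_parameters` object (or coercible named list).
#' @return a data frame with columns `field` and `problem`, one row per
#'   violated invariant; zero rows iff the set is valid.
#' @export
validate_parameters <- function(params) {
  field <- character(0)
  problem <- character(0)
  note <- function(f, msg) {
    field <<- c(field, f)
    problem <<- c(problem, msg)
  }
  for (i in seq_len(nrow(.param_table))) {
    f <- .param_table$field[i]
    v <- params[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      note(f, "must be a single finite number")
      next
    }
    if (.param_table$kind[i] == "proportion") {
      if (v < 0 || v > 1) note(f, "must lie in [0, 1]")
    } else {
      if (v < 0) note(f, "must be nonnegative")
    }
  }
  data.frame(field = field, problem = problem, stringsAsFactors = FALSE)
}

stop_if_invalid <- function(params) {
  rep <- validate_parameters(params)
  if (nrow(rep) > 0L) {
    stop("invalid model parameters: ",
         paste0(rep$field, " ", rep$problem, collapse = "; "),
         call. = FALSE)
  }
  invisible(params)
}

#' Load model parameters from a configuration document
#'
#' Reads a flat JSON or YAML mapping of parameter overrides (long field
#' names or A-K aliases); unspecified fields take the base-case defaults.
#' A named list is accepted directly. The result is validated.
#'
#' @param source path to a `.json`/`.yaml`/`.yml` file, a named list, or an
#'   existing `osa_parameters` object.
#' @return a validated `osa_parameters` object.
#' @export
load_parameters <- function(source) {
  if (inherits(source, "osa_parameters")) {
    return(stop_if_invalid(source))
  }
  if (is.list(source)) {
    return(stop_if_invalid(model_parameters(source)))
  }
  if (is.character(source) && length(source) == 1L) {
    if (!file.exists(source)) {
      stop("parameter file not found: ", source, call. = FALSE)
    }
    ext <- tolower(tools::file_ext(source))
    doc <- if (ext %in% c("yaml", "yml")) {
      yaml::read_yaml(source)
    } else {
      jsonlite::read_json(source, simplifyVector = TRUE)
    }
    if (length(doc) == 0L) doc <- list()
    return(stop_if_invalid(model_parameters(as.list(doc))))
  }
  stop("'source' must be a file path or a named list", call. = FALSE)
}

#' Save model parameters to JSON or YAML
#'
#' Writes the full resolved parameter set (long field names). Round-trips
#' with [load_parameters()].
#'
#' @param params an `osa_parameters` object.
#' @param path output path; format chosen by extension (`.yaml`/`.yml` for
#'   YAML, anything else JSON).
#' @return `path`, invisibly.
#' @export
save_parameters <- function(params, path) {
  stop_if_invalid(params)
  vals <- unclass(params)
  attributes(vals) <- list(names = names(vals))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(vals, path)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @export
print.osa_parameters <- function(x, ...) {
  cat("Diagnostic-pathway model parameters (",
      attr(x, "currency") %||% "unitless", "):\n", sep = "")
  for (i in seq_len(nrow(.param_table))) {
    f <- .param_table$field[i]
    cat(sprintf("  %-22s (%s) = %g\n", f, .param_table$alias[i], x[[f]]))
  }
  invisible(x)
}

#' Define an evaluation scenario
#'
#' A scenario couples a parameter set with a pretest probability of OSA,
#' the unit at which expected costs are evaluated.
#'
#' @param params an `osa_parameters` object (validated).
#' @param pretest_prob probability in \[0, 1\] that the referred patient has
#'   OSA before any testing.
#' @return an object of class `osa_scenario`.
#' @examples
#' sc <- scenario(default_parameters(), 0.5)
#' @export
scenario <- function(params = default_parameters(), pretest_prob) {
  stop_if_invalid(params)
  if (!is.numeric(pretest_prob) || length(pretest_prob) != 1L ||
      !is.finite(pretest_prob) || pretest_prob < 0 || pretest_prob > 1) {
    stop("'pretest_prob' must be a single probability in [0, 1]",
         call. = FALSE)
  }
  structure(list(params = params, pretest_prob = as.numeric(pretest_prob)),
            class = "osa_scenario")
}

#' @export
print.osa_scenario <- function(x, ...) {
  cat("OSA evaluation scenario: pretest probability =", x$pretest_prob, "\n")
  print(x$params)
  invisible(x)
}
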