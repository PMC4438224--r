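#' @title Pregnancy-arm cohort model
#' @description Builds the model's pregnancy arms (normal, GDM,
#'   overweight) as decision trees from a `model_config` and computes
#'   per-case expected cost breakdowns (mother / child / total) and
#'   incremental costs versus the normal-pregnancy comparator.
#' @name cohort_model
NULL

MODEL_ARMS <- c("normal", "gdm", "overweight")

#' Per-case cost breakdown
#'
#' @param mother expected maternal cost (USD).
#' @param child expected child cost (USD).
#' @return object of class `cost_breakdown` with elements `mother`,
#'   `child`, `total` (`total = mother + child`).
#' @export
cost_breakdown <- function(mother, child) {
  stopifnot(is.numeric(mother), length(mother) == 1L, is.finite(mother),
            is.numeric(child), length(child) == 1L, is.finite(child))
  structure(list(mother = as.numeric(mother), child = as.numeric(child),
                 total = as.numeric(mother) + as.numeric(child)),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("<cost_breakdown> mother %s + child %s = total %s\n",
              fmt_usd(x$mother), fmt_usd(x$child), fmt_usd(x$total)))
  invisible(x)
}

#' Expected complication cost under independent events
#'
#' The probability-weighted complication cost of an arm, treating the
#' complications as independent marginal events whose expected costs add:
#' each side's component is the sum over that side's events of
#' `probability * unit cost`. Event side is determined by the cost-item
#' prefix (`Mother_*` accrues to the mother; everything else to the
#' child).
#'
#' @param probabilities named proportion vector (complication name ->
#'   probability), e.g. one element of `config$probabilities`.
#' @param costs the `costs` element of a `model_config` (or any list with
#'   an `entries` named USD vector).
#' @return a [cost_pair()] of expected mother and child complication
#'   costs (routine delivery cost excluded).
#' @export
#' @examples
#' cfg <- builtin_paper_parameters()
#' expected_complication_cost(cfg$probabilities$gdm_untreated, cfg$costs)
expected_complication_cost <- function(probabilities, costs) {
  stopifnot(is.numeric(probabilities))
  if (length(probabilities) == 0L) return(cost_pair(0, 0))
  nm <- names(probabilities)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("probabilities must be a named vector of complication probabilities",
         call. = FALSE)
  }
  unmatched <- setdiff(nm, names(costs$entries))
  if (length(unmatched) > 0L) {
    stop(sprintf("complication(s) without a cost entry: %s",
                 paste(unmatched, collapse = ", ")), call. = FALSE)
  }
  contrib <- probabilities * costs$entries[nm]
  side <- cost_side(nm)
  cost_pair(sum(contrib[side == "mother"]), sum(contrib[side == "child"]))
}

# chain of binary chance nodes, one per complication event; event edges
# carry the unit cost on the appropriate side, every leaf carries the
# routine delivery cost. Node ids are generated fresh in each subtree so
# the expanded tree keeps unique ids.
build_complication_chain <- function(events, routine_cost, arm_label) {
  counter <- 0L
  next_id <- function(stub) {
    counter <<- counter + 1L
    sprintf("%s_%s_%d", arm_label, stub, counter)
  }
  build <- function(i) {
    if (i > nrow(events)) {
      return(terminal_node(next_id("end"), cost_pair(routine_cost, 0),
                           label = "delivery"))
    }
    ev <- events[i, ]
    cost <- if (ev$side == "mother") cost_pair(ev$cost, 0) else
      cost_pair(0, ev$cost)
    # both branches expand the remaining chain independently, so the tree
    # enumerates every complication combination explicitly
    chance_node(next_id("n"), list(
      tree_edge(build(i + 1L), ev$p, cost),
      tree_edge(build(i + 1L), 1 - ev$p, cost_pair(0, 0))
    ), label = ev$name)
  }
  build(1L)
}

#' Build a pregnancy arm as a decision tree
#'
#' Two modes are available. In `"calibrated"` mode (the default where
#' calibration rows exist) the arm is a single terminal node carrying the
#' configuration's printed per-case mother/child totals, so downstream
#' results reproduce the published base case exactly. In `"mechanistic"`
#' mode the arm is a transparent chain of chance nodes, one per
#' complication: each path accrues the routine delivery cost plus the unit
#' costs of the complications that occur, with the macrosomia split
#' (macrosomic vs normal child) placed first where present. Under this
#' wiring the rollback value equals
#' `routine + sum(p * c)` — the independent-complications reading.
#'
#' @param name one of `"normal"`, `"gdm"`, `"overweight"`.
#' @param config a `model_config`.
#' @param mode `"calibrated"` or `"mechanistic"`. Defaults to calibrated
#'   when the config carries a calibration row for the arm, mechanistic
#'   otherwise. The normal arm is always a single routine-cost terminal.
#' @param gdm_source which probability table feeds the mechanistic GDM
#'   arm: `"gdm_untreated"` (default, the conservative untreated/control
#'   estimates) or `"gdm_treated"`.
#' @param overweight_source probability table for the mechanistic
#'   overweight arm (default `"obese"`).
#' @return an object of class `cost_arm`: list with `name`, `tree`
#'   (a valid `decision_tree`), `mode`, `source_table`.
#' @export
#' @examples
#' cfg <- builtin_paper_parameters()
#' per_case_cost(build_arm("gdm", cfg))          # calibrated Table row
#' per_case_cost(build_arm("gdm", cfg, mode = "mechanistic"))
build_arm <- function(name, config,
                      mode = c("auto", "calibrated", "mechanistic"),
                      gdm_source = c("gdm_untreated", "gdm_treated"),
                      overweight_source = "obese") {
  stopifnot(inherits(config, "model_config"))
  if (!name %in% MODEL_ARMS) {
    stop(sprintf("unknown arm name '%s' (expected one of: %s)", name,
                 paste(MODEL_ARMS, collapse = ", ")), call. = FALSE)
  }
  mode <- match.arg(mode)
  gdm_source <- match.arg(gdm_source)
  routine <- config$costs$routine_normal_cost

  if (mode == "auto") {
    mode <- if (!is.null(config$calibration[[name]])) "calibrated" else
      "mechanistic"
  }

  if (name == "normal") {
    # comparator: routine pregnancy and vaginal delivery, no complications
    tree <- decision_tree(
      terminal_node("normal_delivery", cost_pair(routine, 0),
                    label = "routine pregnancy and vaginal delivery"),
      arm_name = "normal")
    return(structure(list(name = name, tree = tree, mode = mode,
                          source_table = "normal"), class = "cost_arm"))
  }

  if (mode == "calibrated") {
    cal <- config$calibration[[name]]
    if (is.null(cal)) {
      stop(sprintf("calibrated mode requires a calibration row for arm '%s'",
                   name), call. = FALSE)
    }
    tree <- decision_tree(
      terminal_node(paste0(name, "_calibrated"),
                    cost_pair(cal$mother, cal$child),
                    label = sprintf("%s pregnancy (calibrated per-case totals)",
                                    name)),
      arm_name = name)
    return(structure(list(name = name, tree = tree, mode = mode,
                          source_table = "calibration"), class = "cost_arm"))
  }

  # mechanistic
  src <- if (name == "gdm") gdm_source else overweight_source
  probs <- config$probabilities[[src]]
  if (is.null(probs)) {
    stop(sprintf("mechanistic mode: probability table '%s' absent from config",
                 src), call. = FALSE)
  }
  nm <- names(probs)
  unmatched <- setdiff(nm, names(config$costs$entries))
  if (length(unmatched) > 0L) {
    stop(sprintf("mechanistic mode: complication(s) without a cost entry: %s",
                 paste(unmatched, collapse = ", ")), call. = FALSE)
  }
  # macrosomia (delivery outcome) first, then the remaining complications
  ord <- order(nm != "Child_macrosomia", nm)
  events <- data.frame(name = nm[ord],
                       p = unname(probs[ord]),
                       cost = unname(config$costs$entries[nm[ord]]),
                       side = cost_side(nm[ord]),
                       stringsAsFactors = FALSE)
  tree <- decision_tree(build_complication_chain(events, routine, name),
                        arm_name = name)
  structure(list(name = name, tree = tree, mode = mode, source_table = src),
            class = "cost_arm")
}

#' Per-case expected cost of an arm
#'
#' Rolls back the arm's decision tree and returns the expected cost per
#' pregnancy/delivery as a mother / child / total breakdown. For a
#' calibrated arm this reproduces the configuration's printed totals
#' exactly.
#'
#' @param arm a `cost_arm` from [build_arm()].
#' @return a [cost_breakdown()].
#' @export
per_case_cost <- function(arm) {
  stopifnot(inherits(arm, "cost_arm"))
  ev <- expected_value(arm$tree)
  cost_breakdown(ev$mother, ev$child)
}

#' Incremental per-case cost between two arms
#'
#' @param arm the condition arm (`cost_arm`).
#' @param reference the comparator arm (`cost_arm`), usually the normal
#'   pregnancy arm.
#' @return `total(arm) - total(reference)` in USD (may be negative for
#'   hypothetical configurations).
#' @export
#' @examples
#' cfg <- builtin_paper_parameters()
#' incremental_cost(build_arm("gdm", cfg), build_arm("normal", cfg))  # 7803
incremental_cost <- function(arm, reference) {
  per_case_cost(arm)$total - per_case_cost(reference)$total
}

#' @export
print.cost_arm <- function(x, ...) {
  cat(sprintf("<cost_arm> '%s' (%s mode, source: %s)\n",
              x$name, x$mode, x$source_table))
  print(per_case_cost(x))
  invisible(x)
}
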