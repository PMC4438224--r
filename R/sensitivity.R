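#' @title One-way deterministic sensitivity analysis
#' @description Recomputes the per-case incremental cost and the national
#'   budget impact while varying one parameter at a time (default +/-20%,
#'   the variation used when no statistical distributions are available),
#'   and ranks parameters tornado-style by the spread of the budget-impact
#'   response.
#' @name sensitivity
NULL

SENSITIVITY_PARAMETERS <- c("incidence", "condition_total_cost",
                            "normal_pregnancy_cost",
                            "child_complication_cost",
                            "mother_complication_cost")

#' Define a sensitivity scenario
#'
#' @param parameter one of `"incidence"`, `"condition_total_cost"`,
#'   `"normal_pregnancy_cost"`, `"child_complication_cost"`,
#'   `"mother_complication_cost"`.
#' @param delta signed relative change (e.g. `-0.20` for a 20% decrease);
#'   must exceed -1.
#' @return object of class `sensitivity_scenario`.
#' @export
sensitivity_scenario <- function(parameter, delta) {
  if (!parameter %in% SENSITIVITY_PARAMETERS) {
    stop(sprintf("unknown sensitivity parameter '%s' (expected one of: %s)",
                 parameter, paste(SENSITIVITY_PARAMETERS, collapse = ", ")),
         call. = FALSE)
  }
  stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta),
            delta > -1)
  structure(list(parameter = parameter, delta = delta),
            class = "sensitivity_scenario")
}

#' Apply a one-way sensitivity scenario
#'
#' Parameter semantics: `incidence` scales the condition incidence by
#' `1 + delta`, leaving all costs (and hence the per-case incremental)
#' unchanged; `condition_total_cost` scales the condition arm's total
#' per-case cost, the reference cost staying fixed;
#' `normal_pregnancy_cost` scales the reference arm's total (the routine
#' delivery cost) only; `child_complication_cost` and
#' `mother_complication_cost` scale that component of the condition arm
#' only. In every case `per_case = adjusted condition total - adjusted
#' reference total` and `bia = annual_cases(adjusted incidence) x
#' per_case`.
#'
#' @param config a `model_config` (population block).
#' @param breakdowns list with elements `condition` and `reference`, each
#'   a [cost_breakdown()] (e.g. from [per_case_cost()]).
#' @param scenario a [sensitivity_scenario()].
#' @return list with `parameter`, `delta`, `per_case` (USD), `bia` (USD),
#'   and `annual_cases` (real, under the adjusted incidence).
#' @export
apply_scenario <- function(config, breakdowns, scenario) {
  stopifnot(inherits(config, "model_config"),
            inherits(scenario, "sensitivity_scenario"),
            inherits(breakdowns$condition, "cost_breakdown"),
            inherits(breakdowns$reference, "cost_breakdown"))
  d <- scenario$delta
  cond <- breakdowns$condition
  ref <- breakdowns$reference
  incidence <- config$population$condition_incidence

  cond_total <- cond$total
  ref_total <- ref$total
  switch(scenario$parameter,
    incidence = {
      incidence <- incidence * (1 + d)
    },
    condition_total_cost = {
      cond_total <- cond$total * (1 + d)
    },
    normal_pregnancy_cost = {
      ref_total <- ref$total * (1 + d)
    },
    child_complication_cost = {
      cond_total <- cond$mother + cond$child * (1 + d)
    },
    mother_complication_cost = {
      cond_total <- cond$mother * (1 + d) + cond$child
    })
  if (incidence > 1) {
    stop(sprintf("scenario pushes incidence to %g > 1", incidence),
         call. = FALSE)
  }
  per_case <- cond_total - ref_total
  cases <- annual_cases(annual_pregnancies(config$population), incidence)
  list(parameter = scenario$parameter, delta = d,
       per_case = per_case, bia = cases * per_case, annual_cases = cases)
}

#' Run the full one-way sensitivity table
#'
#' One row per (parameter, delta) combination over all five parameters,
#' preceded by the base case, for the condition arm versus the reference
#' arm.
#'
#' @param config a `model_config`.
#' @param deltas non-empty numeric vector of relative changes (default
#'   `c(-0.2, 0.2)`).
#' @param arm condition arm name passed to [build_arm()] (default
#'   `"gdm"`).
#' @param reference reference arm name (default `"normal"`).
#' @param mode arm-evaluation mode passed to [build_arm()].
#' @return object of class `sensitivity_table`: `base` (list with
#'   `per_case`, `bia`), `rows` (data.frame with columns `parameter`,
#'   `delta`, `per_case`, `bia`), and the arm names.
#' @export
#' @examples
#' tab <- run_table(builtin_paper_parameters())
#' subset(tab$rows, parameter == "incidence")
run_table <- function(config, deltas = c(-0.2, 0.2), arm = "gdm",
                      reference = "normal", mode = "auto") {
  stopifnot(inherits(config, "model_config"), length(deltas) >= 1L,
            is.numeric(deltas))
  breakdowns <- list(condition = per_case_cost(build_arm(arm, config,
                                                         mode = mode)),
                     reference = per_case_cost(build_arm(reference, config,
                                                         mode = mode)))
  base <- apply_scenario(config, breakdowns,
                         sensitivity_scenario("incidence", 0))
  rows <- expand.grid(parameter = SENSITIVITY_PARAMETERS, delta = deltas,
                      stringsAsFactors = FALSE)
  rows <- rows[order(match(rows$parameter, SENSITIVITY_PARAMETERS),
                     rows$delta), , drop = FALSE]
  res <- lapply(seq_len(nrow(rows)), function(i) {
    apply_scenario(config, breakdowns,
                   sensitivity_scenario(rows$parameter[[i]], rows$delta[[i]]))
  })
  rows$per_case <- vapply(res, `[[`, numeric(1), "per_case")
  rows$bia <- vapply(res, `[[`, numeric(1), "bia")
  rownames(rows) <- NULL
  structure(list(base = list(per_case = base$per_case, bia = base$bia),
                 rows = rows, arm = arm, reference = reference),
            class = "sensitivity_table")
}

#' Tornado ranking of sensitivity parameters
#'
#' Orders parameters by descending spread of the budget-impact response,
#' `|bia(+delta) - bia(-delta)|` at the largest symmetric delta present;
#' ties break alphabetically. The table's delta set must be symmetric
#' around zero for every parameter.
#'
#' @param table a `sensitivity_table` from [run_table()].
#' @return data.frame with columns `parameter`, `bia_low`, `bia_high`,
#'   `range`, ordered by descending `range`.
#' @export
tornado_order <- function(table) {
  stopifnot(inherits(table, "sensitivity_table"))
  rows <- table$rows
  deltas <- sort(unique(rows$delta))
  nonzero <- setdiff(deltas, 0)
  if (length(nonzero) == 0L ||
      !setequal(round(nonzero, 12), round(-nonzero, 12))) {
    stop("tornado_order requires a symmetric delta set (each +delta paired with -delta)",
         call. = FALSE)
  }
  dmax <- max(nonzero)
  params <- sort(unique(rows$parameter))
  out <- do.call(rbind, lapply(params, function(p) {
    lo <- rows$bia[rows$parameter == p & rows$delta == -dmax]
    hi <- rows$bia[rows$parameter == p & rows$delta == dmax]
    data.frame(parameter = p, bia_low = lo, bia_high = hi,
               range = abs(hi - lo), stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$range, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.sensitivity_table <- function(x, ...) {
  cat(sprintf("<sensitivity_table> %s vs %s\n", x$arm, x$reference))
  cat(sprintf("  base: per-case %s, budget impact %s\n",
              fmt_usd(x$base$per_case), fmt_usd(x$base$bia)))
  df <- x$rows
  df$per_case <- fmt_usd(df$per_case)
  df$bia <- fmt_usd(df$bia)
  print(df, row.names = FALSE)
  invisible(x)
}
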