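#' @title Budget-impact analysis
#' @description Translates a per-case incremental cost into a national
#'   annual burden through the chain population -> annual pregnancies ->
#'   annual condition cases -> cases x incremental cost. Intermediates are
#'   kept unrounded; integers appear only in display fields.
#' @name budget_impact
NULL

#' Annual number of pregnancies
#'
#' @param pop the `population` element of a `model_config` (list with
#'   `population_size` and `pregnancy_rate_per_1000`).
#' @return `population_size * pregnancy_rate_per_1000 / 1000` (real).
#' @export
#' @examples
#' annual_pregnancies(list(population_size = 313847500,
#'                         pregnancy_rate_per_1000 = 13.68))  # 4293433.8
annual_pregnancies <- function(pop) {
  stopifnot(is.numeric(pop$population_size),
            is.numeric(pop$pregnancy_rate_per_1000),
            pop$population_size >= 0, pop$pregnancy_rate_per_1000 >= 0)
  pop$population_size * pop$pregnancy_rate_per_1000 / 1000
}

#' Annual number of condition cases
#'
#' @param pregnancies annual number of pregnancies (real).
#' @param incidence condition incidence as a proportion in `[0, 1]`.
#' @return the unrounded case count `pregnancies * incidence`; round with
#'   [round_half_away()] for display.
#' @export
annual_cases <- function(pregnancies, incidence) {
  stopifnot(is.numeric(pregnancies), pregnancies >= 0,
            is.numeric(incidence), incidence >= 0, incidence <= 1)
  pregnancies * incidence
}

#' National annual budget impact of a condition
#'
#' Chains [annual_pregnancies()], [annual_cases()] and
#' [incremental_cost()]: the annual burden is the (unrounded) case count
#' times the per-case incremental cost of the condition arm versus the
#' reference arm.
#'
#' @param config a `model_config` supplying the population block.
#' @param arm condition `cost_arm` (e.g. the GDM arm).
#' @param reference comparator `cost_arm` (normal pregnancy).
#' @return object of class `budget_impact`: `annual_pregnancies`,
#'   `annual_cases` (real), `annual_cases_display` (rounded
#'   half-away-from-zero), `per_case_incremental`, `annual_budget_impact`
#'   (USD), plus the arm names.
#' @export
#' @examples
#' cfg <- builtin_paper_parameters()
#' compute_budget_impact(cfg, build_arm("gdm", cfg), build_arm("normal", cfg))
compute_budget_impact <- function(config, arm, reference) {
  stopifnot(inherits(config, "model_config"),
            inherits(arm, "cost_arm"), inherits(reference, "cost_arm"))
  pregnancies <- annual_pregnancies(config$population)
  cases <- annual_cases(pregnancies, config$population$condition_incidence)
  per_case <- incremental_cost(arm, reference)
  structure(list(
    arm = arm$name,
    reference = reference$name,
    annual_pregnancies = pregnancies,
    annual_cases = cases,
    annual_cases_display = round_half_away(cases),
    per_case_incremental = per_case,
    annual_budget_impact = cases * per_case
  ), class = "budget_impact")
}

#' @export
print.budget_impact <- function(x, ...) {
  cat("<budget_impact>\n")
  cat(sprintf("  arm vs reference:      %s vs %s\n", x$arm, x$reference))
  cat(sprintf("  annual pregnancies:    %s\n",
              formatC(x$annual_pregnancies, format = "f", digits = 1,
                      big.mark = ",")))
  cat(sprintf("  annual cases:          %s (display: %s)\n",
              formatC(x$annual_cases, format = "f", digits = 3,
                      big.mark = ","),
              formatC(x$annual_cases_display, format = "d", big.mark = ",")))
  cat(sprintf("  per-case incremental:  %s\n", fmt_usd(x$per_case_incremental)))
  cat(sprintf("  annual budget impact:  %s\n", fmt_usd(x$annual_budget_impact)))
  invisible(x)
}
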