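#' @title Report generation and command-line surface
#' @description High-level commands tying configuration loading, arm
#'   evaluation, budget impact and sensitivity analysis into reproducible
#'   reports. Every report embeds a run manifest (config checksum,
#'   command, schema version, software version, timestamp); report bodies
#'   are deterministic given identical inputs. A thin command-line wrapper
#'   over these functions ships in `inst/cli/perinatal-costs.R`.
#' @name cli_reporting
NULL

#' Build a run manifest
#'
#' @param config_path path of the configuration the run used.
#' @param command free-text description of the command and flags.
#' @param seed optional integer seed when random fixtures were generated.
#' @return list with `config_checksum` (MD5), `command`,
#'   `schema_version`, `timestamp` (UTC), `software_version`, `seed`.
#' @export
run_manifest <- function(config_path, command, seed = NULL) {
  list(config_checksum = unname(tools::md5sum(config_path)),
       command = command,
       schema_version = CONFIG_SCHEMA_VERSION,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
       software_version = as.character(utils::packageVersion("perinatalcosts")),
       seed = seed)
}

write_report_body <- function(table, format, out) {
  if (format == "csv") {
    utils::write.csv(table, out, row.names = FALSE)
  } else {
    jsonlite::write_json(table, out, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(out)
}

finish_report <- function(report, format, out) {
  if (!is.null(out)) {
    write_report_body(report$table, format, out)
    jsonlite::write_json(report$manifest, paste0(out, ".manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(report)
}

#' Evaluate pregnancy arms (base-case report)
#'
#' Computes the per-case mother / child / total cost breakdown for the
#' requested arms. In mechanistic mode the report also carries a
#' provenance table with the per-complication `probability x unit cost`
#' contributions.
#'
#' @param config_path path to a configuration file.
#' @param arms character vector of arm names (default all three).
#' @param mode `"auto"`, `"calibrated"` or `"mechanistic"`.
#' @param format `"csv"` or `"json"` for the written body.
#' @param out optional output file path; the manifest is written next to
#'   it as `<out>.manifest.json`.
#' @return (invisibly when written) list with `manifest`, `table`
#'   (data.frame: arm, mode, mother, child, total) and, in mechanistic
#'   mode, `provenance` (data.frame: arm, complication, probability,
#'   unit_cost, side, expected_cost).
#' @export
cmd_evaluate <- function(config_path,
                         arms = c("normal", "gdm", "overweight"),
                         mode = "auto", format = c("csv", "json"),
                         out = NULL) {
  format <- match.arg(format)
  config <- load_config(config_path)
  bad <- setdiff(arms, MODEL_ARMS)
  if (length(bad) > 0L) {
    stop(sprintf("unknown arm name(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  built <- lapply(arms, build_arm, config = config, mode = mode)
  rows <- do.call(rbind, lapply(built, function(a) {
    b <- per_case_cost(a)
    data.frame(arm = a$name, mode = a$mode, mother = b$mother,
               child = b$child, total = b$total, stringsAsFactors = FALSE)
  }))
  report <- list(manifest = run_manifest(config_path,
                                         sprintf("evaluate --arms %s --mode %s",
                                                 paste(arms, collapse = ","),
                                                 mode)),
                 table = rows)
  mech <- vapply(built, function(a) a$mode == "mechanistic", logical(1))
  if (any(mech)) {
    report$provenance <- do.call(rbind, lapply(built[mech], function(a) {
      probs <- config$probabilities[[a$source_table]]
      if (length(probs) == 0L) return(NULL)
      nm <- names(probs)
      data.frame(arm = a$name, complication = nm,
                 probability = unname(probs),
                 unit_cost = unname(config$costs$entries[nm]),
                 side = cost_side(nm),
                 expected_cost = unname(probs * config$costs$entries[nm]),
                 stringsAsFactors = FALSE)
    }))
  }
  finish_report(report, format, out)
}

#' Budget-impact report
#'
#' @inheritParams cmd_evaluate
#' @param arm condition arm name (default `"gdm"`).
#' @param reference reference arm name (default `"normal"`).
#' @param population,rate,incidence optional overrides of the
#'   configuration's population size, pregnancy rate per 1,000, and
#'   condition incidence; every override is logged to standard error.
#' @return list with `manifest`, `result` (the `budget_impact` object)
#'   and `table` (its one-row data.frame form).
#' @export
cmd_bia <- function(config_path, arm = "gdm", reference = "normal",
                    population = NULL, rate = NULL, incidence = NULL,
                    mode = "auto", format = c("csv", "json"), out = NULL) {
  format <- match.arg(format)
  config <- load_config(config_path)
  log_override <- function(field, value) {
    message(sprintf("[override] population.%s <- %s", field,
                    format(value, scientific = FALSE)))
  }
  if (!is.null(population)) {
    config$population$population_size <- as.numeric(population)
    log_override("population_size", population)
  }
  if (!is.null(rate)) {
    config$population$pregnancy_rate_per_1000 <- as.numeric(rate)
    log_override("pregnancy_rate_per_1000", rate)
  }
  if (!is.null(incidence)) {
    config$population$condition_incidence <- parse_proportion(incidence,
                                                              "incidence")
    log_override("condition_incidence",
                 config$population$condition_incidence)
  }
  res <- compute_budget_impact(config,
                               build_arm(arm, config, mode = mode),
                               build_arm(reference, config, mode = mode))
  table <- data.frame(arm = res$arm, reference = res$reference,
                      annual_pregnancies = res$annual_pregnancies,
                      annual_cases = res$annual_cases,
                      annual_cases_display = res$annual_cases_display,
                      per_case_incremental = res$per_case_incremental,
                      annual_budget_impact = res$annual_budget_impact,
                      stringsAsFactors = FALSE)
  report <- list(manifest = run_manifest(config_path,
                                         sprintf("bia --arm %s --reference %s",
                                                 arm, reference)),
                 result = res, table = table)
  finish_report(report, format, out)
}

#' Sensitivity-analysis report
#'
#' @inheritParams cmd_bia
#' @param deltas numeric vector of relative changes (default
#'   `c(-0.2, 0.2)`).
#' @return list with `manifest`, `result` (the `sensitivity_table`),
#'   `table` (data.frame: parameter, delta, per_case_usd, bia_usd, with a
#'   leading base row), and `tornado` (the [tornado_order()] ranking when
#'   the delta set is symmetric).
#' @export
cmd_sensitivity <- function(config_path, deltas = c(-0.2, 0.2),
                            arm = "gdm", reference = "normal",
                            mode = "auto", format = c("csv", "json"),
                            out = NULL) {
  format <- match.arg(format)
  config <- load_config(config_path)
  tab <- run_table(config, deltas = deltas, arm = arm,
                   reference = reference, mode = mode)
  body <- rbind(
    data.frame(parameter = "base", delta = 0,
               per_case_usd = tab$base$per_case, bia_usd = tab$base$bia,
               stringsAsFactors = FALSE),
    data.frame(parameter = tab$rows$parameter, delta = tab$rows$delta,
               per_case_usd = tab$rows$per_case, bia_usd = tab$rows$bia,
               stringsAsFactors = FALSE))
  report <- list(manifest = run_manifest(config_path,
                                         sprintf("sensitivity --deltas %s",
                                                 paste(deltas, collapse = ","))),
                 result = tab, table = body)
  nonzero <- setdiff(sort(unique(deltas)), 0)
  if (length(nonzero) > 0L &&
      setequal(round(nonzero, 12), round(-nonzero, 12))) {
    report$tornado <- tornado_order(tab)
  }
  finish_report(report, format, out)
}

#' Full pilot reproduction report
#'
#' Single command reproducing the published pilot outputs for the default
#' configuration: the per-arm base-case table, the national budget impact
#' of GDM (annual cases and the more-than-$1.8-billion annual burden), and
#' the +/-20% one-way sensitivity table. The report's `notes` field spells
#' out the known rounding discrepancies in the published tables (base
#' budget-impact cell and the +20% condition-cost cell) so they are never
#' silently chased.
#'
#' @inheritParams cmd_bia
#' @return list with `manifest`, `evaluate`, `bia`, `sensitivity`,
#'   `notes`.
#' @export
cmd_pilot <- function(config_path, population = NULL, rate = NULL,
                      incidence = NULL, format = c("csv", "json"),
                      out = NULL) {
  format <- match.arg(format)
  ev <- cmd_evaluate(config_path, mode = "auto", format = format)
  bia <- cmd_bia(config_path, population = population, rate = rate,
                 incidence = incidence, format = format)
  sens <- cmd_sensitivity(config_path, format = format)
  notes <- c(
    paste("Budget impact computed from unrounded case counts and the",
          "calibrated per-case totals; the published sensitivity table's",
          "base cell ($1,842,525,634) implies an unrounded per-case",
          "incremental of ~$7,802.72 that is not recoverable from the",
          "printed per-case components, a relative difference of ~3.6e-5",
          "from this report's value."),
    paste("At +20% on the condition arm's total cost the per-case",
          "incremental computed from rounded printed inputs is $10,922;",
          "the published table prints $10,921 (consistent only with",
          "unrounded internals)."))
  report <- list(manifest = run_manifest(config_path, "pilot"),
                 evaluate = ev$table, bia = bia$table,
                 sensitivity = sens$table, tornado = sens$tornado,
                 notes = notes)
  if (!is.null(out)) {
    stub <- sub("\\.(csv|json)$", "", out)
    write_report_body(ev$table, format,
                      paste0(stub, "_evaluate.", format))
    write_report_body(bia$table, format, paste0(stub, "_bia.", format))
    write_report_body(sens$table, format,
                      paste0(stub, "_sensitivity.", format))
    jsonlite::write_json(report$manifest, paste0(stub, ".manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(report)
}

#' Validate a configuration file
#'
#' @param config_path path to a configuration file.
#' @return the validated `model_config`, invisibly; errors describe the
#'   offending field.
#' @export
cmd_validate <- function(config_path) {
  config <- load_config(config_path)
  message(sprintf("configuration OK: %d arm table(s), %d cost item(s), %d odds ratio(s)",
                  length(config$probabilities), length(config$costs$entries),
                  nrow(config$odds_ratios)))
  invisible(config)
}
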