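#' @title Model parameters
#' @description Typed container (`model_config`) and validated readers for
#'   the model's parameter bundle: perinatal complication probabilities per
#'   pregnancy arm, unit costs, treatment-effect odds ratios, macrosomia
#'   delivery-strategy probabilities, population demographics, and optional
#'   per-arm calibration totals.
#' @name parameters
NULL

CONFIG_SCHEMA_VERSION <- 1L

# canonical cost-item vocabulary (the cost table's own names, spaces
# normalized to underscores); complication probabilities must reference
# these keys
CANONICAL_COST_ITEMS <- c(
  "Child_brachplexus", "Child_hyperbili", "Child_hypoglycemia",
  "Comp_child_IUFD", "Mp_child_IUGR", "Child_macrosomia", "Child_NICU",
  "Child_overweight", "Child_premature", "Child_pretermdelivery",
  "Child_resp_distress", "Child_shoulder",
  "Mother_anemia", "Mother_bodymass", "Mother_cesarean",
  "Mother_episiotomy", "Mother_gdm", "Mother_gest", "Mother_gesthyper",
  "Mother_hydramnion", "Mother_hypertension", "Mother_induction",
  "Mother_PIH", "Mother_pre_eclampsia", "Mother_PROM", "Mother_shoulder",
  "Mother_still_birth", "Mother_weight_gain")

ARM_NAMES <- c("gdm_treated", "gdm_untreated", "obese", "non_obese", "normal")
STRATEGY_NAMES <- c("elective_induction", "elective_cesarean", "expectant")

ALLOWED_TOP_KEYS <- c("schema_version", "cost_year", "currency",
                      "probabilities", "significance", "costs",
                      "odds_ratios", "strategies", "population",
                      "calibration", "overrides", "mortality_probability")

canonical_key <- function(x) gsub("[ ]+", "_", trimws(x))

# does a cost item accrue to the mother or the child?
cost_side <- function(name) {
  ifelse(startsWith(name, "Mother_"), "mother", "child")
}

#' Load and validate a model configuration
#'
#' Reads a YAML or JSON configuration document (schema version 1),
#' converts any `"x%"` percentage notation to proportions, normalizes cost
#' item keys (spaces to underscores), and validates the whole bundle:
#' unknown keys are rejected, probabilities must lie in `[0, 1]`, every
#' complication named in a probability table must resolve to a cost entry,
#' odds-ratio confidence bounds must bracket the point estimate, and the
#' population block must be positive with incidence at most 1.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return a validated object of class `model_config` with elements
#'   `probabilities` (named list of named proportion vectors, one per
#'   arm), `costs` (`$entries` named USD vector, `$routine_normal_cost`),
#'   `odds_ratios` (data.frame), `strategies` (named list of named
#'   proportion vectors), `population` (list), `calibration` (named list
#'   of `cost_breakdown`s or `NULL`), and `metadata`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("configuration file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path)
  } else {
    stop(sprintf("unsupported configuration extension '%s' (use yaml or json)",
                 ext), call. = FALSE)
  }
  config_from_document(doc, source = path)
}

# build + validate a model_config from a parsed document
config_from_document <- function(doc, source = "<document>") {
  if (!is.list(doc)) stop("configuration document is not a mapping", call. = FALSE)

  unknown <- setdiff(names(doc), ALLOWED_TOP_KEYS)
  if (length(unknown) > 0L) {
    stop(sprintf("configuration '%s': unknown top-level key(s): %s",
                 source, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  sv <- doc$schema_version %||% NA
  if (!identical(as.integer(sv), CONFIG_SCHEMA_VERSION)) {
    stop(sprintf("configuration '%s': unsupported schema_version '%s' (expected %d)",
                 source, sv, CONFIG_SCHEMA_VERSION), call. = FALSE)
  }

  # --- costs ------------------------------------------------------------
  costs_doc <- doc$costs %||% stop("configuration: missing 'costs' block",
                                   call. = FALSE)
  bad <- setdiff(names(costs_doc), c("routine_normal_cost", "entries"))
  if (length(bad) > 0L) {
    stop(sprintf("costs block: unknown key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  entries <- unlist(costs_doc$entries %||% list())
  names(entries) <- canonical_key(names(entries))
  if (anyDuplicated(names(entries))) {
    stop("costs block: duplicated cost item names after key normalization",
         call. = FALSE)
  }
  if (any(!is.finite(entries)) || any(entries < 0)) {
    stop("costs block: cost entries must be finite and non-negative",
         call. = FALSE)
  }
  routine <- costs_doc$routine_normal_cost %||%
    stop("costs block: missing 'routine_normal_cost'", call. = FALSE)
  stopifnot(is.numeric(routine), length(routine) == 1L, routine >= 0)

  # --- probabilities ----------------------------------------------------
  probs_doc <- doc$probabilities %||% list()
  bad_arms <- setdiff(names(probs_doc), ARM_NAMES)
  if (length(bad_arms) > 0L) {
    stop(sprintf("probabilities block: unknown arm(s): %s (allowed: %s)",
                 paste(bad_arms, collapse = ", "),
                 paste(ARM_NAMES, collapse = ", ")), call. = FALSE)
  }
  probabilities <- lapply(names(probs_doc), function(arm) {
    tbl <- probs_doc[[arm]]
    if (length(tbl) == 0L) return(stats::setNames(numeric(0), character(0)))
    keys <- canonical_key(names(tbl))
    vals <- vapply(seq_along(tbl), function(i) {
      parse_proportion(tbl[[i]], field = sprintf("%s/%s", arm, keys[[i]]))
    }, numeric(1))
    missing <- setdiff(keys, names(entries))
    if (length(missing) > 0L) {
      stop(sprintf("probabilities/%s: complication(s) without a cost entry: %s",
                   arm, paste(missing, collapse = ", ")), call. = FALSE)
    }
    stats::setNames(vals, keys)
  })
  names(probabilities) <- names(probs_doc)

  # --- significance metadata -------------------------------------------
  significance <- doc$significance %||% list()
  for (grp in names(significance)) {
    flags <- significance[[grp]]
    names(significance[[grp]]) <- canonical_key(names(flags))
    ok <- vapply(flags, function(f) f %in% c("S", "NS"), logical(1))
    if (!all(ok)) {
      stop(sprintf("significance/%s: flags must be 'S' or 'NS'", grp),
           call. = FALSE)
    }
  }

  # --- odds ratios ------------------------------------------------------
  ors_doc <- doc$odds_ratios %||% list()
  odds_ratios <- if (length(ors_doc) == 0L) {
    data.frame(outcome = character(0), comparison = character(0),
               odds_ratio = numeric(0), ci_low = numeric(0),
               ci_high = numeric(0), source = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(ors_doc, function(r) {
      need <- c("outcome", "comparison", "odds_ratio", "ci_low", "ci_high")
      miss <- setdiff(need, names(r))
      if (length(miss) > 0L) {
        stop(sprintf("odds_ratios entry: missing field(s): %s",
                     paste(miss, collapse = ", ")), call. = FALSE)
      }
      if (r$odds_ratio <= 0 || r$ci_low <= 0 || r$ci_high <= 0) {
        stop("odds_ratios entry: odds ratio and CI bounds must be positive",
             call. = FALSE)
      }
      if (!(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)) {
        stop(sprintf("odds_ratios entry '%s': point estimate %g outside CI [%g, %g]",
                     r$outcome, r$odds_ratio, r$ci_low, r$ci_high),
             call. = FALSE)
      }
      data.frame(outcome = r$outcome, comparison = r$comparison,
                 odds_ratio = r$odds_ratio, ci_low = r$ci_low,
                 ci_high = r$ci_high, source = r$source %||% NA_character_,
                 stringsAsFactors = FALSE)
    }))
  }

  # --- delivery strategies ---------------------------------------------
  strat_doc <- doc$strategies %||% list()
  bad_strat <- setdiff(names(strat_doc), STRATEGY_NAMES)
  if (length(bad_strat) > 0L) {
    stop(sprintf("strategies block: unknown strategy name(s): %s",
                 paste(bad_strat, collapse = ", ")), call. = FALSE)
  }
  strategies <- lapply(names(strat_doc), function(s) {
    tbl <- strat_doc[[s]]
    vals <- vapply(seq_along(tbl), function(i) {
      parse_proportion(tbl[[i]], field = sprintf("%s/%s", s, names(tbl)[[i]]))
    }, numeric(1))
    stats::setNames(vals, names(tbl))
  })
  names(strategies) <- names(strat_doc)

  # --- population -------------------------------------------------------
  pop_doc <- doc$population %||% stop("configuration: missing 'population' block",
                                      call. = FALSE)
  bad <- setdiff(names(pop_doc),
                 c("population_size", "pregnancy_rate_per_1000",
                   "condition_incidence"))
  if (length(bad) > 0L) {
    stop(sprintf("population block: unknown key(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  population <- list(
    population_size = as.numeric(pop_doc$population_size),
    pregnancy_rate_per_1000 = as.numeric(pop_doc$pregnancy_rate_per_1000),
    condition_incidence = parse_proportion(pop_doc$condition_incidence,
                                           "population/condition_incidence"))
  with(population, {
    if (!(population_size > 0 && pregnancy_rate_per_1000 > 0 &&
          condition_incidence > 0)) {
      stop("population block: all fields must be positive", call. = FALSE)
    }
  })

  # --- calibration ------------------------------------------------------
  cal_doc <- doc$calibration
  calibration <- NULL
  if (!is.null(cal_doc)) {
    calibration <- lapply(names(cal_doc), function(arm) {
      row <- cal_doc[[arm]]
      bad <- setdiff(names(row), c("mother", "child"))
      if (length(bad) > 0L) {
        stop(sprintf("calibration/%s: unknown key(s): %s", arm,
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
      m <- as.numeric(row$mother); c <- as.numeric(row$child)
      if (!is.finite(m) || !is.finite(c) || m < 0 || c < 0 || m + c <= 0) {
        stop(sprintf("calibration/%s: mother/child costs must be non-negative with a positive total",
                     arm), call. = FALSE)
      }
      cost_breakdown(m, c)
    })
    names(calibration) <- names(cal_doc)
  }

  mortality <- doc$mortality_probability %||% 0
  mortality <- parse_proportion(mortality, "mortality_probability")

  structure(list(
    probabilities = probabilities,
    costs = list(entries = entries, routine_normal_cost = as.numeric(routine)),
    odds_ratios = odds_ratios,
    strategies = strategies,
    population = population,
    calibration = calibration,
    metadata = list(schema_version = CONFIG_SCHEMA_VERSION,
                    cost_year = doc$cost_year %||% NA,
                    currency = doc$currency %||% "USD",
                    significance = significance,
                    overrides = doc$overrides %||% list(),
                    mortality_probability = mortality,
                    source = source)
  ), class = "model_config")
}

#' Write a model configuration back to disk
#'
#' Emits the same schema accepted by [load_config()], with all
#' probabilities written as plain proportions (no `%` notation) at 15
#' significant digits, so that a load/write/load round trip reproduces the
#' configuration.
#'
#' @param config a `model_config`.
#' @param path output `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  doc <- list(
    schema_version = CONFIG_SCHEMA_VERSION,
    cost_year = config$metadata$cost_year,
    currency = config$metadata$currency,
    probabilities = lapply(config$probabilities, as.list),
    significance = config$metadata$significance,
    costs = list(routine_normal_cost = config$costs$routine_normal_cost,
                 entries = as.list(config$costs$entries)),
    odds_ratios = lapply(seq_len(nrow(config$odds_ratios)), function(i) {
      as.list(config$odds_ratios[i, , drop = FALSE])
    }),
    strategies = lapply(config$strategies, as.list),
    population = config$population,
    calibration = if (is.null(config$calibration)) NULL else
      lapply(config$calibration, function(b) list(mother = b$mother,
                                                  child = b$child)),
    overrides = config$metadata$overrides,
    mortality_probability = config$metadata$mortality_probability)
  doc <- doc[!vapply(doc, is.null, logical(1))]
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(doc, path, precision = 15L)
  } else if (ext == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop(sprintf("unsupported configuration extension '%s'", ext),
         call. = FALSE)
  }
  invisible(path)
}

#' Built-in US 2011 parameterization
#'
#' Returns the packaged base-case configuration: mild-GDM complication
#' probabilities (treated and untreated arms), obese/non-obese maternal
#' complication rates, the 2011 US unit-cost table (routine normal
#' pregnancy and vaginal delivery at $7,790), macrosomia treatment odds
#' ratios, delivery-strategy probabilities for an estimated fetal weight
#' of 4,500 g, US national demographics (population 313,847,500;
#' 13.68 pregnancies per 1,000; GDM incidence 5.5%), and the printed
#' per-case calibration totals. The Naylor shoulder-dystocia override
#' (14.5%) ships flagged off.
#'
#' @return a validated `model_config`.
#' @export
#' @examples
#' cfg <- builtin_paper_parameters()
#' cfg$costs$routine_normal_cost       # 7790
#' cfg$probabilities$gdm_untreated[["Child_macrosomia"]]  # 0.143
builtin_paper_parameters <- function() {
  path <- system.file("extdata", "us_gdm_2011.yaml", package = "perinatalcosts",
                      mustWork = TRUE)
  load_config(path)
}

#' Convert an odds ratio to a probability
#'
#' Applies an odds ratio to a baseline risk through odds arithmetic:
#' `p = OR * b / (1 - b + OR * b)`. Strictly increasing in both arguments
#' and equal to the baseline at `OR = 1`.
#'
#' @param baseline baseline probability, strictly inside (0, 1).
#' @param odds_ratio positive odds ratio.
#' @return the transformed probability, strictly inside (0, 1). Vectorized
#'   over both arguments.
#' @export
#' @examples
#' or_to_probability(0.143, 0.38)  # ~0.0596: treated macrosomia risk
or_to_probability <- function(baseline, odds_ratio) {
  if (any(!is.finite(baseline)) || any(baseline <= 0) || any(baseline >= 1)) {
    stop("baseline probability must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(odds_ratio)) || any(odds_ratio <= 0)) {
    stop("odds_ratio must be positive and finite", call. = FALSE)
  }
  odds_ratio * baseline / (1 - baseline + odds_ratio * baseline)
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  cat(sprintf("  arms: %s\n", paste(names(x$probabilities), collapse = ", ")))
  cat(sprintf("  cost items: %d (routine normal cost %s)\n",
              length(x$costs$entries), fmt_usd(x$costs$routine_normal_cost)))
  cat(sprintf("  population: %s persons, %.2f pregnancies/1000, incidence %.2f%%\n",
              formatC(x$population$population_size, format = "d", big.mark = ","),
              x$population$pregnancy_rate_per_1000,
              100 * x$population$condition_incidence))
  cat(sprintf("  calibration rows: %s\n",
              if (is.null(x$calibration)) "none"
              else paste(names(x$calibration), collapse = ", ")))
  invisible(x)
}
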