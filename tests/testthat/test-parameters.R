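test_that("the built-in configuration carries the published parameter tables", {
  cfg <- builtin_config()
  expect_s3_class(cfg, "model_config")
  expect_equal(cfg$costs$routine_normal_cost, 7790)
  expect_equal(unname(cfg$costs$entries["Mother_cesarean"]), 4189)
  expect_equal(unname(cfg$costs$entries["Child_NICU"]), 15065)
  expect_equal(unname(cfg$costs$entries["Comp_child_IUFD"]), 82361)
  expect_equal(unname(cfg$costs$entries["Mother_pre_eclampsia"]), 19184)
  expect_length(cfg$costs$entries, 28)

  expect_equal(cfg$probabilities$gdm_untreated[["Child_macrosomia"]], 0.143)
  expect_equal(cfg$probabilities$gdm_untreated[["Mother_cesarean"]], 0.338)
  expect_equal(cfg$probabilities$gdm_treated[["Child_macrosomia"]], 0.059)
  expect_equal(cfg$probabilities$obese[["Mother_pre_eclampsia"]], 0.0589)
  expect_equal(cfg$probabilities$gdm_untreated[["Mother_hydramnion"]], 0.006)
  expect_equal(cfg$probabilities$gdm_untreated[["Mother_still_birth"]], 0.004)

  expect_equal(cfg$population$population_size, 313847500)
  expect_equal(cfg$population$pregnancy_rate_per_1000, 13.68)
  expect_equal(cfg$population$condition_incidence, 0.055)

  expect_equal(nrow(cfg$odds_ratios), 5L)
  expect_equal(cfg$odds_ratios$odds_ratio[[1]], 0.38)
  expect_true(all(cfg$odds_ratios$ci_low <= cfg$odds_ratios$odds_ratio &
                    cfg$odds_ratios$odds_ratio <= cfg$odds_ratios$ci_high))

  expect_equal(cfg$strategies$elective_induction[["cesarean_delivery"]], 0.35)
  expect_equal(cfg$strategies$expectant[["plexus_injury"]], 0.18)

  expect_equal(cfg$calibration$gdm$total, 15593)
  expect_equal(cfg$calibration$overweight$total, 18290)

  # every probability references a costed item, in [0, 1]
  for (arm in names(cfg$probabilities)) {
    p <- cfg$probabilities[[arm]]
    expect_true(all(p >= 0 & p <= 1))
    expect_true(all(names(p) %in% names(cfg$costs$entries)))
  }
  # Naylor shoulder-dystocia override ships flagged off
  expect_false(isTRUE(cfg$metadata$overrides$shoulder_dystocia$applied))
})

test_that("percent notation is normalized at load time", {
  expect_equal(parse_proportion("5.5%"), 0.055)
  expect_equal(parse_proportion("0.40%"), 0.004)
  expect_equal(parse_proportion(0.25), 0.25)
  expect_error(parse_proportion("150%"), "outside")
  expect_error(parse_proportion(-0.1), "outside")
})

test_that("schema violations are rejected with the offending field named", {
  cfg <- builtin_config()

  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  doc <- yaml::read_yaml(path)

  doc_bad <- doc
  doc_bad$typo_block <- list(a = 1)
  yaml::write_yaml(doc_bad, path)
  expect_error(load_config(path), "unknown top-level key.*typo_block")

  doc_bad <- doc
  doc_bad$probabilities$gdm_untreated$Unheard_of_event <- 0.1
  yaml::write_yaml(doc_bad, path)
  expect_error(load_config(path), "without a cost entry.*Unheard_of_event")

  doc_bad <- doc
  doc_bad$probabilities$gdm_untreated$Child_NICU <- 1.5
  yaml::write_yaml(doc_bad, path)
  expect_error(load_config(path), "outside \\[0, 1\\]")

  doc_bad <- doc
  doc_bad$odds_ratios[[1]]$ci_low <- 0.5  # above the 0.38 point estimate
  yaml::write_yaml(doc_bad, path)
  expect_error(load_config(path), "outside CI")
})

test_that("configurations round-trip through write_config", {
  cfg <- builtin_config()
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_config(cfg, path)
    back <- load_config(path)
    expect_equal(back$probabilities, cfg$probabilities)
    expect_equal(back$costs, cfg$costs)
    expect_equal(back$odds_ratios, cfg$odds_ratios)
    expect_equal(back$strategies, cfg$strategies)
    expect_equal(back$population, cfg$population)
    expect_equal(back$calibration, cfg$calibration)
  }
})

test_that("odds-ratio conversion matches explicit odds arithmetic", {
  # identity at OR = 1
  for (b in seq(0.05, 0.95, by = 0.05)) {
    expect_equal(or_to_probability(b, 1), b)
  }
  # independent oracle: odds = b/(1-b), scaled, back-transformed
  expect_equal(or_to_probability(0.10, 2.66), odds_oracle(0.10, 2.66))
  expect_equal(or_to_probability(0.10, 2.66), 0.2281305, tolerance = 1e-6)
  # untreated macrosomia 14.3% under treatment OR 0.38 -> ~5.9% treated risk
  expect_equal(or_to_probability(0.143, 0.38), odds_oracle(0.143, 0.38))
  expect_equal(or_to_probability(0.143, 0.38), 0.0596, tolerance = 1e-3)

  # strictly increasing in OR on a 100-point grid
  ors <- seq(0.05, 5, length.out = 100)
  p <- or_to_probability(0.25, ors)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))

  expect_error(or_to_probability(0, 2), "strictly inside")
  expect_error(or_to_probability(1, 2), "strictly inside")
  expect_error(or_to_probability(0.5, -1), "positive")
})
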