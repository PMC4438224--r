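breakdowns_fixture <- function(cfg) {
  list(condition = per_case_cost(build_arm("gdm", cfg)),
       reference = per_case_cost(build_arm("normal", cfg)))
}

test_that("scenario semantics match the one-way variation rules", {
  cfg <- builtin_config()
  bd <- breakdowns_fixture(cfg)
  base <- apply_scenario(cfg, bd, sensitivity_scenario("incidence", 0))
  expect_equal(base$per_case, 7803)

  # incidence variation leaves the per-case cost untouched, scales the BIA
  lo <- apply_scenario(cfg, bd, sensitivity_scenario("incidence", -0.2))
  hi <- apply_scenario(cfg, bd, sensitivity_scenario("incidence", 0.2))
  expect_equal(lo$per_case, 7803)
  expect_equal(hi$per_case, 7803)
  expect_equal(lo$bia, 0.8 * base$bia)
  expect_equal(hi$bia, 1.2 * base$bia)

  # condition-cost variation scales the condition arm's total only
  cc <- apply_scenario(cfg, bd,
                       sensitivity_scenario("condition_total_cost", -0.2))
  expect_equal(cc$per_case, 0.8 * 15593 - 7790)  # 4684.4
  expect_equal(round_half_away(cc$per_case), 4684)

  # reference-cost variation touches the normal arm only
  np <- apply_scenario(cfg, bd,
                       sensitivity_scenario("normal_pregnancy_cost", 0.2))
  expect_equal(np$per_case, 15593 - 1.2 * 7790)

  # component variations scale one side of the condition arm
  ch <- apply_scenario(cfg, bd,
                       sensitivity_scenario("child_complication_cost", -0.2))
  expect_equal(ch$per_case, 11794 + 0.8 * 3799 - 7790)
  mo <- apply_scenario(cfg, bd,
                       sensitivity_scenario("mother_complication_cost", -0.2))
  expect_equal(mo$per_case, 0.8 * 11794 + 3799 - 7790)

  # zero delta reproduces the base for every parameter
  for (p in c("incidence", "condition_total_cost", "normal_pregnancy_cost",
              "child_complication_cost", "mother_complication_cost")) {
    sc <- apply_scenario(cfg, bd, sensitivity_scenario(p, 0))
    expect_equal(sc$per_case, base$per_case)
    expect_equal(sc$bia, base$bia)
  }

  expect_error(sensitivity_scenario("discount_rate", 0.2),
               "unknown sensitivity parameter")
})

test_that("the full table carries one row per parameter-delta pair", {
  cfg <- builtin_config()
  tab <- run_table(cfg, deltas = c(-0.2, 0.2))
  expect_equal(nrow(tab$rows), 10L)
  expect_equal(tab$base$per_case, 7803)

  flat <- run_table(cfg, deltas = 0)
  expect_true(all(flat$rows$per_case == flat$base$per_case))
  expect_true(all(flat$rows$bia == flat$base$bia))

  # per-case response to the condition total is linear and symmetric
  cc <- tab$rows[tab$rows$parameter == "condition_total_cost", ]
  expect_equal(cc$per_case[cc$delta == 0.2] - cc$per_case[cc$delta == -0.2],
               0.4 * 15593)
  expect_equal(cc$per_case[cc$delta == 0.2] - tab$base$per_case,
               tab$base$per_case - cc$per_case[cc$delta == -0.2])
})

test_that("budget impact brackets the base case for every parameter", {
  cfg <- builtin_config()
  tab <- run_table(cfg, deltas = c(-0.2, 0.2))
  for (p in unique(tab$rows$parameter)) {
    lo <- tab$rows$bia[tab$rows$parameter == p & tab$rows$delta == -0.2]
    hi <- tab$rows$bia[tab$rows$parameter == p & tab$rows$delta == 0.2]
    if (p == "normal_pregnancy_cost") {
      # raising the comparator cost shrinks the incremental burden
      expect_true(hi <= tab$base$bia && tab$base$bia <= lo)
    } else {
      expect_true(lo <= tab$base$bia && tab$base$bia <= hi)
    }
  }
})

test_that("tornado ranking orders parameters by budget-impact spread", {
  cfg <- builtin_config()
  tab <- run_table(cfg, deltas = c(-0.2, 0.2))
  ranked <- tornado_order(tab)
  expect_true(all(diff(ranked$range) <= 0))
  # the condition arm's total dominates incidence: 0.4 * C_total * N versus
  # 0.4 * (C_total - C_normal) * N
  expect_lt(match("condition_total_cost", ranked$parameter),
            match("incidence", ranked$parameter))

  expect_error(tornado_order(run_table(cfg, deltas = c(-0.1, 0.2))),
               "symmetric")

  # degenerate all-zero-cost configuration: every range is 0 and order
  # falls back to alphabetical
  flat <- tab
  flat$rows$bia <- 0
  ranked0 <- tornado_order(flat)
  expect_equal(ranked0$parameter, sort(ranked0$parameter))
  expect_true(all(ranked0$range == 0))
})

test_that("scenarios cannot push the incidence above one", {
  cfg <- builtin_config()
  cfg$population$condition_incidence <- 0.9
  bd <- breakdowns_fixture(cfg)
  expect_error(apply_scenario(cfg, bd, sensitivity_scenario("incidence", 0.2)),
               "> 1")
})
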