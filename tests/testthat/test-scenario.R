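test_that("override application is a pure, local edit", {
  params <- p2i_v2_params()
  expect_identical(apply_overrides(params, NULL), params)
  expect_identical(apply_overrides(params, params[0, 0]), params)

  modified <- apply_overrides(params, evi_overrides())
  row <- modified$archetype == "unprecedented" & modified$phase == "phase1"
  expect_equal(modified$prob_success[row], 0.70)
  expect_equal(modified$length[row], 1.45)
  expect_equal(modified$cost[row], 2.5)  # untouched field survives
  expect_identical(modified[!row, ], params[!row, ])
  # the input table is not mutated
  expect_equal(params$prob_success[params$archetype == "unprecedented" &
                                     params$phase == "phase1"], 0.50)
  # idempotent: applying the same override set twice changes nothing more
  expect_identical(apply_overrides(modified, evi_overrides()), modified)
})

test_that("out-of-domain or dangling overrides are rejected", {
  params <- p2i_v2_params()
  expect_error(parameter_override("simple", "phase1", "prob_success", 1.3),
               "\\[0, 1\\]")
  expect_error(parameter_override("simple", "phase1", "length", 0), "> 0")
  expect_error(parameter_override("simple", "phase1", "cost", -2), ">= 0")
  expect_error(
    apply_overrides(params,
                    tibble::tibble(archetype = "mrna", phase = "phase1",
                                   field = "cost", value = 1)),
    "unknown archetype"
  )
})

test_that("the modified-assumption run reproduces the published comparison", {
  baseline <- aggregate_portfolio(evi_portfolio())
  scenario <- aggregate_portfolio(evi_portfolio(overrides = evi_overrides()))
  cmp <- compare_scenarios(baseline, scenario)

  # malaria: 3 x phase II + 3 x phase I + 2 x preclinical, unprecedented
  expect_equal(cmp$launches_baseline[cmp$disease == "malaria"],
               3 * (0.05 * 0.40) + 3 * (0.50 * 0.05 * 0.40) +
                 2 * (0.41 * 0.50 * 0.05 * 0.40))
  expect_equal(cmp$launches_scenario[cmp$disease == "malaria"],
               3 * (0.05 * 0.40) + 3 * (0.70 * 0.05 * 0.40) +
                 2 * (0.41 * 0.70 * 0.05 * 0.40))
  expect_equal(round(cmp$launches_scenario[cmp$disease == "malaria"], 2), 0.11)

  # archetypes untouched by the overrides are bit-identical across runs
  for (d in c("Nipah", "Zika", "shigellosis, ETEC")) {
    expect_identical(cmp$cost_baseline[cmp$disease == d],
                     cmp$cost_scenario[cmp$disease == d])
    expect_identical(cmp$launches_baseline[cmp$disease == d],
                     cmp$launches_scenario[cmp$disease == d])
  }
  un_b <- baseline$candidates[baseline$candidates$archetype != "unprecedented", ]
  un_s <- scenario$candidates[scenario$candidates$archetype != "unprecedented", ]
  expect_identical(un_b, un_s)

  # raising a success probability weakly raises downstream costs and launches
  expect_true(cmp$cost_delta[cmp$disease == "Total"] > 0)
  expect_true(all(cmp$launches_delta >= 0))
  expect_equal(cmp$cost_scenario[cmp$disease == "Total"], 516.57,
               tolerance = 0.005)
})

test_that("scenario comparison is reflexive and guards the disease set", {
  res <- aggregate_portfolio(evi_portfolio())
  cmp <- compare_scenarios(res, res)
  expect_true(all(cmp$cost_delta == 0))
  expect_true(all(cmp$launches_delta == 0))
  other <- aggregate_portfolio(generate_portfolio(4, seed = 99))
  expect_error(compare_scenarios(res, other), "different disease sets")
})
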