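test_that("remaining_phases enumerates the pipeline tail", {
  expect_identical(remaining_phases("phase3"), "phase3")
  expect_identical(remaining_phases("preclinical"),
                   c("preclinical", "phase1", "phase2", "phase3"))
  expect_identical(remaining_phases("phase1"), c("phase1", "phase2", "phase3"))
  expect_error(remaining_phases("phase4"), "unknown development phase")
})

test_that("launch probability is the product over remaining phases", {
  params <- p2i_v2_params()
  expect_equal(launch_probability(params, "simple", "phase1"),
               0.68 * 0.46 * 0.71)
  expect_equal(launch_probability(params, "unprecedented", "preclinical"),
               0.41 * 0.50 * 0.05 * 0.40)
  # certainty at every phase propagates to a certain launch
  expect_equal(launch_probability(flat_params(prob = 1), "flat", "preclinical"), 1)
  expect_error(launch_probability(params, "no-such-archetype", "phase1"),
               "not present")
})

test_that("entry probability is the product over phases before the query", {
  params <- p2i_v2_params()
  for (ph in p2i_phases()) {
    expect_equal(entry_probability(params, "complex", ph, ph), 1)
  }
  expect_equal(entry_probability(params, "unprecedented", "phase1", "phase3"),
               0.50 * 0.05)
  expect_equal(entry_probability(params, "simple", "phase1", "phase3"),
               0.68 * 0.46)
  expect_error(entry_probability(params, "simple", "phase2", "phase1"),
               "precedes entry phase")
})

test_that("risk-adjusted phase costs weight each phase by its entry probability", {
  params <- p2i_v2_params()
  rc <- risk_adjusted_phase_costs(params, "unprecedented", "phase2")
  expect_equal(rc, c(phase2 = 13.9, phase3 = 0.05 * 223))
  expect_equal(sum(rc), 25.05)
  rc <- risk_adjusted_phase_costs(params, "simple", "phase1")
  expect_equal(rc, c(phase1 = 2.2, phase2 = 0.68 * 13.2,
                     phase3 = 0.68 * 0.46 * 201.0))
  expect_equal(sum(rc), 74.0488)
  # linearity: zero costs give zero everywhere
  expect_equal(unname(risk_adjusted_phase_costs(flat_params(cost = 0), "flat",
                                                "preclinical")),
               rep(0, 4))
})

test_that("phase timeline is contiguous from time zero with published lengths", {
  params <- p2i_v2_params()
  tl <- phase_timeline(params, "simple", "phase1")
  expect_equal(tl$start, c(0, 1.6, 3.8))
  expect_equal(tl$end, c(1.6, 3.8, 6.1))
  tl <- phase_timeline(params, "unprecedented", "preclinical")
  expect_equal(tl$end, c(3.3, 5.3, 9.0, 12.5))
  tl <- phase_timeline(flat_params(length = 2.3), "flat", "phase3")
  expect_equal(nrow(tl), 1L)
  expect_equal(c(tl$start, tl$end), c(0, 2.3))
})

test_that("annual accrual prorates risk-adjusted phase costs by interval overlap", {
  params <- p2i_v2_params()
  acc <- annual_cost_accrual(params, "simple", "phase1", 2019, 2031)
  # year 2: 0.6 y left of phase 1 at 2.2/1.6 per year, then 0.4 y of
  # risk-adjusted phase 2 at 0.68 * 13.2/2.2 per year
  expect_equal(acc$cost[2], (2.2 / 1.6) * 0.6 + (13.2 / 2.2) * 0.68 * 0.4)
  expect_equal(acc$cost[2], 2.457)
  # a single phase spanning exactly year 1 accrues its full cost there
  acc1 <- annual_cost_accrual(flat_params(cost = 7.5, length = 1), "flat",
                              "phase3", 2019, 2019)
  expect_equal(acc1$cost, 7.5)
  # truncation: a horizon shorter than the phase keeps rate x horizon only
  acc2 <- annual_cost_accrual(flat_params(cost = 10, length = 4), "flat",
                              "phase3", 2019, 2020)
  expect_equal(sum(acc2$cost), (10 / 4) * 2)
})

test_that("annual accrual agrees with a Riemann-sum oracle", {
  params <- p2i_v2_params()
  cases <- expand.grid(archetype = c("simple", "complex", "unprecedented"),
                       entry = c("preclinical", "phase1", "phase2"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    tr <- candidate_trajectory(params, cases$archetype[i], cases$entry[i])
    got <- annual_cost_accrual(params, cases$archetype[i], cases$entry[i],
                               2019, 2031)$cost
    expect_equal(got, riemann_accrual(tr, 2019, 2031), tolerance = 1e-3)
  }
})

test_that("launch dating uses the year containing the end of phase III", {
  params <- p2i_v2_params()
  ls <- launch_schedule(params, "simple", "phase1", 2019)
  expect_equal(ls$launch_time, 6.1)
  expect_equal(ls$launch_year, 2025L)
  ls <- launch_schedule(params, "unprecedented", "phase2", 2019)
  expect_equal(ls$launch_time, 7.2)
  expect_equal(ls$launch_year, 2026L)
  # an end instant exactly on a year boundary belongs to the earlier year
  ls <- launch_schedule(flat_params(length = 1), "flat", "phase1", 2019)
  expect_equal(ls$launch_time, 3)
  expect_equal(ls$launch_year, 2021L)
  # all-zero lengths launch immediately, in the start year
  ls <- launch_schedule(flat_params(length = 0), "flat", "preclinical", 2019)
  expect_equal(ls$launch_year, 2019L)
  # beyond the horizon there is no launch, but the probability is kept
  ls <- launch_schedule(params, "unprecedented", "preclinical", 2019,
                        end_year = 2025)
  expect_true(is.na(ls$launch_year))
  expect_equal(ls$launch_probability, 0.41 * 0.50 * 0.05 * 0.40)
})

test_that("a zero-length phase accrues as a point mass in its containing year", {
  params <- flat_params(cost = 8, length = 1, prob = 0.5)
  params$length[params$phase == "phase2"] <- 0
  # phases: pc [0,1), p1 [1,2), p2 point at t = 2 (earlier year), p3 [2,3)
  acc <- annual_cost_accrual(params, "flat", "preclinical", 2019, 2031)
  expect_equal(acc$cost[2], 0.5 * 8 + 0.25 * 8)  # phase1 rate + phase2 mass
  expect_equal(sum(acc$cost), sum(risk_adjusted_phase_costs(params, "flat",
                                                            "preclinical")))
})

test_that("aggregate of a singleton portfolio equals the candidate's values", {
  pf <- one_candidate_portfolio(p2i_v2_params(), "simple", "phase1")
  res <- aggregate_portfolio(pf)
  expect_equal(res$total_launches, 0.68 * 0.46 * 0.71)
  expect_equal(res$total_cost, sum(annual_cost_accrual(
    pf$params, "simple", "phase1", 2019, 2031)$cost))
  expect_equal(res$by_disease$cost, res$total_cost)
  expect_equal(res$annual$launch_cumulative[13], res$total_launches)
})

test_that("accrual sums equal closed-form risk-adjusted costs on a full horizon", {
  params <- p2i_v2_params()
  for (a in unique(params$archetype)) {
    for (ph in p2i_phases()) {
      closed <- sum(risk_adjusted_phase_costs(params, a, ph))
      accrued <- sum(annual_cost_accrual(params, a, ph, 2019, 2060)$cost)
      expect_equal(accrued, closed, tolerance = 1e-9)
    }
  }
})

test_that("cost scaling scales cost outputs exactly and leaves launches alone", {
  for (k in c(0.25, 3)) {
    base <- evi_portfolio()
    scaled <- base
    scaled$params$cost <- scaled$params$cost * k
    r0 <- aggregate_portfolio(base)
    r1 <- aggregate_portfolio(scaled)
    expect_equal(r1$total_cost, k * r0$total_cost)
    expect_equal(r1$annual$cost, k * r0$annual$cost)
    expect_identical(r1$candidates$launch_probability,
                     r0$candidates$launch_probability)
    expect_identical(r1$annual$launch_cumulative, r0$annual$launch_cumulative)
  }
})

test_that("cumulative series are non-decreasing and disease sums are exact", {
  for (seed in 1:5) {
    pf <- generate_portfolio(12, seed = seed, jitter_params = (seed %% 2 == 0))
    res <- aggregate_portfolio(pf)
    expect_true(all(diff(res$annual$cost_cumulative) >= -1e-12))
    expect_true(all(diff(res$annual$launch_cumulative) >= -1e-12))
    expect_true(all(res$candidates$launch_probability >= 0 &
                      res$candidates$launch_probability <= 1))
    expect_equal(sum(res$by_disease$cost), res$total_cost)
    expect_equal(sum(res$by_disease$launches), res$total_launches)
  }
})

test_that("scaling all success probabilities scales launch prob by m^k", {
  params <- p2i_v2_params()
  for (m in c(0.9, 1.1)) {
    perturbed <- perturb_params(params, prob_multiplier = m)
    for (a in unique(params$archetype)) {
      for (ph in p2i_phases()) {
        k <- length(remaining_phases(ph))
        expect_equal(launch_probability(perturbed, a, ph),
                     launch_probability(params, a, ph) * m^k)
      }
    }
  }
})
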