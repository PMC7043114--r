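# Independent oracles used across test files. Kept deliberately naive and
# separate from the implementation they check.

# Midpoint Riemann sum of the piecewise-constant accrual rate implied by a
# trajectory table; an independent check on the interval-overlap arithmetic
# of annual_cost_accrual().
riemann_accrual <- function(trajectory, start_year, end_year, dt = 1e-4) {
  horizon <- end_year - start_year + 1
  t_mid <- seq(dt / 2, horizon, by = dt)
  rate <- numeric(length(t_mid))
  for (i in seq_len(nrow(trajectory))) {
    if (trajectory$length[i] > 0) {
      inside <- t_mid >= trajectory$start[i] & t_mid < trajectory$end[i]
      rate[inside] <- rate[inside] + trajectory$risk_cost[i] / trajectory$length[i]
    }
  }
  # midpoints never sit exactly on a year boundary, so floor() bins cleanly
  as.numeric(tapply(rate * dt, floor(t_mid), sum))
}

# A degenerate parameter table where every number is easy to reason about.
flat_params <- function(cost = 1, length = 1, prob = 0.5,
                        archetype = "flat") {
  tibble::tibble(
    archetype = archetype,
    phase = p2i_phases(),
    cost = rep(cost, 4),
    length = rep(length, 4),
    prob_success = rep(prob, 4)
  )
}

# Single-candidate portfolio over the given horizon.
one_candidate_portfolio <- function(params, archetype, entry_phase,
                                    start_year = 2019, end_year = 2031,
                                    disease = "test disease") {
  p2i_portfolio(
    tibble::tibble(candidate_id = "c1", disease = disease,
                   archetype = archetype, entry_phase = entry_phase),
    params, start_year, end_year
  )
}
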