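# One-way and two-way sensitivity analysis under multiplicative perturbation
# of all success probabilities and/or all phase costs. "10% higher" means
# multiplication by 1.1 (not +10 percentage points): a candidate with k
# remaining phases then has its launch probability scaled by 1.1^k, which is
# what reproduces the published portfolio-level sensitivity figures.

#' Perturb a parameter table multiplicatively
#'
#' Every phase's probability of success is multiplied by `prob_multiplier`
#' (clamped at 1), every phase's cost by `cost_multiplier`; durations are
#' never perturbed.
#'
#' @param params Archetype parameter table.
#' @param prob_multiplier,cost_multiplier Positive multipliers.
#' @return The perturbed, validated parameter table.
#' @export
#' @examples
#' perturb_params(p2i_v2_params(), prob_multiplier = 1.1)
perturb_params <- function(params, prob_multiplier = 1, cost_multiplier = 1) {
  if (!is.finite(prob_multiplier) || prob_multiplier <= 0 ||
      !is.finite(cost_multiplier) || cost_multiplier <= 0) {
    stop("perturbation multipliers must be positive and finite", call. = FALSE)
  }
  params <- validate_params(params)
  params$prob_success <- pmin(1, params$prob_success * prob_multiplier)
  params$cost <- params$cost * cost_multiplier
  validate_params(params)
}

#' Sensitivity table over multiplier combinations
#'
#' Re-runs the model with all probabilities of success and/or all costs
#' perturbed: one-way rows for each multiplier applied to probabilities only
#' and to costs only, then every two-way combination. Deltas are percent
#' changes relative to the unperturbed run; the baseline row (both
#' multipliers 1) reproduces it exactly.
#'
#' @param portfolio A [p2i_portfolio()] object.
#' @param multipliers Numeric vector of multipliers to try (default
#'   `c(0.9, 1.1)`, i.e. 10% lower and higher).
#' @return Tibble with columns `scenario`, `prob_multiplier`,
#'   `cost_multiplier`, `total_cost`, `cost_delta_pct`, `total_launches`,
#'   `launches_delta_pct`.
#' @export
#' @examples
#' sensitivity_table(evi_portfolio())
sensitivity_table <- function(portfolio, multipliers = c(0.9, 1.1)) {
  stopifnot(inherits(portfolio, "p2i_portfolio"))
  if (any(!is.finite(multipliers)) || any(multipliers <= 0)) {
    stop("multipliers must be positive and finite", call. = FALSE)
  }
  multipliers <- sort(unique(multipliers))

  k <- length(multipliers)
  grid <- rbind(
    data.frame(scenario = "baseline", m_prob = 1, m_cost = 1),
    data.frame(scenario = sprintf("probability x%g", multipliers),
               m_prob = multipliers, m_cost = rep(1, k)),
    data.frame(scenario = sprintf("cost x%g", multipliers),
               m_prob = rep(1, k), m_cost = multipliers),
    do.call(rbind, lapply(multipliers, function(ms) {
      data.frame(scenario = sprintf("probability x%g, cost x%g", ms, multipliers),
                 m_prob = rep(ms, k), m_cost = multipliers)
    }))
  )

  run_one <- function(m_prob, m_cost) {
    p <- portfolio
    p$params <- perturb_params(p$params, m_prob, m_cost)
    res <- aggregate_portfolio(p)
    c(cost = res$total_cost, launches = res$total_launches)
  }
  runs <- t(mapply(run_one, grid$m_prob, grid$m_cost))
  base <- runs[1, ]

  tibble::tibble(
    scenario = grid$scenario,
    prob_multiplier = grid$m_prob,
    cost_multiplier = grid$m_cost,
    total_cost = runs[, "cost"],
    cost_delta_pct = 100 * (runs[, "cost"] / base["cost"] - 1),
    total_launches = runs[, "launches"],
    launches_delta_pct = 100 * (runs[, "launches"] / base["launches"] - 1)
  )
}
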