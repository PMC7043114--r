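#' Run the model over a portfolio
#'
#' Computes every candidate's trajectory, accrues costs by calendar year,
#' dates launches, and aggregates to per-disease and portfolio totals.
#' Expected launches are sums of per-candidate launch probabilities (a value
#' of 1 corresponds to one certain launch).
#'
#' @param portfolio A [p2i_portfolio()] object.
#' @return An object of class `p2i_result`: a list with
#'   \describe{
#'     \item{candidates}{per-candidate tibble: launch time/year/probability
#'       and risk-adjusted cost accrued within the horizon,}
#'     \item{by_disease}{per-disease expected cost (US$ millions, within
#'       horizon) and expected launches,}
#'     \item{annual}{per-year accrued and cumulative cost and cumulative
#'       launch probability,}
#'     \item{total_cost}{portfolio cost within the horizon,}
#'     \item{total_launches}{sum of launch probabilities over candidates.}
#'   }
#' @export
#' @examples
#' res <- aggregate_portfolio(evi_portfolio())
#' res$total_launches
aggregate_portfolio <- function(portfolio) {
  stopifnot(inherits(portfolio, "p2i_portfolio"))
  cand <- portfolio$candidates
  params <- portfolio$params
  y0 <- portfolio$start_year
  y1 <- portfolio$end_year
  years <- seq.int(y0, y1)

  n <- nrow(cand)
  cost_by_year <- matrix(0, nrow = length(years), ncol = max(n, 1L))
  launch_year <- integer(n)
  launch_time <- numeric(n)
  launch_prob <- numeric(n)
  for (i in seq_len(n)) {
    acc <- annual_cost_accrual(params, cand$archetype[i], cand$entry_phase[i],
                               y0, y1)
    cost_by_year[, i] <- acc$cost
    ls <- launch_schedule(params, cand$archetype[i], cand$entry_phase[i],
                          y0, y1)
    launch_year[i] <- ls$launch_year
    launch_time[i] <- ls$launch_time
    launch_prob[i] <- ls$launch_probability
  }

  candidates <- tibble::tibble(
    candidate_id = cand$candidate_id,
    disease = cand$disease,
    archetype = cand$archetype,
    entry_phase = cand$entry_phase,
    cost = if (n > 0) colSums(cost_by_year) else numeric(0),
    launch_time = launch_time,
    launch_year = launch_year,
    launch_probability = launch_prob
  )

  by_disease <- dplyr::summarise(
    dplyr::group_by(candidates, disease),
    cost = sum(cost), launches = sum(launch_probability), .groups = "drop"
  )
  # keep first-appearance order of diseases, as in the input table
  by_disease <- by_disease[match(unique(cand$disease), by_disease$disease), ]

  launch_added <- vapply(
    years,
    function(y) sum(launch_prob[!is.na(launch_year) & launch_year == y]),
    numeric(1)
  )
  annual <- tibble::tibble(
    year = years,
    cost = if (n > 0) rowSums(cost_by_year) else numeric(length(years)),
    cost_cumulative = cumsum(if (n > 0) rowSums(cost_by_year) else numeric(length(years))),
    launch_probability = launch_added,
    launch_cumulative = cumsum(launch_added)
  )

  structure(
    list(
      candidates = candidates,
      by_disease = by_disease,
      annual = annual,
      total_cost = sum(candidates$cost),
      total_launches = sum(candidates$launch_probability),
      start_year = y0,
      end_year = y1
    ),
    class = "p2i_result"
  )
}

#' @export
print.p2i_result <- function(x, ...) {
  cat("Portfolio model result (", x$start_year, "-", x$end_year, ")\n", sep = "")
  cat("  total cost within horizon: ", format(round(x$total_cost, 2)),
      " US$ millions\n", sep = "")
  cat("  expected launches:         ", format(round(x$total_launches, 2)),
      "\n", sep = "")
  cat("  by disease:\n")
  bd <- x$by_disease
  for (i in seq_len(nrow(bd))) {
    cat(sprintf("    %-20s %9.2f  %s\n", bd$disease[i], bd$cost[i],
                format(round_launches(bd$launches[i]))))
  }
  invisible(x)
}

# View-layer rounding: costs to 2 decimals; launch probabilities to 2
# decimals, or 3 below 0.1 where 2 would destroy the leading digit.
# Never feeds back into computation.
round_launches <- function(x) {
  round(x, ifelse(abs(x) < 0.1, 3, 2))
}
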