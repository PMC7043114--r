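# Per-candidate mechanics of the deterministic pipeline model.
#
# A candidate entering phase e traverses phases e..phase3 back to back in
# continuous time, starting at time 0 = Jan 1 of the portfolio start year.
# The probability of *reaching* phase p is the product of the success
# probabilities of the phases strictly before p (counted from e); a phase's
# risk-adjusted cost is that entry probability times the phase cost, and it
# accrues uniformly over the phase duration. "Launch" means completing phase
# III; its probability is the product over all remaining phases.

#' Probability that a candidate launches
#'
#' The launch probability is the product of the per-phase probabilities of
#' success over every phase the candidate still has to traverse, from its
#' entry phase through phase III.
#'
#' @param params Archetype parameter table (see [validate_params()]).
#' @param archetype Archetype label of the candidate.
#' @param entry_phase Phase the candidate currently occupies.
#' @return A single probability in \[0, 1\].
#' @export
#' @examples
#' # a simple vaccine entering phase I: 0.68 * 0.46 * 0.71
#' launch_probability(p2i_v2_params(), "simple", "phase1")
launch_probability <- function(params, archetype, entry_phase) {
  slice <- archetype_slice(validate_params(params), archetype)
  keep <- slice$phase %in% remaining_phases(entry_phase)
  prod(slice$prob_success[keep])
}

#' Probability of reaching a given phase
#'
#' The probability that a candidate entering at `entry_phase` survives to the
#' start of `phase`: the product of success probabilities of the phases in
#' \[entry_phase, phase). The empty product (querying the entry phase itself)
#' is 1. This is the risk-adjustment weight applied to the phase's cost.
#'
#' @inheritParams launch_probability
#' @param phase Queried phase; must not precede `entry_phase`.
#' @return A single probability in \[0, 1\].
#' @export
entry_probability <- function(params, archetype, entry_phase, phase) {
  ie <- phase_index(entry_phase)
  ip <- phase_index(phase)
  if (ip < ie) {
    stop("phase '", phase, "' precedes entry phase '", entry_phase, "'",
         call. = FALSE)
  }
  slice <- archetype_slice(validate_params(params), archetype)
  idx <- phase_index(slice$phase)
  prod(slice$prob_success[idx >= ie & idx < ip])
}

#' Full per-phase trajectory of one candidate
#'
#' Derives, for each remaining phase: its half-open time interval
#' \[start, end) in years since the portfolio start, the probability of
#' reaching it, its nominal and risk-adjusted cost, and the uniform accrual
#' rate. Intervals are contiguous, beginning at time 0.
#'
#' @inheritParams launch_probability
#' @return A tibble with one row per remaining phase (pipeline order) and
#'   columns `phase`, `start`, `end`, `length`, `cost`, `prob_success`,
#'   `entry_prob`, `risk_cost`.
#' @export
#' @examples
#' candidate_trajectory(p2i_v2_params(), "unprecedented", "phase2")
candidate_trajectory <- function(params, archetype, entry_phase) {
  slice <- archetype_slice(validate_params(params), archetype)
  keep <- slice$phase %in% remaining_phases(entry_phase)
  slice <- slice[keep, , drop = FALSE]
  ends <- cumsum(slice$length)
  entry_prob <- cumprod(c(1, slice$prob_success[-nrow(slice)]))
  tibble::tibble(
    phase = slice$phase,
    start = c(0, ends[-length(ends)]),
    end = ends,
    length = slice$length,
    cost = slice$cost,
    prob_success = slice$prob_success,
    entry_prob = entry_prob,
    risk_cost = entry_prob * slice$cost
  )
}

#' Risk-adjusted cost of each remaining phase
#'
#' Each remaining phase's cost weighted by the probability of reaching it.
#' Summed over phases this is the candidate's expected (risk-adjusted)
#' development cost, ignoring any horizon truncation.
#'
#' @inheritParams launch_probability
#' @return Named numeric vector, one element per remaining phase.
#' @export
risk_adjusted_phase_costs <- function(params, archetype, entry_phase) {
  tr <- candidate_trajectory(params, archetype, entry_phase)
  stats::setNames(tr$risk_cost, tr$phase)
}

#' Phase timeline of one candidate
#'
#' @inheritParams launch_probability
#' @return Tibble with columns `phase`, `start`, `end` (years since the
#'   portfolio start; half-open intervals) plus attribute-free access to the
#'   launch time as the final `end`.
#' @export
phase_timeline <- function(params, archetype, entry_phase) {
  candidate_trajectory(params, archetype, entry_phase)[c("phase", "start", "end")]
}

# Calendar-year index (0 = start_year) containing the instant t, under the
# half-open convention: an instant landing exactly on a year boundary belongs
# to the earlier year. t is snapped to 1e-9 to absorb float noise in summed
# phase lengths.
year_index_of_instant <- function(t) {
  t <- round(t, 9)
  ifelse(t <= 0, 0L, as.integer(ceiling(t) - 1))
}

#' Calendar-year cost accrual for one candidate
#'
#' Within each phase, the risk-adjusted phase cost accrues at the uniform
#' rate `entry_prob * cost / length` per year; a calendar year's accrual is
#' the accrual-rate-weighted overlap of the year with each phase interval.
#' A zero-length phase contributes its full risk-adjusted cost as a point
#' mass in the year containing its start instant (the limit of uniform
#' accrual). Accrual beyond December 31 of `end_year` is discarded.
#'
#' @inheritParams launch_probability
#' @param start_year,end_year Calendar horizon.
#' @return Tibble with columns `year` and `cost` (US$ millions), one row per
#'   horizon year.
#' @export
#' @examples
#' annual_cost_accrual(p2i_v2_params(), "simple", "phase1", 2019, 2031)
annual_cost_accrual <- function(params, archetype, entry_phase,
                                start_year, end_year) {
  stopifnot(start_year <= end_year)
  tr <- candidate_trajectory(params, archetype, entry_phase)
  years <- seq.int(start_year, end_year)
  n <- length(years)
  acc <- numeric(n)
  for (i in seq_len(nrow(tr))) {
    if (tr$length[i] > 0) {
      rate <- tr$risk_cost[i] / tr$length[i]
      lo <- pmax(tr$start[i], seq_len(n) - 1)
      hi <- pmin(tr$end[i], seq_len(n))
      acc <- acc + rate * pmax(0, hi - lo)
    } else if (tr$risk_cost[i] > 0) {
      k <- year_index_of_instant(tr$start[i])
      if (k < n) acc[k + 1L] <- acc[k + 1L] + tr$risk_cost[i]
    }
  }
  tibble::tibble(year = years, cost = acc)
}

#' Launch year and launch probability of one candidate
#'
#' The launch instant is the end of the phase III interval; it is dated to
#' the calendar year containing it, with an instant landing exactly on a
#' year boundary counted in the earlier year. A candidate whose launch falls
#' after December 31 of `end_year` contributes no launch within the horizon
#' (`launch_year` is `NA` but the probability is still reported).
#'
#' @inheritParams annual_cost_accrual
#' @param end_year Optional horizon end; when `NULL` the launch year is
#'   reported unconditionally.
#' @return List with elements `launch_time` (years since start),
#'   `launch_year` (calendar year or `NA`) and `launch_probability`.
#' @export
launch_schedule <- function(params, archetype, entry_phase,
                            start_year, end_year = NULL) {
  tr <- candidate_trajectory(params, archetype, entry_phase)
  launch_time <- tr$end[nrow(tr)]
  yr <- start_year + year_index_of_instant(launch_time)
  if (!is.null(end_year) && yr > end_year) yr <- NA_integer_
  list(
    launch_time = launch_time,
    launch_year = as.integer(yr),
    launch_probability = prod(tr$prob_success)
  )
}
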