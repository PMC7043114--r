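# Scenario machinery: targeted overrides of single parameter cells, and
# side-by-side comparison of two model runs over the same disease set.

#' Construct a parameter override
#'
#' @param archetype Archetype whose parameters are modified.
#' @param phase Phase whose cell is modified.
#' @param field One of `"cost"`, `"length"`, `"prob_success"`.
#' @param value New value, in the field's units (US$ millions, years, or a
#'   fraction in \[0, 1\]).
#' @return One-row tibble suitable for [apply_overrides()].
#' @export
#' @examples
#' parameter_override("unprecedented", "phase1", "prob_success", 0.70)
parameter_override <- function(archetype, phase, field, value) {
  field <- match.arg(field, c("cost", "length", "prob_success"))
  phase_index(phase)
  value <- as.numeric(value)
  if (!is.finite(value)) stop("override value must be finite", call. = FALSE)
  if (field == "prob_success" && (value < 0 || value > 1)) {
    stop("prob_success override must lie in [0, 1], got ", value, call. = FALSE)
  }
  if (field == "length" && value <= 0) {
    stop("length override must be > 0, got ", value, call. = FALSE)
  }
  if (field == "cost" && value < 0) {
    stop("cost override must be >= 0, got ", value, call. = FALSE)
  }
  tibble::tibble(archetype = archetype, phase = phase, field = field,
                 value = value)
}

#' Apply parameter overrides
#'
#' Returns a modified copy of the parameter table; cells not targeted by any
#' override are value-identical to the input, and the input itself is never
#' mutated. Later overrides of the same cell win (so applying a fixed
#' override set twice is idempotent).
#'
#' @param params Archetype parameter table.
#' @param overrides Tibble of overrides, as produced by
#'   [parameter_override()] / `dplyr::bind_rows()`, or [evi_overrides()].
#' @return The modified, validated parameter table.
#' @export
#' @examples
#' apply_overrides(p2i_v2_params(), evi_overrides())
apply_overrides <- function(params, overrides) {
  params <- validate_params(params)
  if (is.null(overrides) || nrow(overrides) == 0L) {
    return(params)
  }
  overrides <- do.call(
    rbind,
    lapply(seq_len(nrow(overrides)), function(i) {
      parameter_override(overrides$archetype[i], overrides$phase[i],
                         overrides$field[i], overrides$value[i])
    })
  )
  for (i in seq_len(nrow(overrides))) {
    row <- which(params$archetype == overrides$archetype[i] &
                   params$phase == overrides$phase[i])
    if (length(row) != 1L) {
      stop("override targets unknown archetype/phase: ",
           overrides$archetype[i], " / ", overrides$phase[i], call. = FALSE)
    }
    params[[overrides$field[i]]][row] <- overrides$value[i]
  }
  validate_params(params)
}

#' Compare two model runs disease by disease
#'
#' @param baseline,scenario Two [aggregate_portfolio()] results over the same
#'   disease set.
#' @return Tibble with one row per disease plus a `"Total"` row: baseline and
#'   scenario cost and expected launches, and their deltas
#'   (scenario - baseline).
#' @export
#' @examples
#' base <- aggregate_portfolio(evi_portfolio())
#' evi <- aggregate_portfolio(evi_portfolio(overrides = evi_overrides()))
#' compare_scenarios(base, evi)
compare_scenarios <- function(baseline, scenario) {
  stopifnot(inherits(baseline, "p2i_result"), inherits(scenario, "p2i_result"))
  b <- baseline$by_disease
  s <- scenario$by_disease
  if (!setequal(b$disease, s$disease)) {
    stop("the two runs cover different disease sets", call. = FALSE)
  }
  s <- s[match(b$disease, s$disease), ]
  out <- tibble::tibble(
    disease = b$disease,
    cost_baseline = b$cost,
    launches_baseline = b$launches,
    cost_scenario = s$cost,
    launches_scenario = s$launches
  )
  out <- rbind(
    out,
    tibble::tibble(
      disease = "Total",
      cost_baseline = sum(b$cost),
      launches_baseline = sum(b$launches),
      cost_scenario = sum(s$cost),
      launches_scenario = sum(s$launches)
    )
  )
  out$cost_delta <- out$cost_scenario - out$cost_baseline
  out$launches_delta <- out$launches_scenario - out$launches_baseline
  out
}
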