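#' Validate an archetype parameter table
#'
#' An archetype parameter table holds, for each product archetype, the assumed
#' cost (US$ millions), duration (years) and probability of success (fraction)
#' of each of the four development phases. Probabilities are always stored as
#' fractions in \[0, 1\]; percent inputs are converted on read (see
#' [read_params()]).
#'
#' @param params A data frame with columns `archetype`, `phase`, `cost`,
#'   `length`, `prob_success`; one row per archetype x phase, all four phases
#'   present for every archetype.
#' @return The validated table as a tibble, rows ordered by archetype then
#'   phase order.
#' @export
validate_params <- function(params) {
  required <- c("archetype", "phase", "cost", "length", "prob_success")
  missing_cols <- setdiff(required, names(params))
  if (length(missing_cols) > 0) {
    stop("parameter table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  params <- tibble::as_tibble(params)[required]
  phase_index(params$phase)  # errors on unknown labels
  for (a in unique(params$archetype)) {
    have <- params$phase[params$archetype == a]
    if (length(have) != 4L || !setequal(have, p2i_phases()) || anyDuplicated(have)) {
      stop("archetype '", a, "' must have exactly one row per phase (",
           paste(p2i_phases(), collapse = ", "), ")", call. = FALSE)
    }
  }
  if (any(!is.finite(params$cost)) || any(params$cost < 0)) {
    stop("phase costs must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(params$length)) || any(params$length < 0)) {
    stop("phase lengths must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(params$prob_success)) ||
      any(params$prob_success < 0) || any(params$prob_success > 1)) {
    stop("probabilities of success must lie in [0, 1] ",
         "(store fractions, not percent)", call. = FALSE)
  }
  params[order(params$archetype, phase_index(params$phase)), ]
}

# Four-row slice for one archetype, ordered preclinical -> phase3.
archetype_slice <- function(params, archetype) {
  rows <- params[params$archetype == archetype, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("archetype '", archetype, "' not present in the parameter table",
         call. = FALSE)
  }
  rows[order(phase_index(rows$phase)), , drop = FALSE]
}

#' Validate a candidate table
#'
#' @param candidates Data frame with columns `candidate_id`, `disease`,
#'   `archetype`, `entry_phase`.
#' @param params Optional parameter table; when given, every candidate's
#'   archetype must be present in it.
#' @return The validated candidate tibble, row order preserved.
#' @export
validate_candidates <- function(candidates, params = NULL) {
  required <- c("candidate_id", "disease", "archetype", "entry_phase")
  missing_cols <- setdiff(required, names(candidates))
  if (length(missing_cols) > 0) {
    stop("candidate table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  candidates <- tibble::as_tibble(candidates)[required]
  if (anyDuplicated(candidates$candidate_id)) {
    dup <- unique(candidates$candidate_id[duplicated(candidates$candidate_id)])
    stop("duplicate candidate_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad <- which(!candidates$entry_phase %in% p2i_phases())
  if (length(bad) > 0) {
    stop("row ", bad[1], " ('", candidates$candidate_id[bad[1]],
         "'): unknown entry_phase '", candidates$entry_phase[bad[1]], "'",
         call. = FALSE)
  }
  if (!is.null(params)) {
    bad <- which(!candidates$archetype %in% unique(params$archetype))
    if (length(bad) > 0) {
      stop("row ", bad[1], " ('", candidates$candidate_id[bad[1]],
           "'): archetype '", candidates$archetype[bad[1]],
           "' has no parameter rows", call. = FALSE)
    }
  }
  candidates
}

#' Assemble a portfolio
#'
#' A portfolio bundles a candidate list, an archetype parameter table and the
#' calendar horizon over which costs accrue and launches are counted. Every
#' candidate is assumed to sit at the start of its current phase on January 1
#' of `start_year`; accrual past December 31 of `end_year` is discarded.
#'
#' @param candidates Candidate table (see [validate_candidates()]).
#' @param params Archetype parameter table (see [validate_params()]).
#' @param start_year,end_year Integer calendar years bounding the horizon.
#' @return An object of class `p2i_portfolio`.
#' @export
#' @examples
#' pf <- p2i_portfolio(evi_candidates(), p2i_v2_params(), 2019, 2031)
#' pf
p2i_portfolio <- function(candidates, params, start_year, end_year) {
  params <- validate_params(params)
  candidates <- validate_candidates(candidates, params)
  start_year <- as.integer(start_year)
  end_year <- as.integer(end_year)
  if (is.na(start_year) || is.na(end_year) || start_year > end_year) {
    stop("require start_year <= end_year", call. = FALSE)
  }
  structure(
    list(candidates = candidates, params = params,
         start_year = start_year, end_year = end_year),
    class = "p2i_portfolio"
  )
}

#' @export
print.p2i_portfolio <- function(x, ...) {
  cat("Portfolio-to-impact portfolio\n")
  cat("  candidates: ", nrow(x$candidates),
      " (", paste(sprintf("%s: %d", names(table(x$candidates$archetype)),
                          as.integer(table(x$candidates$archetype))),
                  collapse = ", "), ")\n", sep = "")
  cat("  diseases:   ", length(unique(x$candidates$disease)), "\n", sep = "")
  cat("  horizon:    ", x$start_year, "-", x$end_year, "\n", sep = "")
  invisible(x)
}
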