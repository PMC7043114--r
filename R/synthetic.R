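# Seeded generator of synthetic portfolios with the same statistical
# structure as the EVI portfolio (archetype mix 15:2:1, phase mix 3:11:4:0),
# so every pipeline stage is property-testable without external data.

#' Generate a synthetic portfolio
#'
#' Draws `n_candidates` candidates by independent weighted sampling of
#' archetype, entry phase and disease. Defaults reproduce the empirical
#' weights of the EVI portfolio: archetypes unprecedented:simple:complex =
#' 15:2:1 and phases preclinical:phase1:phase2:phase3 = 3:11:4:0. Candidate
#' ids are `"<disease> <k>"` with `k` counting within disease. The draw is
#' fully determined by `seed`; the caller's random-number state is left
#' untouched.
#'
#' With `jitter_params = TRUE` the parameter table itself is also perturbed,
#' cell-wise and uniformly within +/-20% (probabilities clamped to \[0, 1\]) —
#' intended for property tests that must not depend on one fixed parameter
#' set, not for substantive analysis.
#'
#' @param n_candidates Number of candidates to draw (>= 1).
#' @param seed Integer seed; required, for reproducibility.
#' @param archetype_weights,phase_weights Named non-negative weight vectors
#'   over archetypes / phases; need not sum to 1, not all zero.
#' @param disease_pool Character vector of disease labels to sample from.
#' @param params Parameter table backing the portfolio.
#' @param start_year,end_year Horizon.
#' @param jitter_params Also jitter the parameter table (see above).
#' @return A [p2i_portfolio()] object.
#' @export
#' @examples
#' generate_portfolio(5, seed = 1)
generate_portfolio <- function(n_candidates,
                               seed,
                               archetype_weights = c(unprecedented = 15,
                                                     simple = 2, complex = 1),
                               phase_weights = c(preclinical = 3, phase1 = 11,
                                                 phase2 = 4, phase3 = 0),
                               disease_pool = c("malaria", "placental malaria",
                                                "leishmaniasis",
                                                "shigellosis, ETEC",
                                                "Nipah", "Zika"),
                               params = p2i_v2_params(),
                               start_year = 2019L,
                               end_year = 2031L,
                               jitter_params = FALSE) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  n_candidates <- as.integer(n_candidates)
  if (is.na(n_candidates) || n_candidates < 1L) {
    stop("n_candidates must be a positive integer", call. = FALSE)
  }
  check_weights <- function(w, allowed, what) {
    if (is.null(names(w)) || !all(names(w) %in% allowed) ||
        any(!is.finite(w)) || any(w < 0) || sum(w) <= 0) {
      stop(what, " must be named, non-negative, not all zero, with names in {",
           paste(allowed, collapse = ", "), "}", call. = FALSE)
    }
  }
  check_weights(archetype_weights, unique(params$archetype), "archetype_weights")
  check_weights(phase_weights, p2i_phases(), "phase_weights")
  stopifnot(length(disease_pool) >= 1)

  withr::with_seed(as.integer(seed), {
    archetype <- sample(names(archetype_weights), n_candidates, replace = TRUE,
                        prob = archetype_weights)
    entry_phase <- sample(names(phase_weights), n_candidates, replace = TRUE,
                          prob = phase_weights)
    disease <- sample(disease_pool, n_candidates, replace = TRUE)
    if (jitter_params) {
      params <- validate_params(params)
      k <- nrow(params)
      params$cost <- params$cost * stats::runif(k, 0.8, 1.2)
      params$length <- params$length * stats::runif(k, 0.8, 1.2)
      params$prob_success <- pmin(1, params$prob_success *
                                    stats::runif(k, 0.8, 1.2))
    }
  })

  candidate_id <- paste(disease, stats::ave(seq_along(disease), disease,
                                            FUN = seq_along))
  candidates <- tibble::tibble(
    candidate_id = candidate_id,
    disease = disease,
    archetype = archetype,
    entry_phase = entry_phase
  )
  p2i_portfolio(candidates, params, start_year, end_year)
}
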