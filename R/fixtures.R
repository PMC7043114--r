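# Packaged fixtures: the published archetype parameter set (P2I v.2), the
# 18-candidate EVI portfolio, the canonical EVI-scenario overrides, and
# EVI's internal benchmark data (annotations only).

#' Archetype parameters of the P2I v.2 model
#'
#' Per-phase cost (US$ millions), duration (years) and probability of
#' success (fraction) for the three vaccine archetypes: simple (platform
#' previously approved), complex (novel platform), and unprecedented
#' (HIV/TB/malaria vaccines, with much lower phase II/III success than other
#' complex vaccines).
#'
#' @return Validated parameter tibble (12 rows: 3 archetypes x 4 phases).
#' @export
#' @examples
#' p2i_v2_params()
p2i_v2_params <- function() {
  phases <- p2i_phases()
  validate_params(tibble::tibble(
    archetype = rep(c("simple", "complex", "unprecedented"), each = 4),
    phase = rep(phases, times = 3),
    cost = c(6.7, 2.2, 13.2, 201.0,
             16.6, 2.5, 13.9, 223.0,
             16.6, 2.5, 13.9, 223.0),
    length = c(3.4, 1.6, 2.2, 2.3,
               3.3, 2.0, 3.7, 3.5,
               3.3, 2.0, 3.7, 3.5),
    prob_success = c(0.41, 0.68, 0.46, 0.71,
                     0.41, 0.50, 0.22, 0.64,
                     0.41, 0.50, 0.05, 0.40)
  ))
}

#' The 18-candidate EVI vaccine portfolio
#'
#' The anonymized candidate list: 8 malaria, 5 placental malaria, 2
#' leishmaniasis, and one each for shigellosis/ETEC, Nipah and Zika; 15
#' unprecedented, 2 simple, 1 complex; 3 in preclinical, 11 in phase I, 4 in
#' phase II, none in phase III.
#'
#' @return Candidate tibble (18 rows).
#' @export
evi_candidates <- function() {
  validate_candidates(tibble::tibble(
    candidate_id = c(paste("Malaria", 1:13), "Zika 1", "Nipah 1",
                     "Diarrheal disease 1", "Leishmaniasis 1",
                     "Leishmaniasis 2"),
    disease = c("malaria", "malaria", "malaria", "malaria", "malaria",
                "malaria", "malaria",
                "placental malaria", "placental malaria",
                "malaria",
                "placental malaria", "placental malaria", "placental malaria",
                "Zika", "Nipah", "shigellosis, ETEC",
                "leishmaniasis", "leishmaniasis"),
    archetype = c(rep("unprecedented", 13), "simple", "simple", "complex",
                  "unprecedented", "unprecedented"),
    entry_phase = c("phase2", "phase1", "phase1", "phase2", "phase2",
                    "preclinical", "preclinical",
                    "phase1", "phase1", "phase1", "phase1", "phase1", "phase1",
                    "phase1", "phase1", "phase1",
                    "preclinical", "phase2")
  ))
}

#' The EVI portfolio as a ready-to-run model input
#'
#' Bundles [evi_candidates()] with [p2i_v2_params()] over the 2019-2031
#' horizon. Pass `overrides` to obtain the modified-assumption configuration
#' in one call.
#'
#' @param overrides Optional override tibble (e.g. [evi_overrides()]),
#'   applied to the parameter table before assembly.
#' @return A [p2i_portfolio()] object.
#' @export
#' @examples
#' aggregate_portfolio(evi_portfolio())$total_launches
evi_portfolio <- function(overrides = NULL) {
  params <- apply_overrides(p2i_v2_params(), overrides)
  p2i_portfolio(evi_candidates(), params, 2019L, 2031L)
}

#' Canonical EVI-scenario overrides
#'
#' The two modifications that define the modified-assumption run, the only
#' EVI-internal parameters backed by ten data points: unprecedented-vaccine
#' phase I probability of success raised to 0.70 (from 0.50) and phase I
#' duration shortened to 1.45 years, i.e. 17.4 months (from 2 years). The
#' remaining EVI-internal figures (see [evi_internal_data()]) rest on only
#' two or three data points and are deliberately not applied.
#'
#' @return Override tibble with two rows.
#' @export
evi_overrides <- function() {
  rbind(
    parameter_override("unprecedented", "phase1", "prob_success", 0.70),
    parameter_override("unprecedented", "phase1", "length", 1.45)
  )
}

#' EVI's internal benchmark data (annotations only)
#'
#' EVI's own per-phase measurements, carried verbatim as documentation: most
#' rest on two or three data points and are judged too unreliable to drive
#' the model, and EUR cost figures are not currency-converted. Only the two
#' phase I rows with n = 10 become model inputs, via [evi_overrides()].
#'
#' @return Tibble with columns `stage`, `n`, `value`, `unit`, `archetypes`,
#'   `applied`.
#' @export
evi_internal_data <- function() {
  tibble::tibble(
    stage = c("preclinical duration", "preclinical cost",
              "phase1 technical success", "phase1 transition success",
              "phase1 duration", "phase1 cost",
              "phase2 technical success", "phase2 transition success",
              "phase2 duration"),
    n = c(2L, 3L, 10L, 10L, 10L, 3L, 2L, 2L, 2L),
    value = c(36, 2483333, 1.00, 0.70, 17.4, 1500000, 1.00, 1.00, 22.5),
    unit = c("months", "EUR", "fraction", "fraction", "months", "EUR",
             "fraction", "fraction", "months"),
    archetypes = c("all unprecedented", "1 simple, 2 unprecedented",
                   rep("all unprecedented", 7)),
    applied = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
}
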