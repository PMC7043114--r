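#' Development phases of the pipeline model
#'
#' The model covers four ordered phases of product development, from advanced
#' preclinical work through phase III clinical trials. Everything upstream
#' (basic research to lead optimization) and downstream (regulatory review,
#' manufacturing scale-up, phase IV) is outside the model's scope, so cost
#' estimates are a deliberate under-estimate of full development costs.
#'
#' @return Character vector of the four phase labels, in pipeline order.
#' @export
#' @examples
#' p2i_phases()
p2i_phases <- function() {
  c("preclinical", "phase1", "phase2", "phase3")
}

phase_index <- function(phase) {
  idx <- match(phase, p2i_phases())
  if (anyNA(idx)) {
    bad <- unique(phase[is.na(idx)])
    stop("unknown development phase: ", paste(bad, collapse = ", "),
         " (expected one of ", paste(p2i_phases(), collapse = ", "), ")",
         call. = FALSE)
  }
  idx
}

#' Phases remaining from an entry phase
#'
#' A candidate entered at `entry_phase` must still traverse that phase and
#' every later one before launch.
#'
#' @param entry_phase A single phase label (see [p2i_phases()]).
#' @return Character vector of phases from `entry_phase` through `"phase3"`.
#' @export
#' @examples
#' remaining_phases("phase1")
remaining_phases <- function(entry_phase) {
  stopifnot(length(entry_phase) == 1L)
  phases <- p2i_phases()
  phases[seq(phase_index(entry_phase), length(phases))]
}
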