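# Plain-CSV readers and writers. Rendered report tables round for display
# (costs 2 dp, launch probabilities 2-3 dp); the machine-readable results
# file keeps full precision and round-trips exactly.

#' Read a portfolio candidate table from CSV
#'
#' Expected header: `candidate_id,disease,archetype,entry_phase`, with
#' `entry_phase` one of the four phase labels. Row order is preserved;
#' validation errors name the offending row.
#'
#' @param path CSV file path.
#' @return Candidate tibble.
#' @export
#' @examples
#' read_portfolio(system.file("extdata", "evi_portfolio.csv", package = "p2i"))
read_portfolio <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  candidates <- validate_candidates(df)
  if (nrow(candidates) == 0L) {
    warning("portfolio file has a valid header but no candidates: ", path,
            call. = FALSE)
  }
  candidates
}

#' Read an archetype parameter table from CSV
#'
#' Expected header: `archetype,phase,cost_musd,length_years,prob_success`.
#' The probability column accepts fractions (`0.5`), percent strings with a
#' trailing percent sign (`50%`), or — with `prob_unit = "percent"` — bare
#' percent numbers (`50`). Under the default `"auto"`, values carrying `%`
#' are divided by 100 and bare values are taken as fractions.
#'
#' @param path CSV file path.
#' @param prob_unit `"auto"` (default), `"fraction"`, or `"percent"`.
#' @return Validated parameter tibble.
#' @export
#' @examples
#' read_params(system.file("extdata", "p2i_v2_parameters.csv", package = "p2i"))
read_params <- function(path, prob_unit = c("auto", "fraction", "percent")) {
  prob_unit <- match.arg(prob_unit)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  required <- c("archetype", "phase", "cost_musd", "length_years", "prob_success")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("parameter file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  raw <- trimws(df$prob_success)
  has_pct <- grepl("%$", raw)
  num <- suppressWarnings(as.numeric(sub("%$", "", raw)))
  if (anyNA(num)) {
    stop("row ", which(is.na(num))[1], ": unparseable prob_success '",
         raw[is.na(num)][1], "'", call. = FALSE)
  }
  prob <- switch(prob_unit,
    auto = ifelse(has_pct, num / 100, num),
    fraction = {
      if (any(has_pct)) stop("percent strings found but prob_unit = 'fraction'",
                             call. = FALSE)
      num
    },
    percent = num / 100
  )
  if (any(prob < 0 | prob > 1)) {
    bad <- which(prob < 0 | prob > 1)[1]
    stop("row ", bad, ": probability ", raw[bad], " outside [0, 1] ",
         "(use prob_unit = 'percent' for bare percent values)", call. = FALSE)
  }
  validate_params(tibble::tibble(
    archetype = df$archetype,
    phase = df$phase,
    cost = as.numeric(df$cost_musd),
    length = as.numeric(df$length_years),
    prob_success = prob
  ))
}

#' Read a parameter-override table from CSV
#'
#' Expected header: `archetype,phase,field,value`.
#'
#' @param path CSV file path.
#' @return Override tibble, validated cell by cell.
#' @export
read_overrides <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    parameter_override(df$archetype[i], df$phase[i], df$field[i], df$value[i])
  }))
}

#' Rendered per-disease report table
#'
#' @param result A [aggregate_portfolio()] result.
#' @return Tibble with disease rows plus a `"Total"` row; costs rounded to 2
#'   decimals, launches to 2 (3 below 0.1).
#' @export
render_disease_table <- function(result) {
  stopifnot(inherits(result, "p2i_result"))
  bd <- result$by_disease
  tibble::tibble(
    disease = c(bd$disease, "Total"),
    cost_musd = round(c(bd$cost, result$total_cost), 2),
    expected_launches = round_launches(c(bd$launches, result$total_launches))
  )
}

#' Rendered annual report table
#'
#' @param result A [aggregate_portfolio()] result.
#' @return Tibble, one row per horizon year: cumulative cost (2 dp) and
#'   cumulative launch probability (2 dp).
#' @export
render_annual_table <- function(result) {
  stopifnot(inherits(result, "p2i_result"))
  tibble::tibble(
    year = result$annual$year,
    cost_cumulative_musd = round(result$annual$cost_cumulative, 2),
    launch_probability_cumulative = round(result$annual$launch_cumulative, 2)
  )
}

#' Write report files for a model run
#'
#' Writes `disease_table.csv` and `annual_table.csv` (rounded, human-facing)
#' and `results.json` (full precision; [read_results()] reproduces the run's
#' numbers exactly). Optionally also writes a scenario comparison and/or a
#' sensitivity table.
#'
#' @param result A [aggregate_portfolio()] result.
#' @param out_dir Output directory (created if absent).
#' @param comparison Optional [compare_scenarios()] tibble →
#'   `scenario_comparison.csv`.
#' @param sensitivity Optional [sensitivity_table()] tibble →
#'   `sensitivity.csv`.
#' @return Invisibly, the named character vector of files written.
#' @export
write_reports <- function(result, out_dir, comparison = NULL,
                          sensitivity = NULL) {
  stopifnot(inherits(result, "p2i_result"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- c(disease_table = file.path(out_dir, "disease_table.csv"),
             annual_table = file.path(out_dir, "annual_table.csv"),
             results = file.path(out_dir, "results.json"))
  utils::write.csv(render_disease_table(result), paths["disease_table"],
                   row.names = FALSE)
  utils::write.csv(render_annual_table(result), paths["annual_table"],
                   row.names = FALSE)
  machine <- list(
    start_year = result$start_year,
    end_year = result$end_year,
    total_cost = result$total_cost,
    total_launches = result$total_launches,
    by_disease = result$by_disease,
    annual = result$annual,
    candidates = result$candidates
  )
  # 17 significant digits: doubles survive the write/read cycle bit-exactly
  jsonlite::write_json(machine, paths["results"], digits = I(17),
                       auto_unbox = TRUE)
  if (!is.null(comparison)) {
    paths["scenario_comparison"] <- file.path(out_dir, "scenario_comparison.csv")
    utils::write.csv(comparison, paths["scenario_comparison"], row.names = FALSE)
  }
  if (!is.null(sensitivity)) {
    paths["sensitivity"] <- file.path(out_dir, "sensitivity.csv")
    utils::write.csv(sensitivity, paths["sensitivity"], row.names = FALSE)
  }
  invisible(paths)
}

#' Re-read a machine-readable results file
#'
#' @param path Path to a `results.json` written by [write_reports()].
#' @return List with the run's full-precision numbers (tibbles for the
#'   tabular components).
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  res <- jsonlite::read_json(path, simplifyVector = TRUE)
  res$by_disease <- tibble::as_tibble(res$by_disease)
  res$annual <- tibble::as_tibble(res$annual)
  res$candidates <- tibble::as_tibble(res$candidates)
  res
}
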