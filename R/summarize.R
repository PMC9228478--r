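#' Band MZ correlations as a reliability index
#'
#' The MZ twin correlation is a lower bound on test-retest reliability, so
#' correlations are banded as excellent (`>= 0.75`), good (`[0.60, 0.75)`),
#' or moderate (`[0.40, 0.60)`). Correlations below 0.40 are labelled
#' `indeterminate`, not "low": a low MZ correlation does not imply low
#' reliability. Band edges are half-open real intervals so every
#' correlation receives exactly one band.
#'
#' @param r_mz Numeric MZ correlations in `[-1, 1]`.
#' @return Factor with levels excellent, good, moderate, indeterminate.
#' @export
#' @examples
#' classify_reliability(c(0.81, 0.60, 0.39))
classify_reliability <- function(r_mz) {
  if (any(is.na(r_mz)) || any(r_mz < -1) || any(r_mz > 1)) {
    abort("correlations must lie in [-1, 1]")
  }
  bands <- dplyr::case_when(
    r_mz >= 0.75 ~ "excellent",
    r_mz >= 0.60 ~ "good",
    r_mz >= 0.40 ~ "moderate",
    TRUE ~ "indeterminate"
  )
  factor(bands, levels = c("excellent", "good", "moderate", "indeterminate"))
}

#' Per-platform summary of twin correlations and heritability
#'
#' Summarizes a [run_twin_pipeline()] result table per platform: mean and
#' min-max range of the MZ/DZ correlations and the reported heritability,
#' counts of ADE versus ACE assignments, and reliability-band counts of
#' the MZ correlations.
#'
#' @param results A `twin_results` tibble (or any tibble with `platform`,
#'   `r_mz`, `r_dz`, `h2`, `model` columns; missing columns are skipped).
#' @return List with `platform` (one row per platform: means/ranges and
#'   model counts) and `bands` (platform x reliability-band counts).
#' @export
platform_summary <- function(results) {
  if (!nrow(results)) abort("empty results table")
  rng <- function(x) {
    if (all(is.na(x))) return(c(NA_real_, NA_real_))
    range(x, na.rm = TRUE)
  }
  has <- function(col) col %in% names(results)
  platform <- dplyr::summarise(
    dplyr::group_by(results, .data$platform),
    n = dplyr::n(),
    r_mz_mean = if (has("r_mz")) mean(.data$r_mz) else NA_real_,
    r_mz_min = if (has("r_mz")) rng(.data$r_mz)[1] else NA_real_,
    r_mz_max = if (has("r_mz")) rng(.data$r_mz)[2] else NA_real_,
    r_dz_mean = if (has("r_dz")) mean(.data$r_dz) else NA_real_,
    r_dz_min = if (has("r_dz")) rng(.data$r_dz)[1] else NA_real_,
    r_dz_max = if (has("r_dz")) rng(.data$r_dz)[2] else NA_real_,
    h2_mean = if (has("h2")) mean(.data$h2) else NA_real_,
    h2_min = if (has("h2")) rng(.data$h2)[1] else NA_real_,
    h2_max = if (has("h2")) rng(.data$h2)[2] else NA_real_,
    n_ade = if (has("model")) sum(.data$model == "ADE") else NA_integer_,
    n_ace = if (has("model")) sum(.data$model == "ACE") else NA_integer_,
    .groups = "drop"
  )
  by_model <- NULL
  if (has("model") && has("h2")) {
    by_model <- dplyr::summarise(
      dplyr::group_by(results, .data$platform, .data$model),
      n = dplyr::n(),
      h2_mean = mean(.data$h2),
      h2_min = rng(.data$h2)[1],
      h2_max = rng(.data$h2)[2],
      e2_mean = if (has("e2")) mean(.data$e2) else NA_real_,
      .groups = "drop"
    )
  }
  bands <- NULL
  if (has("r_mz")) {
    bands <- dplyr::count(
      dplyr::mutate(results, band = classify_reliability(.data$r_mz)),
      .data$platform, .data$band, .drop = FALSE
    )
  }
  list(platform = platform, by_model = by_model, bands = bands)
}
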