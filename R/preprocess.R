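#' Apply ordered sample-exclusion rules to a cohort table
#'
#' Removes children, in a fixed order that makes reason attribution
#' deterministic: insufficient urine, not first-morning urine, freeze delay
#' over `max_freeze_delay` hours, second twin pair of multiples in the same
#' family, and (for a replication cohort) cross-cohort duplicates. Each
#' excluded child is attributed to the first matching rule. Missing flags
#' are treated as passing, with a warning.
#'
#' @param cohort Cohort tibble (see [simulate_cohort()] for the schema).
#' @param max_freeze_delay Hours between collection and freezing above
#'   which a sample is excluded.
#' @return A list with `cohort` (retained rows) and `report`, a tibble with
#'   one row per input child (`child_id`, `retained`, `reason`).
#' @export
#' @examples
#' res <- apply_sample_exclusions(reference_roster("discovery"))
#' nrow(res$cohort)
#' dplyr::count(res$report, reason)
apply_sample_exclusions <- function(cohort, max_freeze_delay = 2) {
  flags <- c("urine_sufficient", "first_morning", "freeze_delay",
             "second_multiple", "duplicate_of_other_cohort")
  for (f in intersect(flags, names(cohort))) {
    if (anyNA(cohort[[f]])) {
      warn(sprintf("missing `%s` flags treated as passing", f))
    }
  }
  flag_na_false <- function(x) !is.na(x) & x
  reason <- rep(NA_character_, nrow(cohort))
  rules <- list(
    insufficient = flag_na_false(!cohort$urine_sufficient),
    not_first_morning = flag_na_false(!cohort$first_morning),
    late_freeze = flag_na_false(cohort$freeze_delay > max_freeze_delay),
    second_multiple = flag_na_false(cohort$second_multiple),
    cross_cohort_duplicate = flag_na_false(cohort$duplicate_of_other_cohort)
  )
  for (nm in names(rules)) {
    reason[is.na(reason) & rules[[nm]]] <- nm
  }
  report <- tibble::tibble(
    child_id = cohort$child_id,
    retained = is.na(reason),
    reason = reason
  )
  list(cohort = cohort[report$retained, ], report = report)
}

#' Relative standard deviation of pooled-QC injections
#'
#' Computes, per metabolite, `100 * sd / mean` over the ordered pooled-QC
#' injection series — the standard measure of per-metabolite measurement
#' reproducibility in LC-MS/GC-MS panels.
#'
#' @param qc Tibble with columns `metabolite_id`, `value` (and optionally
#'   `injection`).
#' @return Tibble `metabolite_id`, `n_injections`, `rsd_qc` (percent; `NA`
#'   when the mean is zero, which flags the metabolite for exclusion).
#' @export
#' @examples
#' compute_rsdqc(tibble::tibble(
#'   metabolite_id = "m1", injection = 1:3, value = c(10, 9, 11)
#' ))
compute_rsdqc <- function(qc) {
  out <- dplyr::summarise(
    dplyr::group_by(qc, .data$metabolite_id),
    n_injections = sum(!is.na(.data$value)),
    mean_qc = mean(.data$value, na.rm = TRUE),
    sd_qc = sd(.data$value, na.rm = TRUE),
    .groups = "drop"
  )
  if (any(out$n_injections < 2)) {
    abort("RSDqc needs at least 2 QC injections per metabolite")
  }
  out$rsd_qc <- ifelse(out$mean_qc == 0, NA_real_,
                       100 * out$sd_qc / out$mean_qc)
  if (anyNA(out$rsd_qc)) {
    warn("zero QC mean: RSDqc undefined, metabolite flagged for exclusion")
  }
  dplyr::select(out, "metabolite_id", "n_injections", "rsd_qc")
}

#' Filter metabolites on missingness and QC reproducibility
#'
#' Drops metabolites whose missing rate exceeds `missing_threshold`
#' (strict), then metabolites whose QC relative standard deviation is at
#' least `rsd_threshold` percent (inclusive) or undefined. Below-LOD
#' entries are known-low measurements, not missing items, and do not count
#' toward the missing rate.
#'
#' @param metabolites Long metabolite tibble (`sample_id`, `metabolite_id`,
#'   `platform`, `value`, optional `below_lod`).
#' @param rsd Output of [compute_rsdqc()].
#' @param missing_threshold Maximum tolerated missing fraction (strict).
#' @param rsd_threshold RSDqc percent at or above which a metabolite is
#'   dropped.
#' @return List with `metabolites` (retained rows) and `report`, one row
#'   per input metabolite (`metabolite_id`, `platform`, `missing_rate`,
#'   `rsd_qc`, `retained`, `reason`).
#' @export
filter_metabolites <- function(metabolites, rsd,
                               missing_threshold = 0.10,
                               rsd_threshold = 15) {
  below <- if ("below_lod" %in% names(metabolites)) {
    metabolites$below_lod
  } else {
    FALSE
  }
  per_met <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(metabolites, .miss = is.na(.data$value) & !below),
      .data$metabolite_id, .data$platform
    ),
    missing_rate = mean(.data$.miss),
    .groups = "drop"
  )
  per_met <- dplyr::left_join(per_met, rsd, by = "metabolite_id")
  if (anyNA(per_met$n_injections)) {
    abort("RSDqc missing for some metabolites in the matrix")
  }
  reason <- dplyr::case_when(
    per_met$missing_rate > missing_threshold ~ "high_missingness",
    is.na(per_met$rsd_qc) | per_met$rsd_qc >= rsd_threshold ~ "high_rsdqc",
    TRUE ~ NA_character_
  )
  report <- tibble::tibble(
    metabolite_id = per_met$metabolite_id,
    platform = per_met$platform,
    missing_rate = per_met$missing_rate,
    rsd_qc = per_met$rsd_qc,
    retained = is.na(reason),
    reason = reason
  )
  keep <- report$metabolite_id[report$retained]
  list(
    metabolites = metabolites[metabolites$metabolite_id %in% keep, ],
    report = report
  )
}

#' Impute measurements censored below the limit of detection
#'
#' Replaces below-LOD entries with half the limit of detection when the
#' limit is known, otherwise with half the lowest observed level of that
#' metabolite.
#'
#' @param metabolites Long metabolite tibble with `below_lod` flags and a
#'   per-metabolite `lod` column (`NA` when the limit is unknown).
#' @return The tibble with censored values imputed (flags retained).
#' @export
impute_below_lod <- function(metabolites) {
  if (!"below_lod" %in% names(metabolites)) {
    abort("`metabolites` must carry a `below_lod` flag column")
  }
  if (!any(metabolites$below_lod)) return(metabolites)
  lod_col <- if ("lod" %in% names(metabolites)) metabolites$lod else NA_real_
  mins <- dplyr::summarise(
    dplyr::group_by(metabolites, .data$metabolite_id),
    .min_obs = suppressWarnings(min(.data$value, na.rm = TRUE)),
    .groups = "drop"
  )
  out <- dplyr::left_join(metabolites, mins, by = "metabolite_id")
  fill <- ifelse(!is.na(lod_col), lod_col / 2, out$.min_obs / 2)
  bad <- out$below_lod & is.infinite(out$.min_obs) & is.na(lod_col)
  if (any(bad)) {
    abort(paste(
      "cannot impute: metabolite(s) with every entry censored and no LOD:",
      paste(unique(out$metabolite_id[bad]), collapse = ", ")
    ))
  }
  out$value[out$below_lod] <- fill[out$below_lod]
  dplyr::select(out, -".min_obs")
}

#' Normalize metabolite responses by sample creatinine
#'
#' Divides every measured value by the creatinine concentration of its
#' sample, the standard correction for urine dilution. Creatinine units
#' cancel; only consistency across samples matters.
#'
#' @param metabolites Long metabolite tibble.
#' @param cohort Cohort tibble supplying `child_id` and `creatinine`.
#' @return The metabolite tibble with `value` creatinine-normalized.
#' @export
normalize_creatinine <- function(metabolites, cohort) {
  crea <- cohort$creatinine[match(metabolites$sample_id, cohort$child_id)]
  if (anyNA(crea)) {
    abort("samples present in the matrix but absent from the cohort table")
  }
  if (any(crea <= 0)) {
    abort(paste(
      "nonpositive creatinine for sample(s):",
      paste(unique(metabolites$sample_id[crea <= 0]), collapse = ", ")
    ))
  }
  metabolites$value <- metabolites$value / crea
  metabolites
}

#' Inverse normal rank transformation
#'
#' Maps the non-missing values of a vector to standard-normal quantiles of
#' `(rank - offset) / (n - 2 * offset + 1)` with average ranks for ties.
#' The default offset 3/8 is the Blom convention dominant in
#' genetic-epidemiology pipelines; the transform removes scale and
#' distributional shape, so any strictly monotone transform of the input
#' yields identical output.
#'
#' @param x Numeric vector, possibly with missing values.
#' @param offset Rank offset constant (Blom 3/8 by default).
#' @return Numeric vector of the same length; missing stays missing.
#' @export
#' @examples
#' inverse_normal_transform(c(5, 2, 9))
inverse_normal_transform <- function(x, offset = 3 / 8) {
  obs <- !is.na(x)
  n <- sum(obs)
  if (n < 2) abort("inverse normal transform needs at least 2 observed values")
  if (length(unique(x[obs])) == 1L) {
    warn("all observed values identical: transform is degenerate (all zero)")
  }
  r <- rank(x[obs], ties.method = "average")
  out <- x
  out[obs] <- qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Run the full preprocessing pipeline
#'
#' Chains, in order: sample exclusions, metabolite missingness/RSDqc
#' filters, below-LOD imputation, creatinine normalization, and the
#' per-metabolite inverse normal rank transformation (applied within
#' cohort). After the transform every metabolite has mean ~0 and variance
#' ~1 by construction.
#'
#' @param metabolites Long metabolite tibble.
#' @param cohort Cohort tibble.
#' @param qc QC-injection tibble.
#' @param missing_threshold,rsd_threshold Filter settings, see
#'   [filter_metabolites()].
#' @param int_offset Offset constant of [inverse_normal_transform()].
#' @param max_freeze_delay See [apply_sample_exclusions()].
#' @return List with `processed` (long tibble of transformed values),
#'   `cohort` (retained children), `sample_report`, `metabolite_report`
#'   and `rsd`.
#' @export
preprocess_pipeline <- function(metabolites, cohort, qc,
                                missing_threshold = 0.10,
                                rsd_threshold = 15,
                                int_offset = 3 / 8,
                                max_freeze_delay = 2) {
  excl <- apply_sample_exclusions(cohort, max_freeze_delay = max_freeze_delay)
  kept <- metabolites[metabolites$sample_id %in% excl$cohort$child_id, ]
  rsd <- compute_rsdqc(qc)
  filt <- filter_metabolites(kept, rsd,
                             missing_threshold = missing_threshold,
                             rsd_threshold = rsd_threshold)
  imp <- impute_below_lod(filt$metabolites)
  norm <- normalize_creatinine(imp, excl$cohort)
  processed <- dplyr::mutate(
    dplyr::group_by(norm, .data$metabolite_id),
    value = inverse_normal_transform(.data$value, offset = int_offset)
  )
  processed <- dplyr::ungroup(processed)
  list(
    processed = dplyr::select(processed, "sample_id", "metabolite_id",
                              "platform", "value"),
    cohort = excl$cohort,
    sample_report = excl$report,
    metabolite_report = filt$report,
    rsd = rsd
  )
}
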