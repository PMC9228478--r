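#' Deterministic reference rosters with sample-exclusion flags
#'
#' Builds, entirely in code and without randomness, a cohort roster that
#' mirrors the documented intake of a large twin biomarker collection:
#'
#' * `discovery`: 1362 twins — 645 clean complete pairs (531 MZ + 114 DZ),
#'   10 clean singletons whose co-twin is individually excluded, 15 pairs in
#'   which both twins are excluded, and 11 second twin pairs of multiples
#'   (22 children). Exclusion flags total 2 (insufficient urine), 13 (not
#'   first-morning), 25 (freeze delay over 2 h) and 22 (second multiple),
#'   leaving 1300 children after exclusion.
#' * `replication`: 186 children — 179 clean (160 single children, 8 sibling
#'   pairs and 1 sibling trio), 1 cross-cohort duplicate, 3 not
#'   first-morning and 3 with freeze delay over 2 h.
#'
#' Ages, sexes and creatinine values are filled with deterministic, evenly
#' spaced placeholder values; the roster exists to exercise exclusion
#' accounting, not measurement models.
#'
#' @param cohort `"discovery"` or `"replication"`.
#' @return A cohort tibble (see [simulate_cohort()] for the schema).
#' @export
#' @examples
#' nrow(reference_roster("discovery"))
reference_roster <- function(cohort = c("discovery", "replication")) {
  cohort <- match.arg(cohort)
  if (cohort == "discovery") discovery_roster() else replication_roster()
}

blank_roster <- function(n, cohort) {
  tibble::tibble(
    child_id = character(n),
    family_id = character(n),
    cohort = cohort,
    zygosity = NA_character_,
    birth_order = NA_integer_,
    sex = rep_len(c("male", "female"), n),
    age = rep_len(seq(5.7, 12.9, length.out = 50), n),
    first_morning = TRUE,
    freeze_delay = 0,
    urine_sufficient = TRUE,
    second_multiple = FALSE,
    duplicate_of_other_cohort = FALSE,
    creatinine = 1
  )
}

discovery_roster <- function() {
  pair_rows <- function(fid, zyg) {
    r <- blank_roster(2L, "discovery")
    r$family_id <- fid
    r$child_id <- paste0(fid, "_", 1:2)
    r$zygosity <- zyg
    r$birth_order <- 1:2
    r$age <- rep(5.7 + (as.integer(sub("F", "", fid)) %% 72) * 0.1, 2)
    r
  }
  fids <- sprintf("F%04d", 1:670)

  clean_pairs <- purrr::map_dfr(1:645, function(i) {
    pair_rows(fids[i], if (i <= 531) "MZ" else "DZ")
  })

  # families 646-655: one retained singleton, co-twin individually excluded
  co_reason <- c(
    rep("insufficient", 2), rep("not_first_morning", 4), rep("late_freeze", 4)
  )
  singleton_fams <- purrr::map_dfr(646:655, function(i) {
    r <- pair_rows(fids[i], if (i <= 651) "MZ" else "DZ")
    reason <- co_reason[i - 645]
    if (reason == "insufficient") r$urine_sufficient[2] <- FALSE
    if (reason == "not_first_morning") r$first_morning[2] <- FALSE
    if (reason == "late_freeze") r$freeze_delay[2] <- 3
    r
  })

  # families 656-670: both twins excluded (9 not-first-morning, 21 late-freeze)
  both_reason <- c(rep("not_first_morning", 9), rep("late_freeze", 21))
  excl_pairs <- purrr::map_dfr(656:670, function(i) {
    r <- pair_rows(fids[i], "DZ")
    for (k in 1:2) {
      reason <- both_reason[(i - 656) * 2 + k]
      if (reason == "not_first_morning") r$first_morning[k] <- FALSE
      if (reason == "late_freeze") r$freeze_delay[k] <- 2.5
    }
    r
  })

  # 11 families with a second twin pair of multiples (triplet-plus families)
  second_pairs <- purrr::map_dfr(1:11, function(i) {
    r <- pair_rows(fids[i], "DZ")
    r$child_id <- paste0(fids[i], "_", 3:4)
    r$birth_order <- 1:2
    r$second_multiple <- TRUE
    r
  })

  dplyr::bind_rows(clean_pairs, singleton_fams, excl_pairs, second_pairs)
}

replication_roster <- function() {
  n_clean <- 179L
  r <- blank_roster(n_clean + 7L, "replication")
  # 160 singles, 8 sibling pairs, 1 sibling trio, then 7 flagged children
  fam <- c(
    sprintf("R%03d", 1:160),
    rep(sprintf("R%03d", 161:168), each = 2),
    rep("R169", 3),
    sprintf("R%03d", 170:176)
  )
  r$family_id <- fam
  r$child_id <- make.unique(paste0(fam, "_c"), sep = "")
  r$duplicate_of_other_cohort[n_clean + 1L] <- TRUE
  r$first_morning[n_clean + 2:4] <- FALSE
  r$freeze_delay[n_clean + 5:7] <- 4
  r
}

#' Deterministic metabolite panel for the quality-control worked example
#'
#' Builds a 100-sample panel of 66 amines, 21 organic acids and 13 steroids
#' together with pooled-QC injection series, engineered so that exactly 4
#' amines exceed 10% missingness and 6 amines, 1 organic acid and 3
#' steroids have a QC relative standard deviation of at least 15% (one of
#' them exactly 15%, exercising the inclusive boundary). Passing the panel
#' through [compute_rsdqc()] and [filter_metabolites()] retains 56 amines,
#' 20 organic acids and 10 steroids: 86 metabolites.
#'
#' @return A list with `metabolites` (long tibble) and `qc` (injection
#'   tibble).
#' @export
qc_filter_fixture <- function() {
  n_samples <- 100L
  sizes <- c(amine = 66L, organic_acid = 21L, steroid = 13L)
  panel <- purrr::map_dfr(names(sizes), function(pf) {
    tibble::tibble(
      metabolite_id = sprintf("%s_%02d", platform_prefix(pf),
                              seq_len(sizes[[pf]])),
      platform = pf
    )
  })
  sample_id <- sprintf("S%03d", seq_len(n_samples))

  high_missing <- sprintf("am_%02d", 1:4)
  high_rsd <- c(sprintf("am_%02d", 5:10), "oa_01", sprintf("st_%02d", 1:3))

  metabolites <- tidyr::crossing(
    tibble::tibble(sample_id = sample_id), panel
  )
  metabolites <- dplyr::arrange(metabolites, .data$metabolite_id,
                                .data$sample_id)
  metabolites$value <- 10 + (seq_len(nrow(metabolites)) %% 7) * 0.1
  # 15 of 100 samples missing for the high-missing amines (> 10%)
  metabolites$value[
    metabolites$metabolite_id %in% high_missing &
      metabolites$sample_id %in% sample_id[1:15]
  ] <- NA_real_
  metabolites$below_lod <- FALSE
  metabolites$missing <- is.na(metabolites$value)
  metabolites$lod <- NA_real_

  qc <- purrr::map_dfr(panel$metabolite_id, function(m) {
    inj <- if (m == high_rsd[1]) {
      c(8.5, 10, 11.5)            # sd 1.5, mean 10: RSD exactly 15.0%
    } else if (m %in% high_rsd) {
      c(8, 10, 12)                # sd 2, mean 10: RSD 20%
    } else {
      c(9.5, 10, 10.5)            # sd 0.5, mean 10: RSD 5%
    }
    tibble::tibble(metabolite_id = m, injection = seq_along(inj), value = inj)
  })

  list(metabolites = metabolites, qc = qc)
}

#' Deterministic MZ-correlation fixture for reliability banding
#'
#' A panel of 86 MZ twin correlations whose per-platform band counts mirror
#' a published urinary panel: among 56 amines 1 excellent, 8 good, 43
#' moderate and 4 indeterminate; among 20 organic acids 3 good, 13 moderate
#' and 4 indeterminate; among 10 steroids 4 excellent and 6 moderate.
#' Values are evenly spaced within each band and span 0.25-0.75 (amines),
#' 0.33-0.64 (organic acids) and 0.43-0.81 (steroids).
#'
#' @return Tibble with `metabolite_id`, `platform`, `r_mz`.
#' @export
reference_mz_correlations <- function() {
  band_vals <- function(n, lo, hi) {
    if (n == 1L) return((lo + hi) / 2)
    seq(lo, hi, length.out = n)
  }
  specs <- list(
    amine = list(
      excellent = c(1L, 0.75, 0.75), good = c(8L, 0.60, 0.74),
      moderate = c(43L, 0.40, 0.59), indeterminate = c(4L, 0.25, 0.39)
    ),
    organic_acid = list(
      good = c(3L, 0.60, 0.64), moderate = c(13L, 0.40, 0.59),
      indeterminate = c(4L, 0.33, 0.39)
    ),
    steroid = list(
      excellent = c(4L, 0.75, 0.81), moderate = c(6L, 0.43, 0.59)
    )
  )
  purrr::map_dfr(names(specs), function(pf) {
    vals <- unlist(lapply(specs[[pf]], function(b) band_vals(b[1], b[2], b[3])))
    tibble::tibble(
      metabolite_id = sprintf("%s_%02d", platform_prefix(pf), seq_along(vals)),
      platform = pf,
      r_mz = unname(vals)
    )
  })
}
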