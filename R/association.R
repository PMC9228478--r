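#' Benjamini-Hochberg step-up q-values
#'
#' Computes step-up false-discovery-rate q-values for a vector of p-values,
#' optionally against a larger analysis-wide test count `m` (as when a
#' scan's FDR is defined over the full metabolite panel even if some tests
#' are unavailable).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Number of tests the correction is defined over; defaults to
#'   `length(p)` and must be at least that.
#' @return Vector of q-values, monotone nondecreasing in `p`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.5))
bh_fdr <- function(p, m = length(p)) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1] and be non-missing")
  }
  if (m < length(p)) abort("`m` must be at least `length(p)`")
  p.adjust(p, method = "BH", n = m)
}

#' Dichotomize age at a cutoff
#'
#' @param age Numeric ages in years.
#' @param cutoff Boundary; ages at or above it go to the older group.
#' @return Integer vector: 0 (younger) / 1 (older).
#' @export
#' @examples
#' dichotomize_age(c(9.99, 10, 12.9))
dichotomize_age <- function(age, cutoff = 10) {
  as.integer(age >= cutoff)
}

# the eight scan layouts: fixed effects, stratifying variable, age coding
scan_analyses <- function() {
  list(
    sex_age_continuous = list(fixed = c("sex", "age"), stratum = NULL),
    sex_age_dichotomized = list(fixed = c("sex", "age_group"), stratum = NULL),
    age_in_males = list(fixed = "age", stratum = c(sex = "male")),
    age_in_females = list(fixed = "age", stratum = c(sex = "female")),
    age_dichotomized_in_males = list(fixed = "age_group",
                                     stratum = c(sex = "male")),
    age_dichotomized_in_females = list(fixed = "age_group",
                                       stratum = c(sex = "female")),
    sex_in_younger = list(fixed = "sex", stratum = c(age_group = "0")),
    sex_in_older = list(fixed = "sex", stratum = c(age_group = "1"))
  )
}

#' Metabolite-wide association scan for sex and age
#'
#' Runs, per metabolite, a family-clustered linear mixed model
#' ([fit_family_lmm()]) under one of eight analysis layouts: the joint
#' sex + age model with age continuous or dichotomized at 10 years, the
#' sex-stratified age models (continuous and dichotomized), and the
#' age-group-stratified sex models. Within each analysis, q-values are
#' obtained per term by Benjamini-Hochberg over the scanned metabolites
#' (or an explicit `m`), and significance is called at `q <= fdr_q`.
#'
#' @param processed Long tibble of preprocessed values (`sample_id`,
#'   `metabolite_id`, `platform`, `value`).
#' @param cohort Cohort tibble aligned with `processed`.
#' @param analysis One of the eight layout names; see Details.
#' @param fdr_m Test count for the FDR correction; defaults to the number
#'   of metabolites scanned in this analysis.
#' @param fdr_q Significance threshold on the q-value.
#' @param min_families Strata with fewer families than this are refused.
#' @return Tibble of class `twinmetab_scan`: one row per metabolite and
#'   tested term, with `estimate`, `std.error`, `statistic`, `p.value`,
#'   `q.value`, `significant`, `analysis`, `n_used`.
#' @export
run_association_scan <- function(processed, cohort,
                                 analysis = "sex_age_continuous",
                                 fdr_m = NULL, fdr_q = 0.05,
                                 min_families = 10) {
  layouts <- scan_analyses()
  if (!analysis %in% names(layouts)) {
    abort(paste("unknown analysis; use one of:",
                paste(names(layouts), collapse = ", ")))
  }
  layout <- layouts[[analysis]]
  cohort <- dplyr::mutate(cohort, age_group = dichotomize_age(.data$age))
  if (!is.null(layout$stratum)) {
    var <- names(layout$stratum)
    cohort <- cohort[as.character(cohort[[var]]) == layout$stratum, ]
    if (length(unique(cohort$family_id)) < min_families) {
      abort(sprintf(
        "stratum %s = %s has fewer than %d families; analysis refused",
        var, layout$stratum, min_families
      ))
    }
  }
  dat <- dplyr::inner_join(processed, cohort,
                           by = c(sample_id = "child_id"))
  mets <- unique(dat$metabolite_id)
  res <- purrr::map_dfr(mets, function(m) {
    d <- dat[dat$metabolite_id == m, ]
    fit <- tryCatch(
      fit_family_lmm(d, "value", layout$fixed, "family_id"),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      warn(sprintf("metabolite %s: model did not fit; excluded from FDR", m))
      return(tibble::tibble(
        metabolite_id = m, platform = d$platform[1],
        term = layout$fixed, estimate = NA_real_, std.error = NA_real_,
        statistic = NA_real_, p.value = NA_real_, n_used = NA_integer_,
        converged = FALSE
      ))
    }
    td <- tidy(fit)
    td <- td[td$term != "(Intercept)", ]
    td$term[td$term == "sexmale"] <- "sex"
    td$term[grepl("^sex", td$term)] <- "sex"
    td$term[td$term == "age_group"] <- "age_dichotomized"
    tibble::tibble(
      metabolite_id = m, platform = d$platform[1],
      term = td$term, estimate = td$estimate, std.error = td$std.error,
      statistic = td$statistic, p.value = td$p.value,
      n_used = fit$n, converged = TRUE
    )
  })
  m_tests <- fdr_m %||% length(mets)
  res <- dplyr::mutate(
    dplyr::group_by(res, .data$term),
    q.value = {
      q <- rep(NA_real_, dplyr::n())
      ok <- .data$converged & !is.na(.data$p.value)
      if (any(ok)) {
        q[ok] <- bh_fdr(.data$p.value[ok], m = max(m_tests, sum(ok)))
      }
      q
    }
  )
  res <- dplyr::ungroup(res)
  res$significant <- !is.na(res$q.value) & res$q.value <= fdr_q
  res$analysis <- analysis
  class(res) <- c("twinmetab_scan", class(res))
  res
}

#' Discovery-replication concordance of association scans
#'
#' Matches two scan tables on metabolite and term, and reports, per term,
#' the correlation and sign agreement of effect estimates across cohorts
#' and the set of replicated metabolites: significant in both cohorts with
#' the same effect sign.
#'
#' @param discovery,replication `twinmetab_scan` tibbles.
#' @return List with `summary` (per-term tibble: `beta_correlation`,
#'   `sign_agreement`, `n_shared`, `n_discovery_significant`,
#'   `n_replicated`) and `replicated` (metabolite/term pairs).
#' @export
replication_concordance <- function(discovery, replication) {
  shared <- dplyr::inner_join(
    discovery, replication,
    by = c("metabolite_id", "term"), suffix = c("_disc", "_repl")
  )
  if (nrow(shared) == 0L) {
    abort("no shared metabolite/term pairs between the two scans")
  }
  shared$replicated <- shared$significant_disc & shared$significant_repl &
    sign(shared$estimate_disc) == sign(shared$estimate_repl)
  summary <- dplyr::summarise(
    dplyr::group_by(shared, .data$term),
    n_shared = dplyr::n(),
    beta_correlation = cor(.data$estimate_disc, .data$estimate_repl,
                           use = "complete.obs"),
    sign_agreement = mean(
      sign(.data$estimate_disc) == sign(.data$estimate_repl), na.rm = TRUE
    ),
    n_discovery_significant = sum(.data$significant_disc),
    n_replicated = sum(.data$replicated),
    .groups = "drop"
  )
  list(
    summary = summary,
    replicated = dplyr::select(
      shared[shared$replicated, ],
      "metabolite_id", "term", "estimate_disc", "estimate_repl",
      "q.value_disc", "q.value_repl"
    )
  )
}
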