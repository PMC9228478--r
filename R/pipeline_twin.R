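#' Run the full twin-modelling pipeline over a metabolite panel
#'
#' For every metabolite: lays out twin pairs ([pair_data()]), selects the
#' mean-model covariates by likelihood-ratio tests ([select_covariates()]),
#' takes the ML twin correlations from the best saturated fit, chooses ADE
#' or ACE from the correlation pattern ([choose_model()]) and estimates
#' the variance components with the same covariates ([fit_ace_ade()]).
#' Metabolites whose fits fail are skipped with a warning, not fatally.
#'
#' @param processed Long tibble of preprocessed values.
#' @param cohort Cohort tibble (twins with zygosity).
#' @param ci Also compute profile-likelihood intervals for the reported
#'   heritability share (slower).
#' @param level Confidence level of those intervals.
#' @param alpha Rejection level of the covariate-selection tests.
#' @return Tibble of class `twin_results`, one row per metabolite:
#'   `metabolite_id`, `platform`, `covariate_set`, `r_mz`, `r_dz`,
#'   `model`, `A`, `D_or_C`, `E`, `V`, `a2`, `d2_or_c2`, `e2`, `h2`,
#'   `h2_type`, optional `h2_ci_lower`/`h2_ci_upper`, `loglik_sat`,
#'   `loglik_model`, pair counts.
#' @export
run_twin_pipeline <- function(processed, cohort, ci = FALSE, level = 0.95,
                              alpha = 0.05) {
  paired_all <- pair_data(processed, cohort)
  platforms <- unique(processed[, c("metabolite_id", "platform")])
  mets <- unique(paired_all$metabolite_id)
  rows <- purrr::map(mets, function(m) {
    paired <- paired_all[paired_all$metabolite_id == m, ]
    res <- tryCatch({
      sel <- select_covariates(paired, alpha = alpha)
      sat <- sel$fits[[sel$covariate_set]]
      model <- choose_model(sat$r_mz, sat$r_dz)
      vc <- fit_ace_ade(paired, model = model,
                        covariate_set = sel$covariate_set)
      row <- tibble::tibble(
        metabolite_id = m,
        covariate_set = sel$covariate_set,
        r_mz = sat$r_mz,
        r_dz = sat$r_dz,
        model = model,
        A = vc$A,
        D_or_C = unname(vc$D_or_C),
        E = vc$E,
        V = vc$V,
        a2 = vc$a2,
        d2_or_c2 = unname(vc$x2),
        e2 = vc$e2,
        h2 = vc$h2,
        h2_type = vc$h2_type,
        loglik_sat = sat$logLik,
        loglik_model = vc$logLik,
        n_families = vc$n_families,
        n_complete_mz = sat$n_complete_mz,
        n_complete_dz = sat$n_complete_dz
      )
      if (ci) {
        interval <- profile_ci(vc, component = "h2", level = level)
        row$h2_ci_lower <- interval[["lower"]]
        row$h2_ci_upper <- interval[["upper"]]
      }
      row
    }, error = function(e) {
      warn(sprintf("metabolite %s skipped: %s", m, conditionMessage(e)))
      NULL
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::left_join(out, platforms, by = "metabolite_id")
  out <- dplyr::relocate(out, "platform", .after = "metabolite_id")
  class(out) <- c("twin_results", class(out))
  out
}

#' @rdname fit_saturated
#' @param x A `saturated_fit`.
#' @param ... Unused.
#' @export
tidy.saturated_fit <- function(x, ...) {
  tibble::tibble(
    term = c(names(x$coefficients), "sigma2", "cov_mz", "cov_dz",
             "r_mz", "r_dz"),
    estimate = c(unname(x$coefficients), x$sigma2, x$cov_mz, x$cov_dz,
                 x$r_mz, x$r_dz)
  )
}

#' @rdname fit_saturated
#' @export
glance.saturated_fit <- function(x, ...) {
  tibble::tibble(
    covariate_set = x$covariate_set,
    r_mz = x$r_mz,
    r_dz = x$r_dz,
    sigma2 = x$sigma2,
    logLik = x$logLik,
    n_families = x$n_families,
    n_complete_mz = x$n_complete_mz,
    n_complete_dz = x$n_complete_dz
  )
}

#' @rdname fit_ace_ade
#' @param x A `vc_fit`.
#' @param ... Unused.
#' @export
tidy.vc_fit <- function(x, ...) {
  xn <- names(x$D_or_C)
  tibble::tibble(
    term = c(names(x$coefficients), "A", xn, "E", "V",
             "a2", paste0(tolower(xn), "2"), "e2", "h2"),
    estimate = c(unname(x$coefficients), x$A, unname(x$D_or_C), x$E, x$V,
                 x$a2, unname(x$x2), x$e2, x$h2)
  )
}

#' @rdname fit_ace_ade
#' @export
glance.vc_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    covariate_set = x$covariate_set,
    h2 = x$h2,
    h2_type = x$h2_type,
    logLik = x$logLik,
    n_families = x$n_families
  )
}
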