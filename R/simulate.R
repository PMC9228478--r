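#' Default per-metabolite variance fractions for a simulated panel
#'
#' Builds a panel of metabolites across the three urinary platforms (amines,
#' organic acids, steroids) with additive-genetic (A), common-environmental
#' (C), dominant-genetic (D) and unique-environmental (E) variance fractions.
#' Per platform, a fixed proportion of metabolites follows an ADE regime
#' (no shared environment, `r_MZ > 2 r_DZ`) and the remainder an ACE regime;
#' the fraction values are platform-level figures typical of urinary panels
#' in children, where genetic factors explain most familial resemblance.
#'
#' @param n_metabolites Named integer vector with elements `amine`,
#'   `organic_acid` and `steroid`: panel size per platform.
#' @return A tibble with columns `metabolite_id`, `platform`, `A`, `C`, `D`,
#'   `E`. Each row sums to 1 and never has both `C > 0` and `D > 0`.
#' @export
#' @examples
#' default_var_fracs(c(amine = 4, organic_acid = 2, steroid = 2))
default_var_fracs <- function(n_metabolites = c(
                                amine = 56, organic_acid = 20, steroid = 10
                              )) {
  n_metabolites <- check_panel_sizes(n_metabolites)
  # per-platform regimes: (ADE fracs), (ACE fracs), proportion of panel ADE
  regimes <- list(
    amine        = list(ade = c(A = 0.13, D = 0.38, E = 0.49),
                        ace = c(A = 0.50, C = 0.13, E = 0.37),
                        p_ade = 50 / 56),
    organic_acid = list(ade = c(A = 0.40, D = 0.12, E = 0.48),
                        ace = c(A = 0.50, C = 0.06, E = 0.44),
                        p_ade = 13 / 20),
    steroid      = list(ade = c(A = 0.39, D = 0.22, E = 0.39),
                        ace = c(A = 0.47, C = 0.10, E = 0.43),
                        p_ade = 6 / 10)
  )
  purrr::map_dfr(names(regimes), function(pf) {
    n <- n_metabolites[[pf]]
    if (n == 0L) return(NULL)
    reg <- regimes[[pf]]
    n_ade <- round(n * reg$p_ade)
    frac <- function(v, k) tibble::tibble(
      A = rep(v[["A"]], k),
      C = rep(v["C"] %[0]% 0, k),
      D = rep(v["D"] %[0]% 0, k),
      E = rep(v[["E"]], k)
    )
    out <- dplyr::bind_rows(frac(reg$ade, n_ade), frac(reg$ace, n - n_ade))
    out$platform <- pf
    out$metabolite_id <- sprintf("%s_%02d", platform_prefix(pf), seq_len(n))
    dplyr::select(out, "metabolite_id", "platform", "A", "C", "D", "E")
  })
}

# value of a possibly-missing named element, with default
`%[0]%` <- function(x, default) {
  if (is.na(x) || length(x) == 0L) default else unname(x)
}

platform_prefix <- function(pf) {
  c(amine = "am", organic_acid = "oa", steroid = "st")[[pf]]
}

check_panel_sizes <- function(n) {
  wanted <- c("amine", "organic_acid", "steroid")
  if (is.null(names(n)) || !all(wanted %in% names(n))) {
    abort("`n_metabolites` must be named with amine, organic_acid, steroid")
  }
  vapply(n[wanted], as.integer, integer(1))
}

#' Specification of a simulated twin cohort
#'
#' Collects every parameter of the synthetic-data generator: family
#' composition, per-metabolite variance fractions, mean effects of sex and
#' age, and the nuisance layers (creatinine dilution, limit-of-detection
#' censoring, item missingness, pooled-QC injections). Defaults reproduce
#' the composition of a large children's twin cohort: 531 MZ and 114 DZ
#' complete pairs plus 6 MZ and 4 DZ singleton twins (1300 children), ages
#' 5.7-12.9 years, 48.2% girls, and a panel of 56 amines, 20 organic acids
#' and 10 steroids.
#'
#' @param n_mz_pairs,n_dz_pairs Number of complete monozygotic / dizygotic
#'   twin pairs.
#' @param n_mz_singletons,n_dz_singletons Twins whose co-twin contributes no
#'   sample (kept as incomplete pairs for full-information likelihoods).
#' @param var_fracs Tibble with columns `metabolite_id`, `platform`, `A`,
#'   `C`, `D`, `E`; each row must sum to 1 with `C * D == 0`. Defaults to
#'   [default_var_fracs()].
#' @param beta_sex Standardized mean shift for girls (latent scale).
#' @param beta_age Standardized slope per year of age (latent scale).
#' @param age_range Age range in years; pair members share one age drawn
#'   uniformly per family.
#' @param prop_female Probability that a child is a girl. MZ co-twins always
#'   share sex; DZ co-twin sexes are drawn independently.
#' @param creatinine_lognormal Named `(mu, sigma)` of the log-normal
#'   creatinine draw (arbitrary but consistent concentration units).
#' @param lod_quantile Fraction of each metabolite's raw distribution
#'   censored below the limit of detection (0 disables censoring).
#' @param lod_known_fraction Fraction of metabolites whose LOD value is
#'   recorded in the output metadata; for the rest the LOD is withheld so
#'   the half-minimum imputation branch is exercised.
#' @param missing_rate Completely-at-random item missingness.
#' @param qc_cv_percent Coefficient of variation (percent) of pooled-QC
#'   injections; scalar or one value per metabolite.
#' @param qc_interval One QC injection every `qc_interval` study samples.
#' @param raw_scale Log-scale factor mapping the unit-variance latent value
#'   to the raw relative response ratio (`raw = exp(raw_scale * latent)`).
#' @param seed Integer seed; the single RNG stream for the whole draw.
#' @return An object of class `simulation_spec` (a named list).
#' @export
simulation_spec <- function(n_mz_pairs = 531L,
                            n_dz_pairs = 114L,
                            n_mz_singletons = 6L,
                            n_dz_singletons = 4L,
                            var_fracs = NULL,
                            beta_sex = 0,
                            beta_age = 0,
                            age_range = c(5.7, 12.9),
                            prop_female = 0.482,
                            creatinine_lognormal = c(mu = 0, sigma = 0.4),
                            lod_quantile = 0.02,
                            lod_known_fraction = 0.5,
                            missing_rate = 0.02,
                            qc_cv_percent = 8,
                            qc_interval = 10L,
                            raw_scale = 0.5,
                            seed = 1L) {
  if (is.null(var_fracs)) var_fracs <- default_var_fracs()
  var_fracs <- tibble::as_tibble(var_fracs)
  needed <- c("metabolite_id", "platform", "A", "C", "D", "E")
  if (!all(needed %in% names(var_fracs))) {
    abort("`var_fracs` needs columns metabolite_id, platform, A, C, D, E")
  }
  tot <- with(var_fracs, A + C + D + E)
  if (any(abs(tot - 1) > 1e-8)) {
    abort("each var_fracs row must sum to 1")
  }
  if (any(var_fracs$C > 0 & var_fracs$D > 0)) {
    abort(paste(
      "C and D cannot both be positive for the same metabolite:",
      "the classical twin design does not identify an ACDE model"
    ))
  }
  if (any(var_fracs$A < 0 | var_fracs$C < 0 | var_fracs$D < 0 |
            var_fracs$E < 0)) {
    abort("variance fractions must be nonnegative")
  }
  stopifnot(
    length(age_range) == 2L, age_range[1] <= age_range[2],
    prop_female >= 0, prop_female <= 1,
    lod_quantile >= 0, lod_quantile < 1,
    missing_rate >= 0, missing_rate < 1,
    qc_interval >= 1
  )
  spec <- list(
    n_mz_pairs = as.integer(n_mz_pairs),
    n_dz_pairs = as.integer(n_dz_pairs),
    n_mz_singletons = as.integer(n_mz_singletons),
    n_dz_singletons = as.integer(n_dz_singletons),
    var_fracs = var_fracs,
    beta_sex = beta_sex,
    beta_age = beta_age,
    age_range = age_range,
    prop_female = prop_female,
    creatinine_lognormal = creatinine_lognormal,
    lod_quantile = lod_quantile,
    lod_known_fraction = lod_known_fraction,
    missing_rate = missing_rate,
    qc_cv_percent = qc_cv_percent,
    qc_interval = as.integer(qc_interval),
    raw_scale = raw_scale,
    seed = as.integer(seed)
  )
  structure(spec, class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("<simulation_spec>\n")
  cat(sprintf(
    "  families: %d MZ + %d DZ pairs, %d + %d singletons\n",
    x$n_mz_pairs, x$n_dz_pairs, x$n_mz_singletons, x$n_dz_singletons
  ))
  cat(sprintf("  metabolites: %d\n", nrow(x$var_fracs)))
  cat(sprintf(
    "  betas: sex %.3g, age %.3g; ages %.1f-%.1f\n",
    x$beta_sex, x$beta_age, x$age_range[1], x$age_range[2]
  ))
  cat(sprintf(
    "  nuisance: lod q %.3g, missing %.3g, qc cv %s%%, seed %d\n",
    x$lod_quantile, x$missing_rate,
    paste(unique(x$qc_cv_percent), collapse = "/"), x$seed
  ))
  invisible(x)
}

#' Simulate a twin cohort with metabolite panel and QC series
#'
#' Draws a twin cohort under the classical twin design. Per metabolite the
#' latent value of child `i` is
#' `y = beta_sex * sex + beta_age * age + a + c + d + e`, where the
#' within-pair correlations of the components are `corr(a) = 1` (MZ) or
#' `0.5` (DZ), `corr(d) = 1` or `0.25`, `corr(c) = 1` and `corr(e) = 0`,
#' with variances given by the spec's `var_fracs`. The raw relative
#' response ratio is `exp(raw_scale * y)` multiplied by the child's
#' creatinine draw; values below the LOD quantile are censored, items go
#' missing completely at random, and pooled-QC injections are drawn around
#' the pooled mean with the stated coefficient of variation.
#'
#' @param spec A [simulation_spec()].
#' @return A list of class `twin_sim` with elements
#'   \describe{
#'     \item{cohort}{tibble, one row per child (ids, zygosity, birth order,
#'       sex, age, collection flags, creatinine).}
#'     \item{metabolites}{long tibble: `sample_id`, `metabolite_id`,
#'       `platform`, `value` (NA when censored or missing), `below_lod`,
#'       `missing`, `lod` (NA when unknown).}
#'     \item{qc}{tibble of ordered pooled-QC injections per metabolite.}
#'     \item{truth}{ground truth recorded before censoring/missingness:
#'       `var_fracs`, `betas`, per-child latent and raw values, LODs.}
#'   }
#' @export
#' @examples
#' sim <- simulate_cohort(simulation_spec(
#'   n_mz_pairs = 30, n_dz_pairs = 20,
#'   n_mz_singletons = 0, n_dz_singletons = 0,
#'   var_fracs = default_var_fracs(c(amine = 3, organic_acid = 1, steroid = 1)),
#'   seed = 7
#' ))
#' dplyr::count(sim$metabolites, platform)
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  fam <- simulate_families(spec)
  cohort <- fam$cohort
  n_child <- nrow(cohort)
  vf <- spec$var_fracs
  n_met <- nrow(vf)

  # latent matrix: children x metabolites
  latent <- matrix(NA_real_, n_child, n_met,
                   dimnames = list(cohort$child_id, vf$metabolite_id))
  for (j in seq_len(n_met)) {
    latent[, j] <- draw_latent(
      fam, vf$A[j], vf$C[j], vf$D[j], vf$E[j],
      spec$beta_sex, spec$beta_age
    )
  }

  raw <- exp(spec$raw_scale * latent) * cohort$creatinine

  # limit-of-detection censoring on the measured (raw) scale
  lod_known <- runif(n_met) < spec$lod_known_fraction
  lod <- rep(NA_real_, n_met)
  below <- matrix(FALSE, n_child, n_met)
  if (spec$lod_quantile > 0) {
    lod <- apply(raw, 2, quantile, probs = spec$lod_quantile, names = FALSE)
    below <- sweep(raw, 2, lod, "<")
  }

  miss <- matrix(runif(n_child * n_met) < spec$missing_rate, n_child, n_met)

  value <- raw
  value[below | miss] <- NA_real_

  metabolites <- tibble::tibble(
    sample_id = rep(cohort$child_id, times = n_met),
    metabolite_id = rep(vf$metabolite_id, each = n_child),
    platform = rep(vf$platform, each = n_child),
    value = as.vector(value),
    below_lod = as.vector(below & !miss),
    missing = as.vector(miss),
    lod = rep(ifelse(lod_known, lod, NA_real_), each = n_child)
  )

  # pooled-QC injections: one every qc_interval samples plus a lead-in
  n_qc <- max(2L, floor(n_child / spec$qc_interval) + 1L)
  cv <- rep_len(spec$qc_cv_percent, n_met)
  pool_mean <- colMeans(raw)
  qc <- tibble::tibble(
    metabolite_id = rep(vf$metabolite_id, each = n_qc),
    injection = rep(seq_len(n_qc), times = n_met),
    value = rnorm(
      n_qc * n_met,
      mean = rep(pool_mean, each = n_qc),
      sd = rep(pool_mean * cv / 100, each = n_qc)
    )
  )

  truth <- list(
    var_fracs = vf,
    betas = c(sex = spec$beta_sex, age = spec$beta_age),
    latent = tibble::tibble(
      sample_id = rep(cohort$child_id, times = n_met),
      metabolite_id = rep(vf$metabolite_id, each = n_child),
      latent = as.vector(latent),
      raw = as.vector(raw)
    ),
    lod = tibble::tibble(
      metabolite_id = vf$metabolite_id,
      lod = lod, lod_known = lod_known
    )
  )

  structure(
    list(cohort = cohort, metabolites = metabolites, qc = qc, truth = truth),
    class = "twin_sim"
  )
}

# family scaffolding: ids, zygosity, sex, age, creatinine, clean flags
simulate_families <- function(spec) {
  n_fam <- spec$n_mz_pairs + spec$n_dz_pairs +
    spec$n_mz_singletons + spec$n_dz_singletons
  zyg <- rep(
    c("MZ", "DZ", "MZ", "DZ"),
    times = c(spec$n_mz_pairs, spec$n_dz_pairs,
              spec$n_mz_singletons, spec$n_dz_singletons)
  )
  singleton <- rep(
    c(FALSE, TRUE),
    times = c(spec$n_mz_pairs + spec$n_dz_pairs,
              spec$n_mz_singletons + spec$n_dz_singletons)
  )
  family_id <- sprintf("F%04d", seq_len(n_fam))
  age <- runif(n_fam, spec$age_range[1], spec$age_range[2])

  sex1 <- runif(n_fam) < spec$prop_female
  sex2 <- ifelse(zyg == "MZ", sex1, runif(n_fam) < spec$prop_female)

  fam <- tibble::tibble(
    family_id = family_id, zygosity = zyg, singleton = singleton,
    age = age, sex1 = sex1, sex2 = as.logical(sex2)
  )

  child <- tidyr::pivot_longer(
    dplyr::mutate(fam, `1` = sex1, `2` = sex2),
    cols = c("1", "2"), names_to = "birth_order", values_to = "female"
  )
  child$birth_order <- as.integer(child$birth_order)
  child <- child[!(child$singleton & child$birth_order == 2L), ]

  mu <- spec$creatinine_lognormal[["mu"]]
  sig <- spec$creatinine_lognormal[["sigma"]]
  cohort <- tibble::tibble(
    child_id = paste0(child$family_id, "_", child$birth_order),
    family_id = child$family_id,
    cohort = "discovery",
    zygosity = child$zygosity,
    birth_order = child$birth_order,
    sex = ifelse(child$female, "female", "male"),
    age = child$age,
    first_morning = TRUE,
    freeze_delay = 0,
    urine_sufficient = TRUE,
    second_multiple = FALSE,
    duplicate_of_other_cohort = FALSE,
    creatinine = rlnorm(nrow(child), mu, sig)
  )
  list(cohort = cohort, fam = fam)
}

# one metabolite's latent values for every child in the cohort
draw_latent <- function(fam_env, A, C, D, E, beta_sex, beta_age) {
  fam <- fam_env$fam
  cohort <- fam_env$cohort
  n_fam <- nrow(fam)
  mz <- fam$zygosity == "MZ"

  # correlated component draws at family level (unit marginals)
  a1 <- rnorm(n_fam)
  a_extra <- rnorm(n_fam)
  r_a <- ifelse(mz, 1, 0.5)
  a2 <- r_a * a1 + sqrt(1 - r_a^2) * a_extra

  d1 <- rnorm(n_fam)
  d_extra <- rnorm(n_fam)
  r_d <- ifelse(mz, 1, 0.25)
  d2 <- r_d * d1 + sqrt(1 - r_d^2) * d_extra

  c_shared <- rnorm(n_fam)
  e1 <- rnorm(n_fam)
  e2 <- rnorm(n_fam)

  g1 <- sqrt(A) * a1 + sqrt(D) * d1 + sqrt(C) * c_shared + sqrt(E) * e1
  g2 <- sqrt(A) * a2 + sqrt(D) * d2 + sqrt(C) * c_shared + sqrt(E) * e2

  idx <- match(cohort$family_id, fam$family_id)
  gen <- ifelse(cohort$birth_order == 1L, g1[idx], g2[idx])
  beta_sex * (cohort$sex == "female") + beta_age * cohort$age + gen
}

#' Reconstruct the pre-masking metabolite matrix from ground truth
#'
#' Replaces censored and missing entries of a simulated metabolite table
#' with the true raw values recorded in the ground truth, undoing the
#' masking layers of [simulate_cohort()].
#'
#' @param metabolites `metabolites` tibble from a `twin_sim`.
#' @param truth `truth` element of the same `twin_sim`.
#' @return The metabolite tibble with `value` fully observed.
#' @export
unmask_from_truth <- function(metabolites, truth) {
  key <- paste(metabolites$sample_id, metabolites$metabolite_id)
  tkey <- paste(truth$latent$sample_id, truth$latent$metabolite_id)
  raw <- truth$latent$raw[match(key, tkey)]
  out <- metabolites
  masked <- out$below_lod | out$missing
  out$value[masked] <- raw[masked]
  out$below_lod <- FALSE
  out$missing <- FALSE
  out
}
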