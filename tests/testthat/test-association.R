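test_that("with singleton clusters the mixed model reduces to OLS", {
  set.seed(41)
  d <- data.frame(y = rnorm(80), x = rnorm(80), fam = sprintf("f%02d", 1:80))
  fit <- fit_family_lmm(d, "y", "x", "fam")
  ols <- lm(y ~ x, data = d)
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-6)
})

test_that("mixed-model estimates agree with an independent ML fit (nlme)", {
  skip_if_not_installed("nlme")
  paired <- simulate_paired(150, 150, A = 0.5, C = 0, D = 0, E = 0.5,
                            seed = 42, beta_sex = 0.2, beta_age = 0.05)
  d <- tidyr::pivot_longer(paired, c("y1", "y2"), values_to = "y")
  d$sex <- ifelse(d$name == "y1", paired$sex1[match(d$family_id, paired$family_id)],
                  paired$sex2[match(d$family_id, paired$family_id)])
  d <- as.data.frame(d)
  mine <- fit_family_lmm(d, "y", c("sex", "age"), "family_id")
  ref <- nlme::lme(y ~ sex + age, random = ~ 1 | family_id, data = d,
                   method = "ML")
  expect_equal(unname(mine$coefficients), unname(nlme::fixef(ref)),
               tolerance = 1e-5)
  expect_equal(mine$logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
  expect_equal(mine$sigma2, ref$sigma^2, tolerance = 1e-3)
})

test_that("mixed model recovers a generating age effect within 3 SE", {
  set.seed(43)
  n_fam <- 600
  age <- runif(n_fam, 6, 13)
  u <- rnorm(n_fam, sd = sqrt(0.3))
  d <- data.frame(
    fam = rep(seq_len(n_fam), each = 2),
    age = rep(age, each = 2),
    y = 0.3 * rep(age, each = 2) + rep(u, each = 2) +
      rnorm(2 * n_fam, sd = sqrt(0.7))
  )
  fit <- fit_family_lmm(d, "y", "age", "fam")
  est <- fit$coefficients[["age"]]
  se <- fit$se[["age"]]
  expect_lt(abs(est - 0.3), 3 * se)
  expect_lt(abs(fit$tau2 - 0.3), 0.15)
  expect_lt(abs(fit$sigma2 - 0.7), 0.15)
})

test_that("duplicated responses within clusters drive the residual variance to zero", {
  set.seed(44)
  m <- rnorm(50)
  d <- data.frame(y = rep(m, each = 2), fam = rep(1:50, each = 2))
  fit <- fit_family_lmm(d, "y", character(0), "fam")
  expect_equal(unname(fit$coefficients[1]), mean(m), tolerance = 1e-6)
  icc <- fit$tau2 / (fit$tau2 + fit$sigma2)
  expect_gt(icc, 0.97)
  expect_lt(fit$sigma2, 0.05 * var(m))
})

test_that("ML mixed-model log-likelihood is at least the OLS log-likelihood", {
  set.seed(45)
  for (i in 1:5) {
    d <- data.frame(
      y = rnorm(60) + rep(rnorm(30), each = 2),
      x = rnorm(60),
      fam = rep(1:30, each = 2)
    )
    fit <- fit_family_lmm(d, "y", "x", "fam")
    ols <- lm(y ~ x, data = d)
    expect_gte(fit$logLik + 1e-8, as.numeric(logLik(ols)))
  }
})

test_that("step-up q-values equal the brute-force oracle exhaustively", {
  grid <- c(0.001, 0.04, 0.3, 1)
  for (len in 1:6) {
    combos <- do.call(expand.grid, rep(list(grid), len))
    for (i in seq_len(nrow(combos))) {
      p <- as.numeric(combos[i, ])
      expect_equal(bh_fdr(p), bh_brute(p), tolerance = 1e-12)
    }
  }
  # analysis-wide m larger than the available p-values
  p <- c(0.01, 0.02, 0.5)
  expect_equal(bh_fdr(p, m = 6), bh_brute(p, m = 6))
})

test_that("q-values handle the worked example, singletons and ties", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.5)), c(0.03, 0.03, 0.5))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.1, 0.2), m = 1), "at least")
})

test_that("age dichotomization sends the boundary to the older group", {
  expect_equal(dichotomize_age(c(9.99, 10, 12.9, 5.7)), c(0L, 1L, 1L, 0L))
})

test_that("association scan finds simulated age effects with high power and few false hits", {
  n_true <- 8
  n_null <- 18
  vf <- default_var_fracs(c(amine = n_true + n_null, organic_acid = 0,
                            steroid = 0))
  vf$A <- 0.5; vf$C <- 0; vf$D <- 0; vf$E <- 0.5
  sim_true <- simulate_cohort(simulation_spec(
    n_mz_pairs = 531, n_dz_pairs = 114, n_mz_singletons = 0,
    n_dz_singletons = 0, var_fracs = vf[seq_len(n_true), ],
    beta_age = 0.12, lod_quantile = 0, missing_rate = 0, seed = 46
  ))
  sim_null <- simulate_cohort(simulation_spec(
    n_mz_pairs = 531, n_dz_pairs = 114, n_mz_singletons = 0,
    n_dz_singletons = 0, var_fracs = vf[-seq_len(n_true), ],
    beta_age = 0, lod_quantile = 0, missing_rate = 0, seed = 47
  ))
  processed <- dplyr::bind_rows(latent_processed(sim_true),
                                latent_processed(sim_null))
  scan <- run_association_scan(processed, sim_true$cohort,
                               "sex_age_continuous")
  age_hits <- scan$metabolite_id[scan$term == "age" & scan$significant]
  true_ids <- unique(latent_processed(sim_true)$metabolite_id)
  expect_gte(length(intersect(age_hits, true_ids)), 0.8 * n_true)
  expect_lte(length(setdiff(age_hits, true_ids)), 2)
})

test_that("sex-stratified age effects agree when simulated equal across sexes", {
  vf <- tibble::tibble(metabolite_id = "m1", platform = "amine",
                       A = 0.5, C = 0, D = 0, E = 0.5)
  sim <- simulate_cohort(simulation_spec(
    n_mz_pairs = 400, n_dz_pairs = 245, n_mz_singletons = 0,
    n_dz_singletons = 0, var_fracs = vf, beta_age = 0.1,
    lod_quantile = 0, missing_rate = 0, seed = 48
  ))
  processed <- latent_processed(sim)
  males <- run_association_scan(processed, sim$cohort, "age_in_males")
  females <- run_association_scan(processed, sim$cohort, "age_in_females")
  diff <- males$estimate - females$estimate
  joint_se <- sqrt(males$std.error^2 + females$std.error^2)
  expect_lt(abs(diff), 3 * joint_se)
})

test_that("small strata are refused", {
  vf <- tibble::tibble(metabolite_id = "m1", platform = "amine",
                       A = 0, C = 0, D = 0, E = 1)
  sim <- simulate_cohort(simulation_spec(
    n_mz_pairs = 8, n_dz_pairs = 4, n_mz_singletons = 0,
    n_dz_singletons = 0, var_fracs = vf, lod_quantile = 0,
    missing_rate = 0, seed = 49
  ))
  expect_error(
    run_association_scan(latent_processed(sim), sim$cohort, "sex_in_older"),
    "refused"
  )
})

test_that("replication concordance: identical tables replicate fully, noise preserves signs", {
  vf <- default_var_fracs(c(amine = 6, organic_acid = 0, steroid = 0))
  vf$A <- 0.4; vf$C <- 0; vf$D <- 0; vf$E <- 0.6
  sim <- simulate_cohort(simulation_spec(
    n_mz_pairs = 300, n_dz_pairs = 100, n_mz_singletons = 0,
    n_dz_singletons = 0, var_fracs = vf, beta_age = 0.15,
    lod_quantile = 0, missing_rate = 0, seed = 50
  ))
  scan <- run_association_scan(latent_processed(sim), sim$cohort,
                               "sex_age_continuous")
  conc <- replication_concordance(scan, scan)
  age_row <- conc$summary[conc$summary$term == "age", ]
  expect_equal(age_row$beta_correlation, 1)
  expect_equal(age_row$n_replicated, age_row$n_discovery_significant)
  # replicated set is a subset of the discovery-significant set
  expect_true(all(
    conc$replicated$metabolite_id %in%
      scan$metabolite_id[scan$significant]
  ))
  expect_error(
    replication_concordance(scan, dplyr::mutate(scan, metabolite_id = "zz")),
    "no shared"
  )
})
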