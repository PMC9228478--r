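test_that("pair_data lays out families, keeps singletons, rejects extra twins", {
  sim <- simulate_cohort(simulation_spec(
    n_mz_pairs = 20, n_dz_pairs = 10, n_mz_singletons = 3,
    n_dz_singletons = 2,
    var_fracs = tibble::tibble(metabolite_id = "m1", platform = "amine",
                               A = 0.5, C = 0, D = 0, E = 0.5),
    lod_quantile = 0, missing_rate = 0, seed = 61
  ))
  paired <- pair_data(latent_processed(sim), sim$cohort)
  expect_equal(nrow(paired), 35L)
  expect_equal(sum(is.na(paired$y2)), 5L)   # singleton families
  expect_true(all(!is.na(paired$y1) | !is.na(paired$y2)))

  bad_cohort <- dplyr::bind_rows(
    sim$cohort,
    dplyr::mutate(sim$cohort[1, ], child_id = "extra", birth_order = 1L)
  )
  expect_error(pair_data(latent_processed(sim), bad_cohort), "more than 2")
})

test_that("saturated FIML matches a grid-search oracle on complete balanced data", {
  set.seed(62)
  paired <- exact_moment_pairs(60, 40, 0.55, 0.25)
  fit <- fit_saturated(paired, "none")

  # independent oracle: profile the ML intraclass correlation of the MZ group
  # by grid search over (mu, sigma2, cov), equal means/variances within pair
  mz <- paired[paired$zygosity == "MZ", ]
  grid_ll <- function(mu, s2, cv) {
    det <- s2^2 - cv^2
    e1 <- mz$y1 - mu
    e2 <- mz$y2 - mu
    q <- (s2 * e1^2 - 2 * cv * e1 * e2 + s2 * e2^2) / det
    sum(-log(2 * pi) - 0.5 * log(det) - 0.5 * q)
  }
  r_grid <- seq(0.3, 0.8, by = 1e-4)
  # at exact moments the ML mean is 0 and variance 1 by construction
  ll <- vapply(r_grid, function(r) grid_ll(0, 1, r), numeric(1))
  r_oracle <- r_grid[which.max(ll)]
  expect_equal(fit$r_mz, r_oracle, tolerance = 1e-4)
})

test_that("saturated fit recovers generating twin correlations at realistic sizes", {
  paired <- simulate_paired(531, 114, A = 0.22, C = 0, D = 0.39, E = 0.39,
                            seed = 63)
  # truth: r_MZ = A + D = 0.61, r_DZ = A/2 + D/4 = 0.2075
  fit <- fit_saturated(paired, "none")
  se_rmz <- (1 - 0.61^2) / sqrt(531)
  se_rdz <- (1 - 0.21^2) / sqrt(114)
  expect_lt(abs(fit$r_mz - 0.61), 3 * se_rmz)
  expect_lt(abs(fit$r_dz - 0.2075), 3 * se_rdz)
})

test_that("likelihood is invariant to within-pair order swap", {
  paired <- simulate_paired(50, 30, A = 0.4, C = 0.1, D = 0, E = 0.5,
                            seed = 64, beta_sex = 0.3)
  swapped <- paired
  swapped$y1 <- paired$y2
  swapped$y2 <- paired$y1
  swapped$sex1 <- paired$sex2
  swapped$sex2 <- paired$sex1
  f1 <- fit_saturated(paired, "sex")
  f2 <- fit_saturated(swapped, "sex")
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
  expect_equal(f1$r_mz, f2$r_mz, tolerance = 1e-4)
})

test_that("unidentifiable covariance (no complete pairs in a group) is refused", {
  paired <- simulate_paired(20, 20, A = 0.5, C = 0, D = 0, E = 0.5, seed = 65)
  paired$y2[paired$zygosity == "DZ"] <- NA
  expect_error(fit_saturated(paired, "none"), "not identifiable")
})

test_that("deleting a singleton changes the log-likelihood by its univariate density", {
  paired <- simulate_paired(30, 20, A = 0.5, C = 0, D = 0, E = 0.5, seed = 66)
  paired$y2[1] <- NA    # make one MZ family a singleton
  fit <- fit_saturated(paired, "none")
  ll_at <- function(dat) {
    twinmetab:::fiml_loglik(
      dat$y1, dat$y2,
      rep(fit$coefficients[["intercept"]], nrow(dat)),
      rep(fit$coefficients[["intercept"]], nrow(dat)),
      dat$zygosity == "MZ", fit$sigma2, fit$cov_mz, fit$cov_dz
    )
  }
  delta <- ll_at(paired) - ll_at(paired[-1, ])
  expected <- dnorm(paired$y1[1], fit$coefficients[["intercept"]],
                    sqrt(fit$sigma2), log = TRUE)
  expect_equal(delta, expected, tolerance = 1e-10)
})

test_that("covariate selection retains a real age effect and drops a null sex effect", {
  n_keep <- 0
  reps <- 20
  for (i in seq_len(reps)) {
    paired <- simulate_paired(531, 114, A = 0.5, C = 0.1, D = 0, E = 0.4,
                              seed = 600 + i, beta_age = 0.1, beta_sex = 0)
    sel <- select_covariates(paired)
    n_keep <- n_keep + (sel$covariate_set == "age")
    # nesting: removing a covariate never increases the log-likelihood
    ll <- vapply(sel$fits, function(f) f$logLik, numeric(1))
    expect_gte(ll[["sex+age"]] + 1e-6, ll[["sex"]])
    expect_gte(ll[["sex+age"]] + 1e-6, ll[["age"]])
    expect_gte(ll[["age"]] + 1e-6, ll[["none"]])
  }
  expect_gte(n_keep / reps, 0.85)
})

test_that("the correlation rule picks ADE above twice the DZ correlation, ACE otherwise", {
  expect_equal(choose_model(0.61, 0.25), "ADE")
  expect_equal(choose_model(0.50, 0.25), "ACE")   # tie goes to ACE
  expect_equal(choose_model(0.40, 0.30), "ACE")
  expect_equal(choose_model(c(0.8, 0.2), c(0.1, 0.15)), c("ADE", "ACE"))
})

test_that("FIML ADE/ACE estimates equal the closed-form moment solutions", {
  set.seed(67)
  paired <- exact_moment_pairs(400, 400, 0.6, 0.2)
  ade <- fit_ace_ade(paired, "ADE", "none")
  # closed form: A = 4 cov_DZ - cov_MZ, D = 2 cov_MZ - 4 cov_DZ, E = V - cov_MZ
  expect_lt(abs(ade$A - 0.2), 1e-4)
  expect_lt(abs(unname(ade$D_or_C) - 0.4), 1e-4)
  expect_lt(abs(ade$E - 0.4), 1e-4)
  expect_lt(abs(ade$h2 - 0.6), 1e-4)
  expect_equal(ade$h2_type, "broad")

  paired2 <- exact_moment_pairs(400, 400, 0.5, 0.3)
  ace <- fit_ace_ade(paired2, "ACE", "none")
  # closed form: A = 2 (cov_MZ - cov_DZ), C = 2 cov_DZ - cov_MZ
  expect_lt(abs(ace$A - 0.4), 1e-4)
  expect_lt(abs(unname(ace$D_or_C) - 0.1), 1e-4)
  expect_lt(abs(ace$E - 0.5), 1e-4)
  expect_lt(abs(ace$h2 - 0.4), 1e-4)
  expect_equal(ace$h2_type, "narrow")

  # no familial resemblance: everything loads on E
  paired3 <- exact_moment_pairs(400, 400, 0, 0)
  for (model in c("ADE", "ACE")) {
    fit0 <- fit_ace_ade(paired3, model, "none")
    expect_lt(abs(fit0$A), 1e-4)
    expect_lt(abs(unname(fit0$D_or_C)), 1e-4)
    expect_lt(abs(fit0$E - fit0$V), 1e-4)
  }
})

test_that("negative components are allowed when r_MZ exceeds four times r_DZ", {
  set.seed(68)
  paired <- exact_moment_pairs(400, 400, 0.6, 0.1)
  ade <- fit_ace_ade(paired, "ADE", "none")
  expect_lt(abs(ade$A - (4 * 0.1 - 0.6)), 1e-4)   # A = -0.2
  expect_lt(ade$A, 0)
  expect_lt(abs(ade$h2 - 0.6), 1e-4)              # h2 still tracks r_MZ
})

test_that("ADE broad-sense h2 equals the fitted MZ correlation on complete data", {
  set.seed(69)
  paired <- exact_moment_pairs(300, 200, 0.58, 0.21)
  sat <- fit_saturated(paired, "none")
  ade <- fit_ace_ade(paired, "ADE", "none")
  expect_equal(ade$h2, sat$r_mz, tolerance = 1e-4)
  # nesting: the 3-moment ADE model saturates the 3 free moments
  expect_lte(ade$logLik, sat$logLik + 1e-6)
  expect_equal(ade$logLik, sat$logLik, tolerance = 1e-6)
})

test_that("variance-component model log-likelihood never exceeds the saturated one", {
  paired <- simulate_paired(200, 80, A = 0.5, C = 0.1, D = 0, E = 0.4,
                            seed = 70)
  sat <- fit_saturated(paired, "none")
  for (model in c("ADE", "ACE")) {
    vc <- fit_ace_ade(paired, model, "none")
    expect_lte(vc$logLik, sat$logLik + 1e-6)
  }
})

test_that("profile intervals contain the estimate and shrink with sample size", {
  paired_small <- simulate_paired(250, 100, A = 0.5, C = 0.1, D = 0, E = 0.4,
                                  seed = 71)
  paired_big <- simulate_paired(2500, 1000, A = 0.5, C = 0.1, D = 0, E = 0.4,
                                seed = 72)
  ci_small <- profile_ci(fit_ace_ade(paired_small, "ACE", "none"), "a2")
  ci_big <- profile_ci(fit_ace_ade(paired_big, "ACE", "none"), "a2")
  est_small <- attr(ci_small, "estimate")
  expect_gt(est_small, ci_small[["lower"]])
  expect_lt(est_small, ci_small[["upper"]])
  width_small <- ci_small[["upper"]] - ci_small[["lower"]]
  width_big <- ci_big[["upper"]] - ci_big[["lower"]]
  expect_lt(width_big, width_small)
})

test_that("twin pipeline recovers the generating model regime per metabolite", {
  vf <- dplyr::bind_rows(
    tibble::tibble(metabolite_id = sprintf("am_%02d", 1:6), platform = "amine",
                   A = 0.2, C = 0, D = 0.4, E = 0.4),       # r_MZ=.6, r_DZ=.2
    tibble::tibble(metabolite_id = sprintf("st_%02d", 1:2), platform = "steroid",
                   A = 0.4, C = 0.3, D = 0, E = 0.3)        # r_MZ=.7, r_DZ=.5
  )
  sim <- simulate_cohort(simulation_spec(
    n_mz_pairs = 1000, n_dz_pairs = 1000, n_mz_singletons = 0,
    n_dz_singletons = 0, var_fracs = vf, lod_quantile = 0,
    missing_rate = 0, seed = 73
  ))
  res <- run_twin_pipeline(latent_processed(sim), sim$cohort)
  expect_equal(nrow(res), 8L)
  expect_equal(sum(res$model == "ADE"), 6L)
  expect_true(all(res$model[res$platform == "steroid"] == "ACE"))
  expect_true(all(res$loglik_model <= res$loglik_sat + 1e-6))
  # a metabolite with no complete pairs is skipped with a warning, not fatal
  processed_bad <- latent_processed(sim)
  second_twin <- grepl("_2$", processed_bad$sample_id)
  processed_bad$value[processed_bad$metabolite_id == "am_01" & second_twin] <-
    NA
  expect_warning(
    res2 <- run_twin_pipeline(processed_bad, sim$cohort),
    "skipped"
  )
  expect_equal(nrow(res2), 7L)
})
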