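# shared fixtures, all built in code at test time

# processed-style tibble from a simulation's true latent values (skips the
# preprocessing stack when a test targets the modelling layers directly)
latent_processed <- function(sim) {
  plat <- dplyr::distinct(sim$metabolites, metabolite_id, platform)
  out <- dplyr::left_join(sim$truth$latent, plat, by = "metabolite_id")
  tibble::tibble(
    sample_id = out$sample_id,
    metabolite_id = out$metabolite_id,
    platform = out$platform,
    value = out$latent
  )
}

# single-metabolite twin simulation reduced to a paired layout on the latent
# scale; nuisance layers off
simulate_paired <- function(n_mz, n_dz, A, C, D, E, seed,
                            beta_sex = 0, beta_age = 0) {
  vf <- tibble::tibble(
    metabolite_id = "m1", platform = "amine", A = A, C = C, D = D, E = E
  )
  sim <- simulate_cohort(simulation_spec(
    n_mz_pairs = n_mz, n_dz_pairs = n_dz,
    n_mz_singletons = 0, n_dz_singletons = 0,
    var_fracs = vf, beta_sex = beta_sex, beta_age = beta_age,
    lod_quantile = 0, missing_rate = 0, seed = seed
  ))
  pair_data(latent_processed(sim), sim$cohort)
}

# complete balanced pairs whose ML moments are EXACT by construction:
# per zygosity group, column means are 0 and crossprod(Y)/n equals the
# target covariance matrix, so the saturated/variance-component FIML
# estimates can be compared to closed-form moment solutions
exact_moment_pairs <- function(n_mz, n_dz, r_mz, r_dz, v = 1) {
  make <- function(n, r, zyg) {
    x <- matrix(rnorm(2 * n), n, 2)
    x <- scale(x, center = TRUE, scale = FALSE)
    s <- crossprod(x) / n
    e <- eigen(s)
    x <- x %*% (e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors))
    y <- x %*% chol(matrix(c(v, r * v, r * v, v), 2))
    tibble::tibble(
      metabolite_id = "m", family_id = paste0(zyg, seq_len(n)),
      zygosity = zyg, age = 9, sex1 = 0L, sex2 = 0L,
      y1 = y[, 1], y2 = y[, 2]
    )
  }
  dplyr::bind_rows(make(n_mz, r_mz, "MZ"), make(n_dz, r_dz, "DZ"))
}

# independent brute-force step-up FDR oracle
bh_brute <- function(p, m = length(p)) {
  n <- length(p)
  o <- order(p)
  qs <- rev(cummin(rev(m * p[o] / seq_len(n))))
  pmin(1, qs)[order(o)]
}
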