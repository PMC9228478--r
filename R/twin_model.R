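#' Arrange processed metabolite values as one row per twin family
#'
#' Joins processed values with the cohort table and lays each family out as
#' a (possibly incomplete) twin pair: co-twin values `y1`/`y2` by birth
#' order, zygosity, per-twin sex and the shared age. Families where only
#' one twin contributes a value are retained as singletons — the
#' full-information likelihood uses their univariate density.
#'
#' @param processed Long tibble (`sample_id`, `metabolite_id`, `value`).
#' @param cohort Cohort tibble restricted to twins with known zygosity.
#' @return Tibble with columns `metabolite_id`, `family_id`, `zygosity`,
#'   `age`, `sex1`, `sex2`, `y1`, `y2` (sex coded 0 = male, 1 = female).
#' @export
pair_data <- function(processed, cohort) {
  twins <- cohort[!is.na(cohort$zygosity) &
                    cohort$zygosity %in% c("MZ", "DZ"), ]
  n_per_fam <- table(twins$family_id)
  if (any(n_per_fam > 2)) {
    abort(paste(
      "families with more than 2 twins present (second multiples must be",
      "excluded first):",
      paste(names(n_per_fam)[n_per_fam > 2], collapse = ", ")
    ))
  }
  dat <- dplyr::inner_join(processed, twins, by = c(sample_id = "child_id"))
  dat$sex01 <- as.integer(dat$sex == "female")
  wide <- tidyr::pivot_wider(
    dplyr::select(dat, "metabolite_id", "family_id", "zygosity",
                  "birth_order", "age", "sex01", "value"),
    names_from = "birth_order",
    values_from = c("value", "sex01", "age"),
    names_sep = ""
  )
  for (col in c("value1", "value2", "sex011", "sex012", "age1", "age2")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  out <- tibble::tibble(
    metabolite_id = wide$metabolite_id,
    family_id = wide$family_id,
    zygosity = wide$zygosity,
    age = dplyr::coalesce(wide$age1, wide$age2),
    sex1 = wide$sex011,
    sex2 = wide$sex012,
    y1 = wide$value1,
    y2 = wide$value2
  )
  out[!(is.na(out$y1) & is.na(out$y2)), ]
}

# ---- internal FIML machinery ------------------------------------------------

# design matrices for the per-twin mean model
mean_design <- function(paired, covariate_set) {
  covs <- covariate_terms(covariate_set)
  X1 <- cbind(intercept = rep(1, nrow(paired)))
  X2 <- X1
  if ("sex" %in% covs) {
    X1 <- cbind(X1, sex = paired$sex1)
    X2 <- cbind(X2, sex = paired$sex2)
  }
  if ("age" %in% covs) {
    X1 <- cbind(X1, age = paired$age)
    X2 <- cbind(X2, age = paired$age)
  }
  list(X1 = X1, X2 = X2)
}

covariate_terms <- function(covariate_set) {
  set <- match.arg(covariate_set, c("none", "sex", "age", "sex+age"))
  switch(set, none = character(0), sex = "sex", age = "age",
         `sex+age` = c("sex", "age"))
}

# raw-data log-likelihood: each family contributes the normal log-density of
# its observed sub-vector; covariance [[V, cov_z], [cov_z, V]] by zygosity
fiml_loglik <- function(y1, y2, mu1, mu2, mz, V, cov_mz, cov_dz) {
  if (!is.finite(V) || V <= 0) return(-Inf)
  cc <- ifelse(mz, cov_mz, cov_dz)
  e1 <- y1 - mu1
  e2 <- y2 - mu2
  both <- !is.na(y1) & !is.na(y2)
  ll <- 0
  if (any(both)) {
    cb <- cc[both]
    det <- V^2 - cb^2
    if (any(det <= 0)) return(-Inf)
    q <- (V * e1[both]^2 - 2 * cb * e1[both] * e2[both] + V * e2[both]^2) / det
    ll <- ll + sum(-log(2 * pi) - 0.5 * log(det) - 0.5 * q)
  }
  es <- c(e1[!is.na(y1) & is.na(y2)], e2[is.na(y1) & !is.na(y2)])
  if (length(es)) {
    ll <- ll + sum(-0.5 * log(2 * pi * V) - es^2 / (2 * V))
  }
  ll
}

# minimize with jittered restarts on failure
fiml_optimize <- function(obj, start, n_restarts = 3, jitter_sd = 0.3) {
  best <- NULL
  try_fit <- function(par) {
    tryCatch(nlminb(par, obj, control = list(rel.tol = 1e-10, iter.max = 500)),
             error = function(e) NULL)
  }
  fit <- try_fit(start)
  ok <- function(f) {
    !is.null(f) && is.finite(f$objective) && f$convergence == 0
  }
  if (ok(fit)) best <- fit
  i <- 0
  while (is.null(best) && i < n_restarts) {
    i <- i + 1
    fit <- try_fit(start + rnorm(length(start), sd = jitter_sd))
    if (ok(fit)) best <- fit
  }
  if (is.null(best)) {
    abort(paste(
      "twin-model optimizer failed to converge after restarts;",
      "last message:", if (!is.null(fit)) fit$message else "no fit"
    ))
  }
  best
}

one_metabolite <- function(paired) {
  if ("metabolite_id" %in% names(paired) &&
        length(unique(paired$metabolite_id)) > 1L) {
    abort("`paired` holds several metabolites; fit one at a time")
  }
  paired
}

# moment-based starting values on residualized data
pair_moments <- function(paired, covariate_set) {
  des <- mean_design(paired, covariate_set)
  long_y <- c(paired$y1, paired$y2)
  long_X <- rbind(des$X1, des$X2)
  obs <- !is.na(long_y)
  beta <- unname(coef(lm.fit(long_X[obs, , drop = FALSE], long_y[obs])))
  r1 <- paired$y1 - drop(des$X1 %*% beta)
  r2 <- paired$y2 - drop(des$X2 %*% beta)
  v <- var(c(r1, r2), na.rm = TRUE)
  safe_cov <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2) return(0)
    cov(a[ok], b[ok])
  }
  mz <- paired$zygosity == "MZ"
  list(
    beta = beta, v = v,
    cov_mz = safe_cov(r1[mz], r2[mz]),
    cov_dz = safe_cov(r1[!mz], r2[!mz])
  )
}

#' Fit the saturated two-group twin model by full-information ML
#'
#' Maximizes the raw-data likelihood of a two-group (MZ + DZ) model with
#' means and variances equated across birth order and zygosity: each twin's
#' mean is `intercept + beta * covariates`, the common variance is
#' `sigma2`, and each zygosity group has its own within-pair covariance.
#' Incomplete pairs contribute their univariate density. The derived
#' MZ/DZ correlations are the ML twin correlations.
#'
#' The covariance is kept feasible by parameterizing `sigma2` on the log
#' scale and each correlation through `tanh`.
#'
#' @param paired Output of [pair_data()] for a single metabolite.
#' @param covariate_set `"none"`, `"sex"`, `"age"` or `"sex+age"`.
#' @param min_pairs Minimum complete pairs required per zygosity group.
#' @return Object of class `saturated_fit`: mean coefficients, `sigma2`,
#'   `cov_mz`, `cov_dz`, `r_mz`, `r_dz`, `logLik`, `covariate_set`, counts.
#' @export
fit_saturated <- function(paired, covariate_set = "sex+age", min_pairs = 5) {
  paired <- one_metabolite(paired)
  mz <- paired$zygosity == "MZ"
  complete <- !is.na(paired$y1) & !is.na(paired$y2)
  n_cmz <- sum(complete & mz)
  n_cdz <- sum(complete & !mz)
  if (n_cmz < min_pairs || n_cdz < min_pairs) {
    abort(sprintf(
      paste("within-pair covariance not identifiable: need >= %d complete",
            "pairs per zygosity (have %d MZ, %d DZ)"),
      min_pairs, n_cmz, n_cdz
    ))
  }
  des <- mean_design(paired, covariate_set)
  p <- ncol(des$X1)
  mom <- pair_moments(paired, covariate_set)
  clamp <- function(r) max(min(r, 0.95), -0.95)
  start <- c(mom$beta, log(mom$v),
             atanh(clamp(mom$cov_mz / mom$v)),
             atanh(clamp(mom$cov_dz / mom$v)))

  obj <- function(par) {
    beta <- par[seq_len(p)]
    v <- exp(par[p + 1])
    r_mz <- tanh(par[p + 2])
    r_dz <- tanh(par[p + 3])
    ll <- fiml_loglik(
      paired$y1, paired$y2,
      drop(des$X1 %*% beta), drop(des$X2 %*% beta),
      mz, v, r_mz * v, r_dz * v
    )
    if (!is.finite(ll)) 1e10 else -ll
  }
  fit <- fiml_optimize(obj, start)
  par <- fit$par
  beta <- setNames(par[seq_len(p)], colnames(des$X1))
  v <- exp(par[p + 1])
  r_mz <- tanh(par[p + 2])
  r_dz <- tanh(par[p + 3])
  structure(list(
    coefficients = beta,
    sigma2 = v,
    cov_mz = r_mz * v,
    cov_dz = r_dz * v,
    r_mz = r_mz,
    r_dz = r_dz,
    logLik = -fit$objective,
    covariate_set = match.arg(covariate_set,
                              c("none", "sex", "age", "sex+age")),
    n_families = nrow(paired),
    n_complete_mz = n_cmz,
    n_complete_dz = n_cdz,
    converged = TRUE
  ), class = "saturated_fit")
}

#' @export
print.saturated_fit <- function(x, ...) {
  cat(sprintf(
    "Saturated twin model (FIML, covariates: %s)\n", x$covariate_set
  ))
  cat(sprintf("  r_MZ = %.3f, r_DZ = %.3f, sigma2 = %.3f, logLik = %.3f\n",
              x$r_mz, x$r_dz, x$sigma2, x$logLik))
  invisible(x)
}

#' Select mean-model covariates by likelihood-ratio tests
#'
#' Fits the saturated model under all four covariate sets and compares the
#' full `sex+age` model against each reduced model by likelihood-ratio
#' test. A covariate is retained exactly when its removal is rejected at
#' `alpha`; with `criterion = "aic"` the set minimizing AIC is chosen
#' instead.
#'
#' @inheritParams fit_saturated
#' @param alpha Rejection level of the removal tests.
#' @param criterion `"lrt"` (default) or `"aic"`.
#' @return List with `covariate_set` (chosen), `table` (tests: comparison,
#'   df, chisq, p-value) and `fits` (the four saturated fits).
#' @export
select_covariates <- function(paired, alpha = 0.05, criterion = c("lrt", "aic"),
                              min_pairs = 5) {
  criterion <- match.arg(criterion)
  paired <- one_metabolite(paired)
  sets <- c("sex+age", "sex", "age", "none")
  fits <- lapply(sets, function(s) {
    fit_saturated(paired, covariate_set = s, min_pairs = min_pairs)
  })
  names(fits) <- sets
  ll <- vapply(fits, function(f) f$logLik, numeric(1))
  n_par <- vapply(sets, function(s) length(covariate_terms(s)) + 4, numeric(1))
  lrt <- function(reduced, df) {
    chisq <- max(0, 2 * (ll["sex+age"] - ll[reduced]))
    tibble::tibble(
      comparison = paste("sex+age vs", reduced),
      df = df,
      chisq = chisq,
      p.value = pchisq(chisq, df, lower.tail = FALSE)
    )
  }
  table <- dplyr::bind_rows(
    lrt("age", 1),    # removes sex
    lrt("sex", 1),    # removes age
    lrt("none", 2)    # removes both
  )
  table$removed <- c("sex", "age", "sex, age")
  if (criterion == "aic") {
    aic <- 2 * n_par - 2 * ll
    chosen <- sets[which.min(aic)]
  } else {
    keep_sex <- table$p.value[table$removed == "sex"] <= alpha
    keep_age <- table$p.value[table$removed == "age"] <= alpha
    chosen <- if (keep_sex && keep_age) "sex+age"
    else if (keep_sex) "sex"
    else if (keep_age) "age"
    else "none"
  }
  list(covariate_set = chosen, table = table, fits = fits)
}

#' Choose between ADE and ACE from the twin correlations
#'
#' Applies the classical rule of thumb: dominance (ADE) when the MZ
#' correlation exceeds twice the DZ correlation, shared environment (ACE)
#' otherwise; the tie goes to ACE because the rule uses a strict
#' inequality.
#'
#' @param r_mz,r_dz ML twin correlations from the best saturated fit.
#' @return `"ADE"` or `"ACE"` (vectorized).
#' @export
#' @examples
#' choose_model(0.61, 0.25)
#' choose_model(0.50, 0.25)
choose_model <- function(r_mz, r_dz) {
  ifelse(r_mz > 2 * r_dz, "ADE", "ACE")
}

# expected within-pair covariances of the variance-component models
vc_expected_cov <- function(model, A, X) {
  if (model == "ADE") {
    list(mz = A + X, dz = A / 2 + X / 4)
  } else {
    list(mz = A + X, dz = A / 2 + X)
  }
}

#' Fit an ADE or ACE variance-component twin model by FIML
#'
#' Decomposes the phenotypic variance into additive genetic (A), dominant
#' genetic (D) or common environmental (C), and unique environmental (E)
#' components using the expected twin covariances `A + D` (MZ) and
#' `A/2 + D/4` (DZ) for ADE, or `A + C` and `A/2 + C` for ACE. Components
#' are parameterized directly as unconstrained reals, so negative variance
#' estimates are allowed; proposals yielding an infeasible 2x2 covariance
#' get a penalized likelihood. Reports unstandardized components,
#' standardized shares, and the broad-sense (ADE: `(A+D)/V`) or
#' narrow-sense (ACE: `A/V`) heritability.
#'
#' @inheritParams fit_saturated
#' @param model `"ADE"` or `"ACE"`.
#' @return Object of class `vc_fit`.
#' @export
fit_ace_ade <- function(paired, model = c("ADE", "ACE"),
                        covariate_set = "none") {
  model <- match.arg(model)
  paired <- one_metabolite(paired)
  des <- mean_design(paired, covariate_set)
  p <- ncol(des$X1)
  mz <- paired$zygosity == "MZ"
  mom <- pair_moments(paired, covariate_set)
  start_comp <- if (model == "ADE") {
    c(A = 4 * mom$cov_dz - mom$cov_mz,
      X = 2 * mom$cov_mz - 4 * mom$cov_dz,
      E = mom$v - mom$cov_mz)
  } else {
    c(A = 2 * (mom$cov_mz - mom$cov_dz),
      X = 2 * mom$cov_dz - mom$cov_mz,
      E = mom$v - mom$cov_mz)
  }
  start <- c(mom$beta, start_comp)

  obj <- function(par) {
    beta <- par[seq_len(p)]
    A <- par[p + 1]
    X <- par[p + 2]
    E <- par[p + 3]
    V <- A + X + E
    cv <- vc_expected_cov(model, A, X)
    ll <- fiml_loglik(
      paired$y1, paired$y2,
      drop(des$X1 %*% beta), drop(des$X2 %*% beta),
      mz, V, cv$mz, cv$dz
    )
    if (!is.finite(ll)) {
      # smooth penalty pushing infeasible proposals back toward feasibility
      viol <- max(0, -(V - 1e-8)) +
        max(0, abs(cv$mz) - V) + max(0, abs(cv$dz) - V)
      1e8 + 1e6 * viol
    } else {
      -ll
    }
  }
  fit <- fiml_optimize(obj, start)
  par <- fit$par
  beta <- setNames(unname(par[seq_len(p)]), colnames(des$X1))
  A <- unname(par[p + 1])
  X <- unname(par[p + 2])
  E <- unname(par[p + 3])
  V <- A + X + E
  shares <- c(A, X, E) / V
  x_name <- if (model == "ADE") "D" else "C"
  h2 <- if (model == "ADE") (A + X) / V else A / V
  structure(list(
    model = model,
    coefficients = beta,
    A = A,
    D_or_C = setNames(X, x_name),
    E = E,
    V = V,
    a2 = shares[1],
    x2 = setNames(shares[2], paste0(tolower(x_name), "2")),
    e2 = shares[3],
    h2 = h2,
    h2_type = if (model == "ADE") "broad" else "narrow",
    logLik = -fit$objective,
    covariate_set = match.arg(covariate_set,
                              c("none", "sex", "age", "sex+age")),
    n_families = nrow(paired),
    converged = TRUE,
    data = paired
  ), class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  xn <- names(x$D_or_C)
  cat(sprintf("%s twin model (FIML, covariates: %s)\n",
              x$model, x$covariate_set))
  cat(sprintf("  A = %.3f, %s = %.3f, E = %.3f, V = %.3f\n",
              x$A, xn, unname(x$D_or_C), x$E, x$V))
  cat(sprintf("  shares: a2 = %.3f, %s2 = %.3f, e2 = %.3f; h2 (%s) = %.3f\n",
              x$a2, tolower(xn), unname(x$x2), x$e2, x$h2_type, x$h2))
  cat(sprintf("  logLik = %.3f\n", x$logLik))
  invisible(x)
}
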