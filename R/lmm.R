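#' Family-clustered random-intercept linear mixed model (ML)
#'
#' Fits `y = X beta + u_family + e`, `u ~ N(0, tau2)`, `e ~ N(0, sigma2)`,
#' by maximum likelihood with `tau2 >= 0`, the model used to correct
#' metabolite association scans for family clustering. The likelihood is
#' profiled: for a fixed variance ratio `theta = tau2 / sigma2` the GLS
#' coefficients and `sigma2` have closed forms (block-diagonal covariance
#' with a Sherman-Morrison inverse per family), leaving a one-dimensional
#' optimization over `theta`. Fixed effects are tested with Wald z tests.
#'
#' @param data Data frame holding response, covariates and cluster id.
#' @param response Name of the response column.
#' @param fixed Character vector of fixed-effect columns (intercept always
#'   included). May be empty for an intercept-only model.
#' @param cluster Name of the cluster (family) id column.
#' @param theta_max Upper bound of the profiled variance-ratio search.
#' @return Object of class `family_lmm`: coefficients, standard errors,
#'   Wald z and p-values, `tau2`, `sigma2`, `logLik`, `n`, `n_clusters`,
#'   `converged`.
#' @export
#' @examples
#' d <- data.frame(
#'   y = rnorm(40), x = rnorm(40), fam = rep(1:20, each = 2)
#' )
#' fit <- fit_family_lmm(d, "y", "x", "fam")
#' tidy(fit)
fit_family_lmm <- function(data, response, fixed = c("sex", "age"),
                           cluster = "family_id", theta_max = 50) {
  miss <- setdiff(c(response, fixed, cluster), names(data))
  if (length(miss)) {
    abort(paste("columns absent from `data`:", paste(miss, collapse = ", ")))
  }
  keep <- complete.cases(data[, c(response, fixed, cluster), drop = FALSE])
  data <- data[keep, , drop = FALSE]
  y <- as.numeric(data[[response]])
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  for (f in fixed) {
    v <- data[[f]]
    if (is.character(v) || is.factor(v)) {
      v <- as.factor(v)
      if (nlevels(v) != 2L) abort("categorical fixed effects must be binary")
      col <- as.numeric(v == levels(v)[2])
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- paste0(f, levels(v)[2])
    } else {
      X <- cbind(X, as.numeric(v))
      colnames(X)[ncol(X)] <- f
    }
  }
  fit <- lmm_ml_fit(y, X, as.character(data[[cluster]]),
                    theta_max = theta_max)
  fit$response <- response
  fit$fixed <- fixed
  structure(fit, class = "family_lmm")
}

# workhorse: profiled ML for the random-intercept model
lmm_ml_fit <- function(y, X, cluster, theta_max = 50) {
  n <- length(y)
  p <- ncol(X)
  if (qr(X)$rank < p) abort("singular fixed-effect design")
  if (length(unique(cluster)) < 2L) abort("need at least 2 clusters")

  # cluster-level sufficient statistics (independent of theta)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)[, 1]
  yty <- sum(y^2)
  Xc <- rowsum(X, cluster)            # per-cluster column sums of X
  yc <- rowsum(y, cluster)[, 1]
  ni <- as.vector(rowsum(rep(1, n), cluster))

  prof <- function(theta) {
    w <- theta / (1 + ni * theta)
    A <- XtX - crossprod(Xc * sqrt(w))
    b <- Xty - colSums(Xc * (w * yc))
    beta <- solve(A, b)
    rss <- (yty - sum(w * yc^2)) - sum(beta * b)
    sigma2 <- rss / n
    ll <- -0.5 * n * log(2 * pi) - 0.5 * n * log(sigma2) -
      0.5 * sum(log1p(ni * theta)) - 0.5 * n
    list(loglik = ll, beta = beta, sigma2 = sigma2, A = A)
  }

  opt <- optimize(function(th) -prof(th)$loglik,
                  interval = c(0, theta_max), tol = 1e-9)
  theta <- opt$minimum
  # the boundary theta = 0 (pure OLS) can beat the interior optimum
  if (prof(0)$loglik >= -opt$objective) theta <- 0
  sol <- prof(theta)
  vcov_beta <- solve(sol$A) * sol$sigma2
  se <- sqrt(diag(vcov_beta))
  z <- sol$beta / se
  list(
    coefficients = sol$beta,
    se = se,
    statistic = z,
    p_value = 2 * pnorm(-abs(z)),
    tau2 = theta * sol$sigma2,
    sigma2 = sol$sigma2,
    logLik = sol$loglik,
    vcov = vcov_beta,
    n = n,
    n_clusters = length(ni),
    converged = TRUE
  )
}

#' @export
print.family_lmm <- function(x, ...) {
  cat(sprintf(
    "Family-clustered LMM (ML): n = %d, clusters = %d\n", x$n, x$n_clusters
  ))
  cat(sprintf("tau2 = %.4g, sigma2 = %.4g, logLik = %.3f\n",
              x$tau2, x$sigma2, x$logLik))
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_family_lmm
#' @param x A `family_lmm` object.
#' @param ... Unused.
#' @export
tidy.family_lmm <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(x$statistic),
    p.value = unname(x$p_value)
  )
}

#' @rdname fit_family_lmm
#' @export
glance.family_lmm <- function(x, ...) {
  tibble::tibble(
    nobs = x$n,
    n_clusters = x$n_clusters,
    tau2 = x$tau2,
    sigma2 = x$sigma2,
    icc = x$tau2 / (x$tau2 + x$sigma2),
    logLik = x$logLik
  )
}
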