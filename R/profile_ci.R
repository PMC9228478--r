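#' Profile-likelihood confidence interval for a standardized component
#'
#' Computes a profile-likelihood interval for a standardized variance
#' share of a fitted ADE/ACE model: the bounds are the values where twice
#' the drop from the maximized log-likelihood equals the chi-squared(1)
#' quantile at `level`. At each candidate value the share is fixed and the
#' remaining parameters (mean coefficients, total variance, the other
#' share) are re-maximized; bounds are located by stepping outward from
#' the estimate and root-bracketing the profile deviance.
#'
#' @param fit A `vc_fit` from [fit_ace_ade()].
#' @param component One of `"a2"`, `"d2"`, `"c2"`, `"e2"`, `"h2"` (for an
#'   ADE fit `"h2"` profiles the broad-sense share `(A+D)/V`; for ACE it
#'   equals `"a2"`).
#' @param level Confidence level.
#' @param window Search window on the standardized scale; a bound falling
#'   outside is reported as `NA` (open-ended) with a warning.
#' @return Named numeric `c(lower, upper)` with attributes `level`,
#'   `component` and `estimate`.
#' @export
profile_ci <- function(fit, component = "a2", level = 0.95,
                       window = c(-1, 2)) {
  stopifnot(inherits(fit, "vc_fit"))
  valid <- c("a2", "d2", "c2", "e2", "h2")
  component <- match.arg(component, valid)
  x2_name <- paste0(tolower(names(fit$D_or_C)), "2")  # "d2" or "c2"
  if (component %in% c("d2", "c2") && component != x2_name) {
    abort(sprintf("fit is %s: component `%s` not present", fit$model,
                  component))
  }
  estimate <- switch(component,
    a2 = fit$a2,
    d2 = unname(fit$x2),
    c2 = unname(fit$x2),
    e2 = fit$e2,
    h2 = fit$h2
  )
  if (fit$model == "ACE" && component == "h2") component <- "a2"

  paired <- fit$data
  des <- mean_design(paired, fit$covariate_set)
  p <- ncol(des$X1)
  mz <- paired$zygosity == "MZ"
  target <- qchisq(level, df = 1)
  ll_hat <- fit$logLik

  # profile log-likelihood with the chosen share fixed at s;
  # free parameters: betas, log V, one remaining share
  profile_ll <- function(s) {
    shares_fn <- switch(component,
      a2 = function(t) c(s, t, 1 - s - t),
      d2 = ,
      c2 = function(t) c(t, s, 1 - s - t),
      e2 = function(t) c(t, 1 - s - t, s),
      h2 = function(t) c(t, s - t, 1 - s)  # ADE: a2 + d2 fixed at s
    )
    obj <- function(par) {
      beta <- par[seq_len(p)]
      V <- exp(par[p + 1])
      sh <- shares_fn(par[p + 2])
      A <- sh[1] * V
      X <- sh[2] * V
      E <- sh[3] * V
      cv <- vc_expected_cov(fit$model, A, X)
      ll <- fiml_loglik(
        paired$y1, paired$y2,
        drop(des$X1 %*% beta), drop(des$X2 %*% beta),
        mz, V, cv$mz, cv$dz
      )
      if (!is.finite(ll)) 1e10 else -ll
    }
    t_start <- switch(component,
      a2 = unname(fit$x2),
      d2 = ,
      c2 = fit$a2,
      e2 = fit$a2,
      h2 = fit$a2
    )
    opt <- tryCatch(
      fiml_optimize(obj, c(fit$coefficients, log(fit$V), t_start),
                    n_restarts = 2),
      error = function(e) NULL
    )
    if (is.null(opt)) -Inf else -opt$objective
  }

  deviance_gap <- function(s) 2 * (ll_hat - profile_ll(s)) - target

  find_bound <- function(direction) {
    step <- 0.05 * direction
    s_prev <- estimate
    s_cur <- estimate + step
    limit <- if (direction < 0) window[1] else window[2]
    repeat {
      if ((direction < 0 && s_cur < limit) ||
            (direction > 0 && s_cur > limit)) {
        warn(sprintf(
          "profile bound beyond search window [%g, %g]: reported open-ended",
          window[1], window[2]
        ))
        return(NA_real_)
      }
      g <- deviance_gap(s_cur)
      if (is.finite(g) && g > 0) break
      s_prev <- s_cur
      s_cur <- s_cur + step
    }
    uniroot(deviance_gap, lower = min(s_prev, s_cur),
            upper = max(s_prev, s_cur), tol = 1e-4)$root
  }

  out <- c(lower = find_bound(-1), upper = find_bound(1))
  attr(out, "level") <- level
  attr(out, "component") <- component
  attr(out, "estimate") <- estimate
  out
}
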