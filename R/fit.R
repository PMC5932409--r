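PAR_NAMES <- c("mu_intercept", "mu_slope", "var_intercept", "var_slope",
               "cov_intercept_slope", "var_residual")

#' Fit a linear latent growth curve model by maximum likelihood
#'
#' Estimates the six LGCM parameters (intercept and slope means, their
#' variances and covariance, residual variance) from a complete
#' longitudinal sample by minimizing the multivariate-normal ML
#' discrepancy between the sample moments and the model-implied moments.
#' Any subset of parameters can be fixed through \code{constraints}, which
#' is how the nested model pairs of the variance tests are formed.
#'
#' Free latent means are profiled out by generalized least squares at each
#' candidate covariance structure, so the optimization runs over the free
#' variance components only. Starting values come from a method-of-moments
#' decomposition of per-subject least-squares growth coefficients; on
#' non-convergence the fit is retried from jittered starts (up to
#' \code{max_restarts}) and flagged if still unsuccessful. Variance
#' parameters are deliberately estimated without a non-negativity
#' constraint, so likelihood ratio statistics for boundary hypotheses can
#' be referred to plain chi-square distributions.
#'
#' @param sample an \code{\link{lgcm_sample}} (or matrix coercible via
#'   \code{lgcm_sample} together with a design in its attributes).
#' @param constraints named numeric vector fixing parameters, e.g.
#'   \code{c(var_slope = 0, cov_intercept_slope = 0)}; names must be among
#'   \code{mu_intercept, mu_slope, var_intercept, var_slope,
#'   cov_intercept_slope, var_residual}.
#' @param se logical; compute standard errors from the observed information
#'   (numerical Hessian of -2LL at the optimum)? Skipping them speeds up
#'   simulation loops.
#' @param start optional full-length named numeric vector of starting
#'   values overriding the method-of-moments start.
#' @param max_restarts number of jittered restarts before a fit is flagged
#'   non-convergent.
#' @return An object of class \code{lgcm_fit} with components
#'   \code{estimates} (all six parameters, constrained ones at their fixed
#'   values), \code{se} (NA for constrained parameters, or NULL if not
#'   requested), \code{minus2LL}, \code{converged}, \code{constraints},
#'   \code{n_subjects}, \code{design}, and \code{vcov} (free parameters).
#' @examples
#' p <- lgcm_params(mu_intercept = 50, mu_slope = -1, var_intercept = 10,
#'                  var_slope = 1, var_residual = 50)
#' s <- simulate_sample(lgcm_design(0:4), p, n = 200, seed = 7)
#' fit <- lgcm_fit(s, constraints = c(cov_intercept_slope = 0))
#' coef(fit)
#' @seealso \code{\link{lr_test}}, \code{\link{wald_test}},
#'   \code{\link{mc_power}}
#' @export
lgcm_fit <- function(sample, constraints = NULL, se = TRUE, start = NULL,
                     max_restarts = 5L) {
  if (!inherits(sample, "lgcm_sample"))
    stop("'sample' must be an lgcm_sample (see lgcm_sample(), read_growth_csv())",
         call. = FALSE)
  x <- sample$values
  design <- sample$design
  M <- ncol(x)
  n <- nrow(x)
  if (M < 3L)
    stop("model fitting requires at least 3 measurement occasions",
         call. = FALSE)
  fixed <- check_constraints(constraints)
  n_free <- 6L - length(fixed)
  if (n <= n_free)
    stop("need more subjects than free parameters", call. = FALSE)

  L <- lgcm_loadings(design)
  xbar <- colMeans(x)
  xc <- sweep(x, 2L, xbar)
  S <- crossprod(xc) / n  # ML (biased) sample covariance

  free_cov <- setdiff(PAR_NAMES[3:6], names(fixed))
  free_mean <- setdiff(PAR_NAMES[1:2], names(fixed))

  # -2LL/n minus the M*log(2*pi) constant, free means profiled by GLS
  core <- function(theta_cov) {
    par <- fill_params(theta_cov, free_cov, fixed)
    Psi <- matrix(c(par["var_intercept"], par["cov_intercept_slope"],
                    par["cov_intercept_slope"], par["var_slope"]), 2L, 2L)
    Sig <- L %*% Psi %*% t(L) + par["var_residual"] * diag(M)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    inv <- chol2inv(ch)
    nu <- profile_means(xbar, L, inv, free_mean, fixed)
    d <- xbar - drop(L %*% nu)
    2 * sum(log(diag(ch))) + sum(inv * S) + drop(crossprod(d, inv %*% d))
  }

  start_cov <- if (!is.null(start)) {
    start[free_cov]
  } else {
    mom_start(x, L, S)[free_cov]
  }

  fit1 <- run_optim(core, start_cov)
  restarts <- 0L
  while ((!fit1$ok) && restarts < max_restarts) {
    restarts <- restarts + 1L
    jit <- start_cov * stats::runif(length(start_cov), 0.5, 1.5) +
      stats::rnorm(length(start_cov), 0, 0.1 + 0.1 * abs(start_cov))
    cand <- run_optim(core, jit)
    if (cand$ok || cand$value < fit1$value) fit1 <- cand
  }

  par_hat <- fill_params(fit1$par, free_cov, fixed)
  Psi <- matrix(c(par_hat["var_intercept"], par_hat["cov_intercept_slope"],
                  par_hat["cov_intercept_slope"], par_hat["var_slope"]),
                2L, 2L)
  Sig <- L %*% Psi %*% t(L) + par_hat["var_residual"] * diag(M)
  inv <- chol2inv(chol(Sig))
  nu <- profile_means(xbar, L, inv, free_mean, fixed)
  par_hat["mu_intercept"] <- nu[1]
  par_hat["mu_slope"] <- nu[2]
  minus2LL <- n * (fit1$value + M * log(2 * pi))

  out <- structure(list(
    estimates = par_hat, minus2LL = minus2LL,
    converged = fit1$ok, n_restarts = restarts,
    constraints = fixed, n_subjects = n, design = design,
    se = NULL, vcov = NULL
  ), class = "lgcm_fit")

  if (se) {
    free_all <- setdiff(PAR_NAMES, names(fixed))
    m2ll_free <- function(th) {
      par <- par_hat
      par[free_all] <- th
      n * (m2ll_full(par, L, S, xbar, M) + M * log(2 * pi))
    }
    H <- pracma::hessian(m2ll_free, par_hat[free_all])
    V <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(V) && all(is.finite(diag(V))) && all(diag(V) > 0)) {
      dimnames(V) <- list(free_all, free_all)
      ses <- rep(NA_real_, 6)
      names(ses) <- PAR_NAMES
      ses[free_all] <- sqrt(diag(V))
      out$se <- ses
      out$vcov <- V
    } else {
      ses <- rep(NA_real_, 6)
      names(ses) <- PAR_NAMES
      out$se <- ses
    }
  }
  out
}

check_constraints <- function(constraints) {
  if (is.null(constraints)) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(constraints)) || !all(names(constraints) %in% PAR_NAMES))
    stop("constraint names must be among: ",
         paste(PAR_NAMES, collapse = ", "), call. = FALSE)
  vapply(constraints, as.numeric, numeric(1))
}

fill_params <- function(theta, free_cov, fixed) {
  par <- stats::setNames(rep(0, 6L), PAR_NAMES)
  par[names(fixed)] <- fixed
  par[free_cov] <- theta
  par
}

profile_means <- function(xbar, L, inv, free_mean, fixed) {
  nu <- c(mu_intercept = 0, mu_slope = 0)
  nu[names(fixed)[names(fixed) %in% names(nu)]] <-
    fixed[names(fixed) %in% names(nu)]
  if (length(free_mean) == 0L) return(nu)
  idx <- match(free_mean, c("mu_intercept", "mu_slope"))
  Lf <- L[, idx, drop = FALSE]
  d <- xbar - L[, -idx, drop = FALSE] %*% nu[-idx]
  A <- crossprod(Lf, inv %*% Lf)
  nu[idx] <- solve(A, crossprod(Lf, inv %*% d))
  nu
}

# full -2LL/n (minus constant) with all parameters explicit
m2ll_full <- function(par, L, S, xbar, M) {
  Psi <- matrix(c(par["var_intercept"], par["cov_intercept_slope"],
                  par["cov_intercept_slope"], par["var_slope"]), 2L, 2L)
  Sig <- L %*% Psi %*% t(L) + par["var_residual"] * diag(M)
  ch <- tryCatch(chol(Sig), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  inv <- chol2inv(ch)
  d <- xbar - drop(L %*% c(par["mu_intercept"], par["mu_slope"]))
  2 * sum(log(diag(ch))) + sum(inv * S) + drop(crossprod(d, inv %*% d))
}

run_optim <- function(fn, start) {
  start <- as.numeric(start)
  if (length(start) == 0L) {
    v <- fn(numeric(0))
    return(list(par = numeric(0), value = v, ok = v < 1e9))
  }
  if (length(start) == 1L) {
    # bracketed 1-d minimization
    o <- stats::optim(start, fn, method = "Brent",
                      lower = start - 1e3 * (1 + abs(start)),
                      upper = start + 1e3 * (1 + abs(start)))
    return(list(par = o$par, value = o$value, ok = o$value < 1e9))
  }
  o <- stats::optim(start, fn, method = "Nelder-Mead",
                    control = list(reltol = 1e-12, maxit = 2000))
  # polish: restart the simplex at the solution
  o2 <- stats::optim(o$par, fn, method = "Nelder-Mead",
                     control = list(reltol = 1e-12, maxit = 2000))
  ok <- o2$convergence == 0 && o2$value < 1e9 &&
    abs(o$value - o2$value) < 1e-6 * (1 + abs(o2$value))
  list(par = o2$par, value = o2$value, ok = ok)
}

# method-of-moments start: per-subject OLS growth coefficients
mom_start <- function(x, L, S) {
  n <- nrow(x)
  M <- nrow(L)
  B <- x %*% L %*% solve(crossprod(L))  # n x 2 (icept, slope)
  resid <- x - B %*% t(L)
  ve <- if (M > 2L) sum(resid^2) / (n * (M - 2L)) else
    mean(diag(S)) * 0.5
  ve <- max(ve, 1e-4)
  Vb <- stats::cov(B) * (n - 1) / n
  Psi0 <- Vb - ve * solve(crossprod(L))
  c(mu_intercept = mean(B[, 1]), mu_slope = mean(B[, 2]),
    var_intercept = max(Psi0[1, 1], 1e-3),
    var_slope = Psi0[2, 2],
    cov_intercept_slope = Psi0[1, 2],
    var_residual = ve)
}

#' @export
print.lgcm_fit <- function(x, digits = 4, ...) {
  cat("Linear latent growth curve model (ML)\n")
  cat(sprintf("  N = %d subjects, M = %d occasions; -2LL = %.*f%s\n",
              x$n_subjects, length(x$design$times), 2, x$minus2LL,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  est <- format(signif(x$estimates, digits))
  flag <- ifelse(PAR_NAMES %in% names(x$constraints), " (fixed)", "")
  for (i in seq_along(PAR_NAMES))
    cat(sprintf("  %-20s %s%s\n", PAR_NAMES[i], est[i], flag[i]))
  invisible(x)
}

#' @export
summary.lgcm_fit <- function(object, ...) {
  tab <- data.frame(
    estimate = object$estimates,
    std_error = if (is.null(object$se)) NA_real_ else object$se,
    row.names = PAR_NAMES)
  tab$z <- tab$estimate / tab$std_error
  tab$z[PAR_NAMES %in% names(object$constraints)] <- NA
  structure(list(coefficients = tab, minus2LL = object$minus2LL,
                 converged = object$converged,
                 n_subjects = object$n_subjects,
                 constraints = object$constraints),
            class = "summary.lgcm_fit")
}

#' @export
print.summary.lgcm_fit <- function(x, digits = 4, ...) {
  cat("ML latent growth curve fit: N =", x$n_subjects,
      " -2LL =", format(x$minus2LL, digits = 8),
      if (x$converged) "" else " [NOT CONVERGED]", "\n")
  if (length(x$constraints))
    cat("Fixed:", paste(names(x$constraints), "=", x$constraints,
                        collapse = ", "), "\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.lgcm_fit <- function(object, ...) object$estimates

#' @export
logLik.lgcm_fit <- function(object, ...) {
  val <- -object$minus2LL / 2
  attr(val, "df") <- 6L - length(object$constraints)
  attr(val, "nobs") <- object$n_subjects
  class(val) <- "logLik"
  val
}

#' @export
vcov.lgcm_fit <- function(object, ...) object$vcov

#' @export
fitted.lgcm_fit <- function(object, ...) {
  drop(lgcm_loadings(object$design) %*%
         object$estimates[c("mu_intercept", "mu_slope")])
}

#' Simulate new samples from a fitted growth model
#'
#' @param object an \code{lgcm_fit}.
#' @param nsim number of samples to draw.
#' @param seed optional integer seed.
#' @param n_subjects subjects per sample; defaults to the fitted N.
#' @param ... unused.
#' @return A list of \code{lgcm_sample}s (a single sample if
#'   \code{nsim = 1}).
#' @export
simulate.lgcm_fit <- function(object, nsim = 1, seed = NULL,
                              n_subjects = object$n_subjects, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  e <- object$estimates
  par <- lgcm_params(e["mu_intercept"], e["mu_slope"], e["var_intercept"],
                     max(e["var_slope"], 0),
                     clamp_cov(e["cov_intercept_slope"],
                               e["var_intercept"], max(e["var_slope"], 0)),
                     max(e["var_residual"], 1e-12))
  out <- lapply(seq_len(nsim), function(i)
    simulate_sample(object$design, par, n = n_subjects))
  if (nsim == 1) out[[1]] else out
}

clamp_cov <- function(cis, vi, vs) {
  b <- sqrt(max(vi, 0) * max(vs, 0))
  min(max(cis, -b), b)
}

#' Likelihood ratio tests for zero slope variance
#'
#' Fits the nested model pair of the requested test and returns the
#' difference in -2LL. The specific 1-df test compares a model with slope
#' variance and intercept-slope covariance both fixed at zero against one
#' freeing the slope variance only (covariance still zero); the generalized
#' 2-df test compares the same restricted model against the model with all
#' three latent (co)variances free. Remaining parameters (means, intercept
#' variance, residual variance) are freely estimated in both members.
#'
#' @inheritParams lgcm_fit
#' @param kind \code{"specific_1df"} or \code{"generalized_2df"}.
#' @param extra_constraints additional fixed parameters applied to both
#'   members (used by the Monte Carlo oracle mode).
#' @return An object of class \code{lgcm_test} with \code{statistic}
#'   (clipped at 0), \code{df}, \code{p_value} (plain chi-square
#'   reference), \code{kind}, and the two fits (\code{fit_null},
#'   \code{fit_alt}).
#' @examples
#' p <- lgcm_params(var_intercept = 10, var_slope = 1, var_residual = 50)
#' s <- simulate_sample(lgcm_design(0:4), p, n = 200, seed = 11)
#' lr_test(s, "specific_1df")
#' @export
lr_test <- function(sample, kind = c("specific_1df", "generalized_2df"),
                    extra_constraints = NULL) {
  kind <- match.arg(kind)
  null_con <- c(var_slope = 0, cov_intercept_slope = 0)
  alt_con <- if (kind == "specific_1df") c(cov_intercept_slope = 0) else NULL
  null_con <- c(null_con,
                extra_constraints[setdiff(names(extra_constraints),
                                          names(null_con))])
  alt_con <- c(alt_con,
               extra_constraints[setdiff(names(extra_constraints),
                                         names(alt_con))])
  f0 <- lgcm_fit(sample, constraints = null_con, se = FALSE)
  f1 <- lgcm_fit(sample, constraints = alt_con, se = FALSE)
  stat <- f0$minus2LL - f1$minus2LL
  if (stat < 0) {
    # the larger model must fit at least as well; refit from the null
    # solution if the optimizer missed the basin
    f1b <- lgcm_fit(sample, constraints = alt_con, se = FALSE,
                    start = f0$estimates)
    if (f1b$minus2LL < f1$minus2LL) f1 <- f1b
    stat <- f0$minus2LL - f1$minus2LL
  }
  clipped <- stat < 0
  stat <- max(stat, 0)
  df <- if (kind == "specific_1df") 1L else 2L
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 kind = kind, clipped = clipped,
                 converged = f0$converged && f1$converged,
                 fit_null = f0, fit_alt = f1),
            class = "lgcm_test")
}

#' Wald test for zero slope variance
#'
#' The estimated slope variance divided by its observed-information
#' standard error, referred to a one-sided standard normal distribution.
#' Any fit with a free slope variance can be tested; the conventional
#' choice is the fully estimated model (all six parameters free), whose
#' Wald power is insensitive to intercept variance, unlike the LR tests.
#'
#' @param fit an \code{lgcm_fit} with a free slope variance and standard
#'   errors available, e.g. \code{lgcm_fit(s)}.
#' @return An \code{lgcm_test} with \code{statistic} (z), \code{df = 1},
#'   one-sided \code{p_value}.
#' @examples
#' p <- lgcm_params(var_intercept = 10, var_slope = 1, var_residual = 50)
#' s <- simulate_sample(lgcm_design(0:4), p, n = 200, seed = 11)
#' wald_test(lgcm_fit(s, constraints = c(cov_intercept_slope = 0)))
#' @export
wald_test <- function(fit) {
  if (!inherits(fit, "lgcm_fit"))
    stop("'fit' must be an lgcm_fit", call. = FALSE)
  if ("var_slope" %in% names(fit$constraints))
    stop("the Wald test needs a fit with free slope variance", call. = FALSE)
  if (is.null(fit$se) || !is.finite(fit$se["var_slope"]))
    stop("standard error of the slope variance is unavailable ",
         "(refit with se = TRUE or check the information matrix)",
         call. = FALSE)
  z <- unname(fit$estimates["var_slope"] / fit$se["var_slope"])
  if (fit$estimates["var_slope"] <= 0) z <- max(z, 0)
  structure(list(statistic = z, df = 1L,
                 p_value = stats::pnorm(z, lower.tail = FALSE),
                 kind = "wald", clipped = FALSE,
                 converged = fit$converged,
                 fit_null = NULL, fit_alt = fit),
            class = "lgcm_test")
}

#' @export
print.lgcm_test <- function(x, digits = 4, ...) {
  lab <- switch(x$kind,
                specific_1df = "Specific 1-df LR test of zero slope variance",
                generalized_2df =
                  "Generalized 2-df LR test of zero slope variance/covariance",
                wald = "Wald test of zero slope variance (one-sided z)")
  cat(lab, "\n")
  cat(sprintf("  statistic = %.*g, df = %d, p = %.*g\n",
              digits, x$statistic, x$df, digits, x$p_value))
  if (!x$converged) cat("  warning: a member fit did not converge\n")
  invisible(x)
}
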