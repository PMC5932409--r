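#' Noncentrality of the slope-variance LR test from ECR
#'
#' The likelihood ratio test of zero slope variance has, under the
#' alternative, an approximately noncentral chi-square sampling distribution
#' with noncentrality
#' \deqn{\lambda = N [ 1/(1-ECR) - \ln(1/(1-ECR)) - 1 ],}
#' derived from a power-equivalent minimal model in which the slope is
#' observed directly. \code{noncentrality_approx} evaluates the small-effect
#' shorthand \eqn{\lambda \approx N\, ECR^2/(1-ECR)}; it is provided for
#' reference only and is not used internally (its leading Taylor term is
#' twice that of the exact expression, so the two diverge even for small
#' ECR).
#'
#' @param ecr effective curve reliability in [0, 1).
#' @param n_subjects sample size N, >= 1.
#' @return Noncentrality parameter lambda >= 0.
#' @examples
#' noncentrality_from_ecr(0.2857143, 100)
#' @export
noncentrality_from_ecr <- function(ecr, n_subjects) {
  check_ecr_n(ecr, n_subjects)
  n_subjects * (1 / (1 - ecr) - log(1 / (1 - ecr)) - 1)
}

#' @rdname noncentrality_from_ecr
#' @export
noncentrality_approx <- function(ecr, n_subjects) {
  check_ecr_n(ecr, n_subjects)
  n_subjects * ecr^2 / (1 - ecr)
}

check_ecr_n <- function(ecr, n_subjects) {
  if (ecr < 0 || ecr >= 1)
    stop("'ecr' must lie in [0, 1)", call. = FALSE)
  if (n_subjects < 1)
    stop("'n_subjects' must be >= 1", call. = FALSE)
  invisible(NULL)
}

# ML discrepancy of a candidate covariance against the population covariance
# (mean structure unrestricted, so means contribute nothing)
ml_discrepancy <- function(sigma_pop, sigma_model) {
  M <- nrow(sigma_pop)
  ch <- tryCatch(chol(sigma_model), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  inv <- chol2inv(ch)
  ld_model <- 2 * sum(log(diag(ch)))
  ld_pop <- as.numeric(determinant(sigma_pop, logarithm = TRUE)$modulus)
  ld_model + sum(inv * sigma_pop) - ld_pop - M
}

#' Satorra-Saris noncentrality for slope-variance tests
#'
#' Builds the population moments implied by the alternative-hypothesis
#' parameters and evaluates the minimized ML discrepancy of the restricted
#' model (slope variance fixed at 0; for both tests the restricted model
#' also fixes the intercept-slope covariance at 0) against them; for the
#' specific 1-df test the discrepancy of the larger comparison model (which
#' still assumes zero covariance) is subtracted, so that lambda approximates
#' the mean shift of the LR statistic. The mean structure is unrestricted
#' throughout, so only the covariance structure contributes.
#'
#' With \code{nuisance = "fixed_true"} the untested parameters are held at
#' their population values (the power-equivalence convention under which
#' lambda is exactly \code{N} times the minimal-model discrepancy); with
#' \code{"free"} they are re-optimized, giving the smaller noncentrality
#' that corresponds to fully estimated models.
#'
#' @inheritParams implied_moments
#' @param test \code{"specific_1df"} or \code{"generalized_2df"}.
#' @param nuisance \code{"fixed_true"} or \code{"free"}.
#' @param n_subjects sample size multiplying the per-subject discrepancy;
#'   defaults to \code{design$n}, or 1 when neither is given.
#' @return Noncentrality lambda >= 0 (for \code{n_subjects} subjects).
#' @examples
#' p <- lgcm_params(var_intercept = 10, var_slope = 1, var_residual = 50)
#' satorra_saris_lambda(lgcm_design(0:4), p, n_subjects = 100)
#' @export
satorra_saris_lambda <- function(design, params,
                                 test = c("specific_1df", "generalized_2df"),
                                 nuisance = c("fixed_true", "free"),
                                 n_subjects = NULL) {
  design <- as_lgcm_design(design)
  params <- as_lgcm_params(params)
  test <- match.arg(test)
  nuisance <- match.arg(nuisance)
  if (is.null(n_subjects)) n_subjects <- if (is.null(design$n)) 1 else design$n
  sigma_pop <- implied_moments(design, params)$cov
  L <- lgcm_loadings(design)
  M <- nrow(L)

  model_cov <- function(vi, vs, cis, ve) {
    Psi <- matrix(c(vi, cis, cis, vs), 2L, 2L)
    S <- L %*% Psi %*% t(L) + ve * diag(M)
    (S + t(S)) / 2
  }

  f_restricted <- if (nuisance == "fixed_true") {
    ml_discrepancy(sigma_pop,
                   model_cov(params$var_intercept, 0, 0, params$var_residual))
  } else {
    obj <- function(p) ml_discrepancy(sigma_pop, model_cov(p[1], 0, 0, p[2]))
    minimize_discrepancy(obj, c(params$var_intercept, params$var_residual))
  }

  f_comparison <- if (test == "generalized_2df") {
    0  # the full model reproduces the population moments exactly
  } else if (nuisance == "fixed_true") {
    obj <- function(p)
      ml_discrepancy(sigma_pop, model_cov(params$var_intercept, p[1], 0,
                                          params$var_residual))
    minimize_discrepancy(obj, params$var_slope)
  } else {
    obj <- function(p)
      ml_discrepancy(sigma_pop, model_cov(p[1], p[2], 0, p[3]))
    minimize_discrepancy(obj, c(params$var_intercept, params$var_slope,
                                params$var_residual))
  }
  max(0, n_subjects * (f_restricted - f_comparison))
}

minimize_discrepancy <- function(obj, start) {
  if (length(start) == 1L) {
    o <- stats::optim(start, obj, method = "Brent",
                      lower = -1e3 * max(1, abs(start)),
                      upper = 1e3 * max(1, abs(start)))
  } else {
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  }
  if (o$value >= 1e9)
    stop("restricted-model discrepancy minimization failed", call. = FALSE)
  o$value
}

#' Power of a chi-square test from its noncentrality
#'
#' Tail probability of the noncentral chi-square distribution beyond the
#' null critical value: \eqn{1-\beta = P(\chi^2_{df,\lambda} > c_\alpha)}.
#' The default null reference is the central chi-square with \code{df}
#' degrees of freedom. Because the null slope variance lies on the boundary
#' of the parameter space, the LR null distribution is, strictly, a mixture
#' of chi-squares when variances are constrained non-negative;
#' \code{null_reference = "boundary_mixture"} uses the corresponding 50:50
#' mixture critical value (chi0/chi1 for df = 1, chi1/chi2 for df = 2).
#' The mixture shifts power equally across designs, so the plain reference
#' is the default for design comparison.
#'
#' @param lambda noncentrality, >= 0.
#' @param df degrees of freedom (1 or 2).
#' @param alpha test size in (0, 1).
#' @param null_reference \code{"plain"} or \code{"boundary_mixture"}.
#' @return Power in [alpha, 1].
#' @examples
#' power_from_lambda(6.353, df = 1, alpha = 0.05)
#' @export
power_from_lambda <- function(lambda, df, alpha = 0.05,
                              null_reference = c("plain",
                                                 "boundary_mixture")) {
  null_reference <- match.arg(null_reference)
  if (lambda < 0) stop("'lambda' must be >= 0", call. = FALSE)
  if (!df %in% c(1, 2)) stop("'df' must be 1 or 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0,1)", call. = FALSE)
  crit <- critical_value(df, alpha, null_reference)
  stats::pchisq(crit, df = df, ncp = lambda, lower.tail = FALSE)
}

critical_value <- function(df, alpha, null_reference) {
  if (null_reference == "plain")
    return(stats::qchisq(alpha, df = df, lower.tail = FALSE))
  if (df == 1) {
    # null = 0.5 chi2_0 + 0.5 chi2_1
    if (2 * alpha >= 1) return(0)
    stats::qchisq(2 * alpha, df = 1, lower.tail = FALSE)
  } else {
    # null = 0.5 chi2_1 + 0.5 chi2_2
    tail <- function(c) 0.5 * stats::pchisq(c, 1, lower.tail = FALSE) +
      0.5 * stats::pchisq(c, 2, lower.tail = FALSE) - alpha
    stats::uniroot(tail, c(0, 1e3), tol = 1e-12)$root
  }
}

#' Analytic power for tests of zero slope variance
#'
#' Chains the closed-form change-sensitivity quantities into a power
#' estimate: effective error from the design and variance components, ECR
#' from the slope variance, the noncentrality lambda from ECR and N, and
#' power from the noncentral chi-square tail. With non-zero intercept-slope
#' covariance (or for the generalized 2-df test) the noncentrality is
#' computed from the population ML discrepancy instead
#' (\code{\link{satorra_saris_lambda}}).
#'
#' Analytic power assumes all parameters other than the tested ones are
#' known; it therefore typically exceeds the Monte Carlo power of fully
#' estimated models (see \code{\link{mc_power}}).
#'
#' @inheritParams implied_moments
#' @inheritParams power_from_lambda
#' @param n_subjects sample size; defaults to \code{design$n}.
#' @param test \code{"specific_1df"} or \code{"generalized_2df"}.
#' @param nuisance how untested parameters enter the noncentrality; see
#'   \code{\link{satorra_saris_lambda}}.
#' @return An object of class \code{lgcm_power}: noncentrality, df, alpha,
#'   power, n_subjects, ecr, method \code{"analytic"}.
#' @examples
#' analytic_power(lgcm_design(0:4, n = 100),
#'                lgcm_params(var_intercept = 10, var_slope = 1,
#'                            var_residual = 50))
#' @export
analytic_power <- function(design, params, n_subjects = NULL,
                           test = c("specific_1df", "generalized_2df"),
                           alpha = 0.05,
                           nuisance = c("fixed_true", "free"),
                           null_reference = c("plain", "boundary_mixture")) {
  design <- as_lgcm_design(design)
  params <- as_lgcm_params(params)
  test <- match.arg(test)
  nuisance <- match.arg(nuisance)
  null_reference <- match.arg(null_reference)
  if (is.null(n_subjects)) n_subjects <- design$n
  if (is.null(n_subjects))
    stop("a sample size is required for power", call. = FALSE)
  df <- if (test == "specific_1df") 1L else 2L
  if (test == "specific_1df" && params$cov_intercept_slope == 0 &&
      nuisance == "fixed_true") {
    e <- ecr(params$var_slope,
             effective_error(design, params$var_intercept,
                             params$var_residual))
    lambda <- noncentrality_from_ecr(e, n_subjects)
  } else {
    lambda <- satorra_saris_lambda(design, params, test = test,
                                   nuisance = nuisance,
                                   n_subjects = n_subjects)
    e <- ecr_from_noncentrality(lambda / n_subjects)
  }
  structure(list(noncentrality = lambda, df = df, alpha = alpha,
                 power = power_from_lambda(lambda, df, alpha,
                                           null_reference),
                 n_subjects = as.integer(n_subjects), ecr = e,
                 test = test, method = "analytic",
                 null_reference = null_reference),
            class = "lgcm_power")
}

#' @export
print.lgcm_power <- function(x, digits = 3, ...) {
  cat(sprintf("%s power for the %s slope-variance test\n",
              if (x$method == "analytic") "Analytic" else "Monte Carlo",
              sub("_", " ", x$test)))
  cat(sprintf("  N = %d, alpha = %g, df = %d\n", x$n_subjects, x$alpha, x$df))
  if (x$method == "analytic") {
    cat(sprintf("  ECR = %.*g, noncentrality = %.*g\n",
                digits, x$ecr, digits, x$noncentrality))
    cat(sprintf("  power = %.*g\n", digits, x$power))
  } else {
    cat(sprintf("  power = %.*g (MC SE %.*g, %d replications, %d dropped)\n",
                digits, x$power, 2, x$mc_standard_error, x$nrep,
                x$n_nonconverged))
  }
  invisible(x)
}
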