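#' Effective error of the slope-variance test
#'
#' The effective error is the residual variance a hypothetical single direct
#' measurement of the latent slope would carry in a power-equivalent minimal
#' model; its inverse quantifies the precision of a repeated-measures design
#' for detecting individual differences in linear change. Under zero
#' intercept-slope covariance,
#' \deqn{\sigma^2_{eff} = \sigma^2_\epsilon / (\sum_j t_j^2 - \eta (\sum_j t_j)^2)}
#' with the shrinkage weight \eqn{\eta = 1/(M + \sigma^2_\epsilon/\sigma^2_I)}
#' (defined as 0 when the intercept variance is 0). Effective error grows
#' with residual variance and with intercept variance (through \eqn{\eta}),
#' and shrinks as occasions are added or spread further in time.
#'
#' @inheritParams lgcm_loadings
#' @param var_intercept latent intercept variance, >= 0.
#' @param var_residual residual variance, > 0.
#' @return Effective error variance (squared score units).
#' @examples
#' effective_error(lgcm_design(0:4), var_intercept = 10, var_residual = 50)
#' @export
effective_error <- function(design, var_intercept, var_residual) {
  design <- as_lgcm_design(design)
  if (var_intercept < 0 || var_residual < 0)
    stop("variances must be non-negative", call. = FALSE)
  if (var_residual == 0) return(0)
  t <- design$times
  M <- length(t)
  eta <- if (var_intercept == 0) 0 else 1 / (M + var_residual / var_intercept)
  denom <- sum(t^2) - eta * sum(t)^2
  if (denom <= 0)
    stop("degenerate design: occasions carry no information about the slope",
         call. = FALSE)
  var_residual / denom
}

#' Intraclass correlation of M repeated measures
#'
#' ICC2 = sigma_I^2 / (sigma_I^2 + sigma_e^2 / M): the reliability of the
#' person mean over M occasions, equal to M times the shrinkage weight eta
#' used in \code{\link{effective_error}}.
#'
#' @param var_intercept latent intercept variance, >= 0.
#' @param var_residual residual variance, >= 0 (not both zero).
#' @param n_occasions number of repeated measures M, >= 1.
#' @return ICC2 in [0, 1].
#' @examples
#' icc2(10, 50, 5)  # 0.5
#' @export
icc2 <- function(var_intercept, var_residual, n_occasions) {
  if (n_occasions < 1) stop("'n_occasions' must be >= 1", call. = FALSE)
  if (var_intercept < 0 || var_residual < 0)
    stop("variances must be non-negative", call. = FALSE)
  if (var_intercept == 0 && var_residual == 0)
    stop("ICC2 undefined when both variances are zero", call. = FALSE)
  var_intercept / (var_intercept + var_residual / n_occasions)
}

#' Effective curve reliability (ECR)
#'
#' ECR scales the slope variance against the sum of slope variance and
#' effective error, ECR = sigma_S^2 / (sigma_S^2 + sigma_eff^2). It is a
#' standardized effect size in [0, 1] coherent with the power of the
#' likelihood ratio test of zero slope variance.
#'
#' @param var_slope latent slope variance, >= 0.
#' @param effective_error effective error variance, >= 0 (see
#'   \code{\link{effective_error}}).
#' @return ECR in [0, 1].
#' @examples
#' ecr(1, effective_error(lgcm_design(0:4), 10, 50))
#' @export
ecr <- function(var_slope, effective_error) {
  if (var_slope < 0 || effective_error < 0)
    stop("arguments must be non-negative", call. = FALSE)
  if (var_slope == 0 && effective_error == 0)
    stop("ECR undefined when slope variance and effective error are both 0",
         call. = FALSE)
  var_slope / (var_slope + effective_error)
}

#' Growth rate reliability (GRR)
#'
#' Willett's reliability of the individual growth rate,
#' GRR = sigma_S^2 / (sigma_S^2 + sigma_e^2 / SST), where SST is the sum of
#' squared deviations of the occasions about their mean time. GRR is the
#' limiting case of ECR when ICC2 = 1 (or for time-centered designs) and is
#' coherent with the Wald test, which ignores intercept variance.
#'
#' @param var_slope latent slope variance, >= 0.
#' @param var_residual residual variance, >= 0.
#' @param sst sum of squared deviations of occasion times about their mean
#'   (years^2), > 0; see \code{\link{design_sst}}.
#' @return GRR in [0, 1].
#' @examples
#' grr(1.35, 10, design_sst(lgcm_design(c(0, 2.5, 5)))$sst)
#' @export
grr <- function(var_slope, var_residual, sst) {
  if (sst <= 0)
    stop("SST must be positive (occasions cannot all coincide)",
         call. = FALSE)
  if (var_slope < 0 || var_residual < 0)
    stop("variances must be non-negative", call. = FALSE)
  if (var_slope == 0 && var_residual == 0)
    stop("GRR undefined when slope and residual variance are both 0",
         call. = FALSE)
  var_slope / (var_slope + var_residual / sst)
}

#' Precision and reliability summary of a design
#'
#' Evaluates all change-sensitivity indices for one design and one set of
#' population parameters: effective error, its centered-design special case
#' sigma_e^2/SST, ECR, GRR, ICC2, eta, SST, mean time and dispersion.
#' With zero intercept-slope covariance the closed forms are used; otherwise
#' ECR is obtained from the generalized (likelihood-based) construction of
#' \code{\link{generalized_ecr}} and effective error is back-solved from it.
#'
#' @inheritParams implied_moments
#' @param test which test the generalized ECR should cohere with when
#'   \code{cov_intercept_slope != 0}: \code{"specific_1df"} or
#'   \code{"generalized_2df"}.
#' @return An object of class \code{lgcm_precision}: a list with fields
#'   \code{effective_error}, \code{special_case_error}, \code{ecr},
#'   \code{grr}, \code{icc2}, \code{eta}, \code{sst}, \code{mean_time},
#'   \code{dispersion}, plus the inputs.
#' @examples
#' precision_summary(lgcm_design(0:4),
#'                   lgcm_params(var_intercept = 10, var_slope = 1,
#'                               var_residual = 50))
#' @export
precision_summary <- function(design, params, test = c("specific_1df",
                                                       "generalized_2df")) {
  design <- as_lgcm_design(design)
  params <- as_lgcm_params(params)
  test <- match.arg(test)
  M <- length(design$times)
  ss <- design_sst(design)
  eta <- if (params$var_intercept == 0) 0 else
    1 / (M + params$var_residual / params$var_intercept)
  if (params$cov_intercept_slope == 0) {
    s_eff <- effective_error(design, params$var_intercept,
                             params$var_residual)
    e <- ecr(params$var_slope, s_eff)
  } else {
    e <- generalized_ecr(design, params, test = test)
    # invert ECR = vs/(vs + s_eff) for the implied effective error
    s_eff <- if (e > 0) params$var_slope * (1 - e) / e else Inf
  }
  structure(list(
    effective_error = s_eff,
    special_case_error = params$var_residual / ss$sst,
    ecr = e,
    grr = grr(params$var_slope, params$var_residual, ss$sst),
    icc2 = icc2(params$var_intercept, params$var_residual, M),
    eta = eta,
    sst = ss$sst,
    mean_time = ss$mean_time,
    dispersion = ss$dispersion,
    design = design, params = params, test = test
  ), class = "lgcm_precision")
}

#' @export
print.lgcm_precision <- function(x, digits = 3, ...) {
  cat("Change sensitivity of LGCM design",
      sprintf("{%s}\n", paste(fmt_times(x$design$times), collapse = ", ")))
  cat(sprintf("  effective error  %.*g\n", digits, x$effective_error))
  cat(sprintf("  ECR              %.*g\n", digits, x$ecr))
  cat(sprintf("  GRR              %.*g\n", digits, x$grr))
  cat(sprintf("  ICC2             %.*g\n", digits, x$icc2))
  cat(sprintf("  SST %.*g yr^2,  dispersion %.*g yr^2,  mean time %.*g yr\n",
              digits, x$sst, digits, x$dispersion, digits, x$mean_time))
  invisible(x)
}

#' Generalized effective curve reliability
#'
#' Likelihood-based ECR for arbitrary intercept-slope covariance, coherent
#' with the chosen variance test. The per-subject noncentrality
#' f = lambda / N of the test is computed from the population discrepancy of
#' the restricted model via \code{\link{satorra_saris_lambda}}, and ECR is
#' the unique value in [0, 1) solving
#' \deqn{f = 1/(1-ECR) - \ln(1/(1-ECR)) - 1,}
#' the per-subject noncentrality of a minimal model in which the slope is
#' observed directly with reliability ECR. When the intercept-slope
#' covariance is zero and nuisance parameters are held at their true values
#' this reproduces the closed-form ECR exactly.
#'
#' @inheritParams implied_moments
#' @param test \code{"specific_1df"} (slope variance only, covariance
#'   assumed zero) or \code{"generalized_2df"} (slope variance and
#'   covariance tested jointly).
#' @param nuisance \code{"fixed_true"} holds all untested parameters at
#'   their population values (the power-equivalence convention);
#'   \code{"free"} re-optimizes them under the restricted model, which
#'   yields a smaller noncentrality and hence smaller ECR.
#' @return ECR in [0, 1).
#' @examples
#' p <- lgcm_params(var_intercept = 10, var_slope = 1, var_residual = 50)
#' generalized_ecr(lgcm_design(0:4), p)  # equals the closed form, 0.2857
#' @export
generalized_ecr <- function(design, params,
                            test = c("specific_1df", "generalized_2df"),
                            nuisance = c("fixed_true", "free")) {
  test <- match.arg(test)
  nuisance <- match.arg(nuisance)
  f <- satorra_saris_lambda(design, params, test = test,
                            nuisance = nuisance, n_subjects = 1)
  ecr_from_noncentrality(f)
}

# invert f = 1/(1-E) - log(1/(1-E)) - 1 for E in [0, 1)
ecr_from_noncentrality <- function(f) {
  # f ~ ECR^2/2 near zero, so numerical noise in f is amplified; treat
  # discrepancies at the optimizer tolerance as exact fit
  if (f < 1e-12) return(0)
  g <- function(e) 1 / (1 - e) - log(1 / (1 - e)) - 1 - f
  upper <- 1 - 1e-12
  if (g(upper) < 0) return(upper)
  stats::uniroot(g, c(0, upper), tol = 1e-12)$root
}
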