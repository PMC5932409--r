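#' Variance components from an instrument reliability
#'
#' Under classical test theory with no true change, an alternate-forms (or
#' parallel-forms) reliability coefficient splits the total observed
#' variance into stable between-person variance (the latent intercept
#' variance) and residual variance:
#' sigma_I^2 = rho * total, sigma_e^2 = (1 - rho) * total.
#' With T-score scaling (SD = 10) the total is 100.
#'
#' @param reliability alternate-forms reliability in (0, 1].
#' @param total_variance total observed variance (squared score units),
#'   default 100 (T-score units).
#' @return Named numeric vector with \code{var_intercept} and
#'   \code{var_residual}.
#' @examples
#' params_from_reliability(0.9)   # 90 and 10
#' @export
params_from_reliability <- function(reliability, total_variance = 100) {
  if (reliability <= 0 || reliability > 1)
    stop("'reliability' must be in (0, 1]", call. = FALSE)
  if (total_variance <= 0)
    stop("'total_variance' must be positive", call. = FALSE)
  c(var_intercept = reliability * total_variance,
    var_residual = (1 - reliability) * total_variance)
}

#' Stability coefficient implied by growth parameters
#'
#' The model-implied correlation of the outcome with itself across an
#' interval of \code{elapsed_time} years:
#' \deqn{\rho_{stab} = (\sigma_I^2 + T\sigma_{IS}) /
#'   \sqrt{(\sigma_I^2+\sigma_e^2)(\sigma_I^2+\sigma_e^2+T^2\sigma_S^2+2T\sigma_{IS})}}
#' At T = 0 this reduces to the reliability of
#' \code{\link{params_from_reliability}}; with no individual differences in
#' change it equals the reliability for every interval.
#'
#' @param params an \code{\link{lgcm_params}} object (means are ignored).
#' @param elapsed_time interval T in years, >= 0.
#' @return Stability coefficient.
#' @examples
#' p <- lgcm_params(var_intercept = 90, var_slope = 1.35, var_residual = 10)
#' stability_coefficient(p, 3)   # 0.85
#' @export
stability_coefficient <- function(params, elapsed_time) {
  params <- as_lgcm_params(params)
  if (elapsed_time < 0) stop("'elapsed_time' must be >= 0", call. = FALSE)
  T <- elapsed_time
  v0 <- params$var_intercept + params$var_residual
  vT <- v0 + T^2 * params$var_slope + 2 * T * params$cov_intercept_slope
  if (v0 <= 0 || vT <= 0)
    stop("observed variance must be positive at both occasions",
         call. = FALSE)
  (params$var_intercept + T * params$cov_intercept_slope) / sqrt(v0 * vT)
}

#' Slope variance implied by a stability coefficient
#'
#' Inverts the stability equation for the slope variance given the
#' intercept and residual variances (for instance from
#' \code{\link{params_from_reliability}}), an observed stability over
#' \code{elapsed_time} years, and an assumed intercept-slope covariance
#' (zero being the recommended starting point). A stability coefficient at
#' least as large as what the reliability permits leaves no room for true
#' individual differences in change and yields zero (or, if impossible, an
#' error): when reliability and stability coincide the implied slope
#' variance is exactly zero.
#'
#' @param var_intercept latent intercept variance.
#' @param var_residual residual variance.
#' @param stability observed stability coefficient in (0, 1].
#' @param elapsed_time interval T in years, > 0.
#' @param cov_intercept_slope assumed intercept-slope covariance
#'   (default 0).
#' @return Implied slope variance (>= 0).
#' @examples
#' slope_var_from_stability(90, 10, 0.85, 3)  # 1.35
#' @export
slope_var_from_stability <- function(var_intercept, var_residual, stability,
                                     elapsed_time,
                                     cov_intercept_slope = 0) {
  if (stability <= 0 || stability > 1)
    stop("'stability' must be in (0, 1]", call. = FALSE)
  if (elapsed_time <= 0) stop("'elapsed_time' must be > 0", call. = FALSE)
  T <- elapsed_time
  v0 <- var_intercept + var_residual
  if (v0 <= 0) stop("total variance must be positive", call. = FALSE)
  num <- var_intercept + T * cov_intercept_slope
  vs <- ((num / stability)^2 / v0 - v0 - 2 * T * cov_intercept_slope) / T^2
  if (vs < -1e-10)
    stop("stability exceeds what the reliability permits: no non-negative ",
         "slope variance is consistent with these inputs", call. = FALSE)
  max(vs, 0)
}

#' Slope-variance grid over reliability and stability
#'
#' Evaluates the reliability/stability heuristics on a grid: each cell is
#' the slope variance implied by the row reliability and column stability
#' over \code{elapsed_time} years, assuming zero intercept-slope
#' covariance. Cells where the stability exceeds the reliability (no
#' non-negative solution) are \code{NA}. The grid is monotone: implied
#' slope variance falls as stability rises and grows as reliability rises.
#'
#' @param reliabilities numeric vector of reliabilities.
#' @param stabilities numeric vector of stabilities.
#' @param elapsed_time interval T in years (default 3).
#' @param total_variance total observed variance (default 100, T-scores).
#' @return Numeric matrix, rows named by reliability, columns by stability.
#' @examples
#' reliability_stability_table(c(0.89, 0.9, 0.925),
#'                             c(0.75, 0.8, 0.85, 0.875, 0.89))
#' @export
reliability_stability_table <- function(reliabilities, stabilities,
                                        elapsed_time = 3,
                                        total_variance = 100) {
  out <- matrix(NA_real_, length(reliabilities), length(stabilities),
                dimnames = list(format(reliabilities, nsmall = 3),
                                format(stabilities, nsmall = 3)))
  for (i in seq_along(reliabilities)) {
    vc <- params_from_reliability(reliabilities[i], total_variance)
    for (j in seq_along(stabilities)) {
      out[i, j] <- tryCatch(
        slope_var_from_stability(vc["var_intercept"], vc["var_residual"],
                                 stabilities[j], elapsed_time),
        error = function(e) NA_real_)
    }
  }
  out
}

#' Compare the change sensitivity of candidate study designs
#'
#' Evaluates each candidate design under one common set of population
#' parameters and sample size and reports, per design: the occasion
#' dispersion SST/(M-1), GRR, ECR, effective error, analytic power of the
#' chosen test, and optionally Monte-Carlo power from full ML refitting.
#' Comparing effective error across designs presumes the outcome is scaled
#' in the same metric in all of them.
#'
#' @param designs a list of \code{\link{lgcm_design}}s (or numeric time
#'   vectors).
#' @inheritParams analytic_power
#' @param with_mc logical; add a Monte Carlo power column?
#' @param nrep,seed Monte Carlo settings (see \code{\link{mc_power}}).
#' @return A data frame of class \code{lgcm_design_report}, one row per
#'   design, with columns \code{design}, \code{dispersion}, \code{grr},
#'   \code{ecr}, \code{effective_error}, \code{analytic_power} and
#'   optionally \code{mc_power}, \code{mc_se}.
#' @examples
#' p <- lgcm_params(var_intercept = 10, var_slope = 1, var_residual = 50)
#' compare_designs(list(c(0, 1, 2, 3, 4), c(0, 1, 3, 3.5, 4)), p,
#'                 n_subjects = 100)
#' @export
compare_designs <- function(designs, params, n_subjects,
                            test = c("specific_1df", "generalized_2df"),
                            alpha = 0.05, with_mc = FALSE,
                            nrep = 1000L, seed = 1L) {
  test <- match.arg(test)
  params <- as_lgcm_params(params)
  designs <- lapply(designs, as_lgcm_design)
  rows <- lapply(seq_along(designs), function(i) {
    d <- designs[[i]]
    ps <- precision_summary(d, params, test = test)
    ap <- analytic_power(d, params, n_subjects = n_subjects, test = test,
                         alpha = alpha)
    row <- data.frame(
      design = paste0("{", paste(fmt_times(d$times),
                                 collapse = ", "), "}"),
      dispersion = ps$dispersion,
      grr = ps$grr,
      ecr = ps$ecr,
      effective_error = ps$effective_error,
      analytic_power = ap$power,
      stringsAsFactors = FALSE)
    if (with_mc) {
      mp <- mc_power(d, params, n_subjects = n_subjects, test = test,
                     alpha = alpha, nrep = nrep, seed = rep_seed(seed, i))
      row$mc_power <- mp$power
      row$mc_se <- mp$mc_standard_error
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "params") <- params
  attr(out, "n_subjects") <- n_subjects
  attr(out, "alpha") <- alpha
  attr(out, "test") <- test
  class(out) <- c("lgcm_design_report", "data.frame")
  out
}

#' @export
print.lgcm_design_report <- function(x, digits = 2, ...) {
  cat(sprintf("Design comparison (%s test, N = %s, alpha = %g)\n",
              sub("_", " ", attr(x, "test")), attr(x, "n_subjects"),
              attr(x, "alpha")))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}
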