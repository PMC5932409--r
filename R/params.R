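#' Population parameters of a linear latent growth curve model
#'
#' Bundles the six parameters of the univariate linear LGCM: the latent
#' intercept and slope means, their variances and covariance, and the
#' occasion-specific residual variance (assumed homogeneous and uncorrelated
#' across occasions). Units follow the outcome's score scale; the slope is
#' per year.
#'
#' @param mu_intercept latent intercept mean (score units).
#' @param mu_slope latent slope mean (score units / year).
#' @param var_intercept latent intercept variance, >= 0.
#' @param var_slope latent slope variance, >= 0.
#' @param cov_intercept_slope intercept-slope covariance; the 2 x 2 latent
#'   covariance matrix must be positive semidefinite.
#' @param var_residual residual variance, >= 0.
#' @return An object of class \code{lgcm_params} (a named list).
#' @examples
#' lgcm_params(var_intercept = 10, var_slope = 1, var_residual = 50)
#' @export
lgcm_params <- function(mu_intercept = 0, mu_slope = 0,
                        var_intercept = 0, var_slope = 0,
                        cov_intercept_slope = 0, var_residual = 0) {
  p <- list(mu_intercept = as.numeric(mu_intercept),
            mu_slope = as.numeric(mu_slope),
            var_intercept = as.numeric(var_intercept),
            var_slope = as.numeric(var_slope),
            cov_intercept_slope = as.numeric(cov_intercept_slope),
            var_residual = as.numeric(var_residual))
  if (any(!vapply(p, function(v) length(v) == 1L && is.finite(v), logical(1))))
    stop("all parameters must be single finite numbers", call. = FALSE)
  if (p$var_intercept < 0 || p$var_slope < 0 || p$var_residual < 0)
    stop("variances must be non-negative", call. = FALSE)
  if (p$cov_intercept_slope^2 > p$var_intercept * p$var_slope + 1e-12)
    stop("latent covariance matrix is not positive semidefinite: ",
         "cov_intercept_slope^2 exceeds var_intercept * var_slope",
         call. = FALSE)
  structure(p, class = "lgcm_params")
}

as_lgcm_params <- function(x) {
  if (inherits(x, "lgcm_params")) return(x)
  do.call(lgcm_params, as.list(x))
}

#' @export
print.lgcm_params <- function(x, ...) {
  cat("LGCM population parameters\n")
  cat(sprintf("  means:      intercept %g, slope %g\n",
              x$mu_intercept, x$mu_slope))
  cat(sprintf("  variances:  intercept %g, slope %g, residual %g\n",
              x$var_intercept, x$var_slope, x$var_residual))
  cat(sprintf("  covariance: intercept-slope %g\n", x$cov_intercept_slope))
  invisible(x)
}

latent_cov <- function(params) {
  matrix(c(params$var_intercept, params$cov_intercept_slope,
           params$cov_intercept_slope, params$var_slope), 2L, 2L)
}

#' Model-implied moments of a linear LGCM
#'
#' Computes the mean vector and covariance matrix of the observed repeated
#' measures implied by the growth model: Sigma = Lambda Psi Lambda' + Theta
#' and mu = Lambda nu, with Lambda the loading matrix of
#' \code{\link{lgcm_loadings}}, Psi the latent covariance matrix, nu the
#' latent means and Theta the diagonal residual covariance.
#'
#' @inheritParams lgcm_loadings
#' @param params an \code{\link{lgcm_params}} object.
#' @return A list of class \code{lgcm_moments} with \code{mean} (length M),
#'   \code{cov} (M x M), and \code{loadings} (M x 2).
#' @examples
#' implied_moments(lgcm_design(0:2),
#'                 lgcm_params(var_intercept = 10, var_slope = 2,
#'                             var_residual = 20))
#' @export
implied_moments <- function(design, params) {
  design <- as_lgcm_design(design)
  params <- as_lgcm_params(params)
  L <- lgcm_loadings(design)
  Sigma <- L %*% latent_cov(params) %*% t(L) +
    params$var_residual * diag(nrow(L))
  Sigma <- (Sigma + t(Sigma)) / 2  # enforce exact symmetry
  mu <- drop(L %*% c(params$mu_intercept, params$mu_slope))
  structure(list(mean = mu, cov = Sigma, loadings = L),
            class = "lgcm_moments")
}

#' Simulate complete longitudinal samples from a linear LGCM
#'
#' Draws \code{n} independent subjects from the multivariate normal
#' distribution with the model-implied moments of the design and parameters.
#'
#' @inheritParams implied_moments
#' @param n number of subjects; defaults to \code{design$n}.
#' @param seed optional integer seed; when supplied, the draw is
#'   reproducible and the global RNG stream is advanced as by
#'   \code{set.seed}.
#' @return An object of class \code{lgcm_sample}: a list with \code{values}
#'   (an \code{n} x M numeric matrix, columns named \code{t<time>}) and
#'   \code{design}.
#' @examples
#' s <- simulate_sample(lgcm_design(0:4),
#'                      lgcm_params(var_intercept = 10, var_slope = 1,
#'                                  var_residual = 50),
#'                      n = 5, seed = 1)
#' dim(s$values)
#' @export
simulate_sample <- function(design, params, n = design$n, seed = NULL) {
  design <- as_lgcm_design(design)
  params <- as_lgcm_params(params)
  if (is.null(n)) stop("sample size 'n' is required", call. = FALSE)
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  mom <- implied_moments(design, params)
  x <- MASS::mvrnorm(n, mu = mom$mean, Sigma = mom$cov)
  if (n == 1L) x <- matrix(x, nrow = 1L)
  colnames(x) <- paste0("t", fmt_times(design$times))
  structure(list(values = x, design = design), class = "lgcm_sample")
}

#' @export
print.lgcm_sample <- function(x, ...) {
  cat(sprintf("LGCM sample: %d subjects x %d occasions (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(fmt_times(x$design$times), collapse = ", ")))
  invisible(x)
}

#' Construct a longitudinal sample from a matrix
#'
#' Wraps an existing complete N x M score matrix and its design as an
#' \code{lgcm_sample}, validating dimensions and completeness.
#'
#' @param values numeric matrix or data frame, one row per subject, one
#'   column per occasion; no missing cells.
#' @inheritParams lgcm_loadings
#' @return An \code{lgcm_sample}.
#' @export
lgcm_sample <- function(values, design) {
  design <- as_lgcm_design(design)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) != length(design$times))
    stop("column count must equal the number of design occasions",
         call. = FALSE)
  if (anyNA(values))
    stop("longitudinal samples must be complete (no missing cells)",
         call. = FALSE)
  structure(list(values = values, design = design), class = "lgcm_sample")
}
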