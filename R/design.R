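#' Define a longitudinal study design
#'
#' A study design is the half of a linear latent growth curve model (LGCM)
#' that the investigator controls: the measurement occasions \code{times}
#' (in years, relative to an arbitrary origin) and, optionally, the number
#' of subjects \code{n}. Two occasions suffice for the precision formulas;
#' model fitting additionally requires at least three occasions for
#' identification.
#'
#' The intercept of the growth model is defined at time 0, so shifting the
#' time axis (see \code{\link{shift_design}}) changes where the intercept is
#' anchored. Designs need not contain 0.
#'
#' @param times numeric vector of measurement occasions in years; strictly
#'   increasing, finite, length >= 2.
#' @param n optional positive integer sample size; required only for power
#'   computations and simulation.
#' @return An object of class \code{lgcm_design}: a list with elements
#'   \code{times} and \code{n}.
#' @examples
#' d <- lgcm_design(c(0, 1, 2, 3, 4), n = 100)
#' d
#' @seealso \code{\link{shift_design}}, \code{\link{scale_design}},
#'   \code{\link{center_design}}, \code{\link{design_sst}}
#' @export
lgcm_design <- function(times, n = NULL) {
  times <- as.numeric(times)
  if (length(times) < 2L)
    stop("a study design needs at least 2 measurement occasions", call. = FALSE)
  if (any(!is.finite(times)))
    stop("all measurement times must be finite", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("measurement times must be strictly increasing", call. = FALSE)
  if (!is.null(n)) {
    n <- as.integer(n)
    if (length(n) != 1L || is.na(n) || n < 1L)
      stop("'n' must be a single positive integer", call. = FALSE)
  }
  structure(list(times = times, n = n), class = "lgcm_design")
}

as_lgcm_design <- function(x) {
  if (inherits(x, "lgcm_design")) x else lgcm_design(x)
}

# element-wise time labels without common-width padding ("0", "2.5", "5")
fmt_times <- function(times) {
  vapply(times, function(t) format(t, trim = TRUE), character(1))
}

#' @export
print.lgcm_design <- function(x, ...) {
  cat("LGCM study design\n")
  cat("  occasions (years):", paste(fmt_times(x$times), collapse = ", "),
      "\n")
  cat("  M =", length(x$times))
  if (!is.null(x$n)) cat(",  N =", x$n)
  cat("\n")
  invisible(x)
}

#' Factor loading matrix of a linear growth model
#'
#' Builds the M x 2 loading matrix with a unit column for the latent
#' intercept and the measurement times for the latent slope.
#'
#' @param design an \code{\link{lgcm_design}} or a numeric vector of times.
#' @return M x 2 numeric matrix with columns \code{icept} and \code{slope}.
#' @examples
#' lgcm_loadings(lgcm_design(c(0, 2.5, 5)))
#' @export
lgcm_loadings <- function(design) {
  design <- as_lgcm_design(design)
  t <- design$times
  matrix(c(rep(1, length(t)), t), ncol = 2L,
         dimnames = list(NULL, c("icept", "slope")))
}

#' Shift, rescale or center a design in time
#'
#' Time transformations of a design: \code{shift_design} adds \code{delta}
#' years to every occasion (moving the intercept anchor), \code{scale_design}
#' multiplies all occasions by \code{factor} (prolonging or compressing the
#' study), and \code{center_design} subtracts the mean occasion time so that
#' the occasions sum to zero. Shifting leaves the occasion spread (SST) and
#' therefore growth rate reliability unchanged, but alters effective error
#' and ECR; a centered design has the largest effective error over all
#' shifts.
#'
#' @param design an \code{\link{lgcm_design}} or numeric vector of times.
#' @param delta shift in years (may be negative).
#' @param factor positive multiplier for the time axis.
#' @return A new \code{lgcm_design} with transformed times (same \code{n}).
#' @examples
#' shift_design(lgcm_design(c(0, 2, 4)), -4)  # anchor intercept at last wave
#' center_design(lgcm_design(0:4))
#' @export
shift_design <- function(design, delta) {
  design <- as_lgcm_design(design)
  stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta))
  lgcm_design(design$times + delta, n = design$n)
}

#' @rdname shift_design
#' @export
scale_design <- function(design, factor) {
  design <- as_lgcm_design(design)
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0)
    stop("'factor' must be a single positive number", call. = FALSE)
  lgcm_design(design$times * factor, n = design$n)
}

#' @rdname shift_design
#' @export
center_design <- function(design) {
  design <- as_lgcm_design(design)
  shift_design(design, -mean(design$times))
}

#' Occasion spread of a design
#'
#' Returns the sum of squared deviations of the measurement times about
#' their mean (SST), the mean time, and the dispersion SST/(M-1) (the
#' sample variance of the occasion times). SST is the design quantity that
#' drives growth rate reliability and is invariant under time shifts.
#'
#' @inheritParams lgcm_loadings
#' @return A list with components \code{sst} (years^2), \code{mean_time}
#'   (years) and \code{dispersion} (years^2).
#' @examples
#' design_sst(lgcm_design(c(0, 1, 3, 3.5, 4)))
#' @export
design_sst <- function(design) {
  design <- as_lgcm_design(design)
  t <- design$times
  tbar <- mean(t)
  sst <- sum((t - tbar)^2)
  list(sst = sst, mean_time = tbar, dispersion = sst / (length(t) - 1L))
}
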