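#' Read longitudinal data from CSV
#'
#' Two layouts are supported. Wide: one row per subject, header
#' \code{id,t<time1>,...,t<timeM>}, where the column names after the
#' leading \code{t} encode the occasion times in years (e.g. \code{t0,
#' t2.5, t5}). Long: header \code{id,time,value}, one row per measurement;
#' every subject must be observed on the same occasion grid (complete
#' data).
#'
#' @param path path to a CSV file.
#' @param format \code{"wide"} or \code{"long"}.
#' @param n optional sample-size override stored in the design.
#' @return An \code{\link{lgcm_sample}}.
#' @export
read_growth_csv <- function(path, format = c("wide", "long"), n = NULL) {
  format <- match.arg(format)
  dat <- utils::read.csv(path, check.names = FALSE)
  if (format == "wide") {
    if (names(dat)[1] != "id")
      stop("wide CSV must start with an 'id' column", call. = FALSE)
    tcols <- names(dat)[-1]
    if (!all(grepl("^t", tcols)))
      stop("wide CSV occasion columns must be named t<time>", call. = FALSE)
    times <- as.numeric(sub("^t", "", tcols))
    if (anyNA(times))
      stop("could not parse occasion times from column names", call. = FALSE)
    vals <- as.matrix(dat[, -1, drop = FALSE])
  } else {
    need <- c("id", "time", "value")
    if (!all(need %in% names(dat)))
      stop("long CSV must have columns id, time, value", call. = FALSE)
    times <- sort(unique(dat$time))
    ids <- unique(dat$id)
    tab <- table(dat$id, dat$time)
    if (any(tab != 1L))
      stop("long CSV must be complete: every subject measured exactly once ",
           "at every occasion", call. = FALSE)
    vals <- matrix(NA_real_, length(ids), length(times),
                   dimnames = list(NULL, paste0("t", times)))
    for (j in seq_along(times)) {
      sub_j <- dat[dat$time == times[j], ]
      vals[, j] <- sub_j$value[match(ids, sub_j$id)]
    }
  }
  if (anyNA(vals))
    stop("missing cells found: only complete designs are supported",
         call. = FALSE)
  lgcm_sample(vals, lgcm_design(times, n = n))
}

#' Write a longitudinal sample to wide CSV
#'
#' @param sample an \code{\link{lgcm_sample}}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_growth_csv <- function(sample, path) {
  stopifnot(inherits(sample, "lgcm_sample"))
  df <- data.frame(id = seq_len(nrow(sample$values)), sample$values,
                   check.names = FALSE)
  names(df)[-1] <- paste0("t", fmt_times(sample$design$times))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scenario configuration from YAML
#'
#' A scenario bundles a design, population parameters and a seed:
#' keys \code{design.times}, \code{design.n},
#' \code{params.\{mu_i, mu_s, var_i, var_s, cov_is, var_e\}} and
#' \code{seed}. Unspecified parameters default to zero (means) or must be
#' given (variances used by downstream calls will error if degenerate).
#'
#' @param path path to a YAML file.
#' @return A list with elements \code{design} (an
#'   \code{\link{lgcm_design}}), \code{params} (an
#'   \code{\link{lgcm_params}}) and \code{seed} (integer or NULL).
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$design$times))
    stop("scenario must provide design.times", call. = FALSE)
  # YAML 1.1 reads a bare key `n` as a boolean; accept either spelling
  nval <- y$design$n
  if (is.null(nval)) nval <- y$design[["FALSE"]]
  design <- lgcm_design(unlist(y$design$times), n = nval)
  p <- y$params
  gv <- function(key) if (is.null(p[[key]])) 0 else as.numeric(p[[key]])
  params <- lgcm_params(mu_intercept = gv("mu_i"), mu_slope = gv("mu_s"),
                        var_intercept = gv("var_i"),
                        var_slope = gv("var_s"),
                        cov_intercept_slope = gv("cov_is"),
                        var_residual = gv("var_e"))
  list(design = design, params = params,
       seed = if (is.null(y$seed)) NULL else as.integer(y$seed))
}
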