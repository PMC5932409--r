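# Worked-example parameter sets used across tests.

# Memory study planned from reliability 0.9 / 3-year stability 0.85
# (T-score scaling): intercept 90, residual 10, implied slope var 1.35,
# three equally spaced occasions over five years.
case1 <- function() {
  list(design = lgcm_design(c(0, 2.5, 5)),
       params = lgcm_params(var_intercept = 90, var_slope = 1.35,
                            var_residual = 10))
}

# Two published studies measured quarterly over one year, shared intercept
# variance 90; they differ in residual and slope variance.
case2 <- function() {
  list(design = lgcm_design(c(0, 0.25, 0.5, 0.75, 1)),
       study_a = lgcm_params(var_intercept = 90, var_slope = 3,
                             var_residual = 5.9),
       study_b = lgcm_params(var_intercept = 90, var_slope = 5,
                             var_residual = 10))
}

# Five annual occasions, intercept 10, slope 1, residual 50.
case3 <- function() {
  list(design = lgcm_design(0:4, n = 100),
       params = lgcm_params(var_intercept = 10, var_slope = 1,
                            var_residual = 50),
       alt_designs = list(lgcm_design(c(0, 0.5, 1, 3, 4), n = 100),
                          lgcm_design(c(0, 1, 3, 3.5, 4), n = 100)))
}

# Random zero-covariance scenario for property tests (call under a set seed).
random_scenario <- function(max_m = 6) {
  m <- sample(3:max_m, 1)
  times <- sort(round(runif(m, 0, 8), 2))
  while (any(diff(times) < 0.05)) times <- sort(round(runif(m, 0, 8), 2))
  list(design = lgcm_design(times),
       params = lgcm_params(mu_intercept = runif(1, -10, 10),
                            mu_slope = runif(1, -2, 2),
                            var_intercept = runif(1, 1, 100),
                            var_slope = runif(1, 0.1, 5),
                            var_residual = runif(1, 1, 60)))
}

# A sample whose ML sample moments (mean, covariance with 1/n divisor)
# exactly equal the implied moments of `params` -- "perfect data" at which
# the ML criterion attains its global minimum at the generating values.
perfect_sample <- function(design, params, n = 200, seed = 42) {
  set.seed(seed)
  mom <- implied_moments(design, params)
  M <- length(design$times)
  x0 <- matrix(rnorm(n * M), n, M)
  x0 <- sweep(x0, 2, colMeans(x0))
  s0 <- crossprod(x0) / n
  x <- x0 %*% solve(chol(s0)) %*% chol(mom$cov)
  x <- sweep(x, 2, mom$mean, `+`)
  lgcm_sample(x, design)
}
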