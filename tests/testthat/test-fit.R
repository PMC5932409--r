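test_that("ML fit recovers the truth exactly from perfect data", {
  p <- lgcm_params(mu_intercept = 50, mu_slope = -1, var_intercept = 10,
                   var_slope = 1, cov_intercept_slope = 0.8,
                   var_residual = 50)
  s <- perfect_sample(lgcm_design(0:4), p, n = 200)
  fit <- lgcm_fit(s, se = FALSE)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates),
               c(50, -1, 10, 1, 0.8, 50), tolerance = 1e-5)
})

test_that("constrained parameters are honored and reported at their values", {
  p <- lgcm_params(mu_intercept = 5, var_intercept = 10, var_slope = 1,
                   var_residual = 50)
  s <- simulate_sample(lgcm_design(0:4), p, n = 150, seed = 21)
  fit <- lgcm_fit(s, constraints = c(var_slope = 0,
                                     cov_intercept_slope = 0), se = FALSE)
  expect_identical(unname(fit$estimates["var_slope"]), 0)
  expect_identical(unname(fit$estimates["cov_intercept_slope"]), 0)
  expect_true(fit$converged)
  # more free parameters cannot fit worse
  fit_free <- lgcm_fit(s, constraints = c(cov_intercept_slope = 0),
                       se = FALSE)
  expect_lte(fit_free$minus2LL, fit$minus2LL + 1e-6)
  expect_error(lgcm_fit(s, constraints = c(nonsense = 1)), "names")
})

test_that("parameters are recovered within 3 SE at large N", {
  p <- lgcm_params(mu_intercept = 50, mu_slope = -1, var_intercept = 10,
                   var_slope = 1, cov_intercept_slope = 1,
                   var_residual = 50)
  s <- simulate_sample(lgcm_design(0:4), p, n = 5000, seed = 77)
  fit <- lgcm_fit(s)
  truth <- unlist(p)[names(fit$estimates)]
  expect_true(fit$converged)
  expect_true(all(abs(fit$estimates - truth) < 3 * fit$se))
})

test_that("ML deviance matches the mixed-model oracle", {
  p <- lgcm_params(mu_intercept = 20, mu_slope = 1, var_intercept = 10,
                   var_slope = 2, cov_intercept_slope = 1,
                   var_residual = 20)
  s <- simulate_sample(lgcm_design(0:4), p, n = 300, seed = 5)
  fit <- lgcm_fit(s, se = FALSE)
  long <- data.frame(
    id = rep(seq_len(nrow(s$values)), each = 5),
    time = rep(0:4, nrow(s$values)),
    value = as.vector(t(s$values)))
  lf <- lme4::lmer(value ~ time + (1 + time | id), data = long, REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
  expect_equal(fit$minus2LL, as.numeric(deviance(lf)), tolerance = 1e-5)
  vc <- lme4::VarCorr(lf)$id
  expect_equal(unname(fit$estimates["var_intercept"]), vc[1, 1],
               tolerance = 1e-3)
  expect_equal(unname(fit$estimates["var_slope"]), vc[2, 2],
               tolerance = 1e-3)
})

test_that("fit methods expose the usual modelling interface", {
  p <- lgcm_params(mu_intercept = 10, mu_slope = 0.5, var_intercept = 10,
                   var_slope = 1, var_residual = 30)
  s <- simulate_sample(lgcm_design(0:3), p, n = 120, seed = 31)
  fit <- lgcm_fit(s, constraints = c(cov_intercept_slope = 0))
  expect_named(coef(fit))
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), -fit$minus2LL / 2)
  expect_equal(attr(ll, "df"), 5L)
  expect_equal(dim(vcov(fit)), c(5L, 5L))
  expect_length(fitted(fit), 4L)
  sim <- simulate(fit, seed = 2, n_subjects = 17)
  expect_s3_class(sim, "lgcm_sample")
  expect_equal(nrow(sim$values), 17L)
  expect_output(print(fit), "latent growth curve")
  expect_output(print(summary(fit)), "std_error")
})

test_that("LR statistics are non-negative and zero under no misfit", {
  p0 <- lgcm_params(mu_intercept = 5, var_intercept = 10, var_residual = 50)
  s <- perfect_sample(lgcm_design(0:4), p0, n = 150, seed = 3)
  tst <- lr_test(s, "specific_1df")
  expect_equal(tst$statistic, 0, tolerance = 1e-5)
  tst2 <- lr_test(s, "generalized_2df")
  expect_equal(tst2$statistic, 0, tolerance = 1e-5)
  expect_equal(tst2$df, 2L)

  p1 <- lgcm_params(var_intercept = 10, var_slope = 1, var_residual = 50)
  s1 <- simulate_sample(lgcm_design(0:4), p1, n = 200, seed = 8)
  t1 <- lr_test(s1, "specific_1df")
  expect_gte(t1$statistic, 0)
  expect_equal(t1$p_value,
               pchisq(t1$statistic, 1, lower.tail = FALSE))
})

test_that("Wald test tracks a dominant slope-variance signal", {
  p <- lgcm_params(var_intercept = 5, var_slope = 4, var_residual = 0.5)
  s <- simulate_sample(lgcm_design(0:4), p, n = 300, seed = 12)
  w <- wald_test(lgcm_fit(s, constraints = c(cov_intercept_slope = 0)))
  expect_gt(w$statistic, 10)
  expect_lt(w$p_value, 1e-10)
  # requesting Wald on a slope-fixed fit is an error
  f0 <- lgcm_fit(s, constraints = c(var_slope = 0,
                                    cov_intercept_slope = 0), se = FALSE)
  expect_error(wald_test(f0), "free slope variance")
})

test_that("fitting refuses unidentified or underdetermined input", {
  p <- lgcm_params(var_intercept = 10, var_slope = 1, var_residual = 50)
  s2 <- simulate_sample(lgcm_design(0:1), p, n = 50, seed = 1)
  expect_error(lgcm_fit(s2), "at least 3")
  s3 <- simulate_sample(lgcm_design(0:3), p, n = 5, seed = 1)
  expect_error(lgcm_fit(s3), "more subjects")
})
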