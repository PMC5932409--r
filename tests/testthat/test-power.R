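test_that("noncentrality from ECR matches direct evaluation", {
  expect_equal(noncentrality_from_ecr(0, 50), 0)
  e <- 0.2857143
  expect_equal(noncentrality_from_ecr(e, 100),
               100 * (1 / (1 - e) - log(1 / (1 - e)) - 1))
  expect_equal(round(noncentrality_from_ecr(e, 100), 3), 6.353)
  # linear in N, increasing and convex in ECR
  expect_equal(noncentrality_from_ecr(0.4, 200),
               2 * noncentrality_from_ecr(0.4, 100))
  g <- vapply(seq(0.05, 0.9, by = 0.05),
              noncentrality_from_ecr, numeric(1), n_subjects = 1)
  expect_true(all(diff(g) > 0))
  expect_true(all(diff(diff(g)) > 0))
  expect_error(noncentrality_from_ecr(1, 10), "\\[0, 1\\)")
})

test_that("the printed small-effect shorthand is evaluated verbatim", {
  expect_equal(noncentrality_approx(0, 100), 0)
  expect_equal(round(noncentrality_approx(0.2857, 100), 2), 11.43)
  # its leading Taylor coefficient is twice that of the exact expression
  ratio <- noncentrality_approx(1e-4, 1) / noncentrality_from_ecr(1e-4, 1)
  expect_equal(ratio, 2, tolerance = 1e-3)
})

test_that("population noncentrality vanishes when the null is true", {
  p0 <- lgcm_params(var_intercept = 10, var_residual = 50)
  expect_equal(satorra_saris_lambda(lgcm_design(0:4), p0,
                                    n_subjects = 100), 0)
  expect_equal(satorra_saris_lambda(lgcm_design(0:4), p0,
                                    test = "generalized_2df",
                                    nuisance = "free",
                                    n_subjects = 100),
               0, tolerance = 1e-8)
})

test_that("discrepancy-based lambda equals the minimal-model formula", {
  c3 <- case3()
  e <- ecr(1, effective_error(c3$design, 10, 50))
  lam <- satorra_saris_lambda(c3$design, c3$params, n_subjects = 100)
  expect_equal(lam, noncentrality_from_ecr(e, 100), tolerance = 1e-6 * 100)
})

test_that("the 2-df test dominates the misspecified 1-df test under
           non-zero covariance", {
  p <- lgcm_params(var_intercept = 20, var_slope = 2,
                   cov_intercept_slope = 4, var_residual = 20)
  d <- lgcm_design(0:2)
  lam1 <- satorra_saris_lambda(d, p, test = "specific_1df",
                               nuisance = "free", n_subjects = 100)
  lam2 <- satorra_saris_lambda(d, p, test = "generalized_2df",
                               nuisance = "free", n_subjects = 100)
  expect_gte(lam2, lam1)
})

test_that("free-nuisance lambda never exceeds the fixed-true lambda", {
  set.seed(13)
  for (i in 1:5) {
    sc <- random_scenario()
    lf <- satorra_saris_lambda(sc$design, sc$params, nuisance = "free",
                               n_subjects = 100)
    lt <- satorra_saris_lambda(sc$design, sc$params, nuisance = "fixed_true",
                               n_subjects = 100)
    expect_lte(lf, lt + 1e-6)
  }
})

test_that("noncentral chi-square power behaves correctly at the edges", {
  expect_equal(power_from_lambda(0, 1, 0.05), 0.05)
  expect_equal(power_from_lambda(0, 2, 0.10), 0.10)
  expect_gt(power_from_lambda(1e4, 1, 0.05), 1 - 1e-12)
  expect_equal(round(power_from_lambda(6.353, 1, 0.05), 3), 0.712)
  expect_error(power_from_lambda(-1, 1, 0.05), ">= 0")
  expect_error(power_from_lambda(1, 3, 0.05), "1 or 2")
})

test_that("power agrees with simulated noncentral chi-square draws", {
  set.seed(99)
  lam <- 6.353; n_draw <- 1e5
  draws <- rchisq(n_draw, df = 1, ncp = lam)
  emp <- mean(draws > qchisq(0.95, 1))
  p <- power_from_lambda(lam, 1, 0.05)
  expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / n_draw))
  draws2 <- rchisq(n_draw, df = 2, ncp = 4)
  emp2 <- mean(draws2 > qchisq(0.95, 2))
  p2 <- power_from_lambda(4, 2, 0.05)
  expect_lt(abs(emp2 - p2), 3 * sqrt(p2 * (1 - p2) / n_draw))
})

test_that("boundary-mixture reference gives more power at equal lambda", {
  for (lam in c(0.5, 2, 6, 12)) {
    expect_gt(power_from_lambda(lam, 1, 0.05, "boundary_mixture"),
              power_from_lambda(lam, 1, 0.05, "plain"))
    expect_gt(power_from_lambda(lam, 2, 0.05, "boundary_mixture"),
              power_from_lambda(lam, 2, 0.05, "plain"))
  }
})

test_that("analytic power chains the closed-form quantities", {
  c3 <- case3()
  ap <- analytic_power(c3$design, c3$params, n_subjects = 100)
  expect_equal(round(ap$power, 3), 0.712)
  expect_equal(ap$df, 1L)
  expect_equal(round(ap$ecr, 4), 0.2857)
  # null-true inputs give power = alpha
  ap0 <- analytic_power(c3$design,
                        lgcm_params(var_intercept = 10, var_residual = 50),
                        n_subjects = 100)
  expect_equal(ap0$power, 0.05)
  # increasing in N
  pw <- vapply(c(50, 100, 200, 400), function(n)
    analytic_power(c3$design, c3$params, n_subjects = n)$power, numeric(1))
  expect_true(all(diff(pw) > 0))
  # non-zero covariance routes through the discrepancy construction
  pcv <- lgcm_params(var_intercept = 20, var_slope = 2,
                     cov_intercept_slope = 3, var_residual = 20)
  ap2 <- analytic_power(lgcm_design(0:2), pcv, n_subjects = 100,
                        test = "generalized_2df")
  expect_equal(ap2$df, 2L)
  expect_true(ap2$power > 0.05 && ap2$power <= 1)
})
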