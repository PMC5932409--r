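test_that("effective error reproduces the worked examples", {
  expect_equal(effective_error(lgcm_design(0:4), 10, 50), 2.5)
  expect_equal(round(effective_error(lgcm_design(c(0, 0.25, 0.5, 0.75, 1)),
                                     90, 5.9), 2), 9.20)
  expect_equal(round(effective_error(lgcm_design(c(0, 0.25, 0.5, 0.75, 1)),
                                     90, 10), 2), 15.33)
  # centered design: sum of times is zero, so it reduces to var_e / sum t^2
  expect_equal(effective_error(lgcm_design(-2:2), 10, 50), 5)
  # zero intercept variance: eta = 0 by continuity
  expect_equal(effective_error(lgcm_design(0:4), 0, 50), 50 / 30)
  expect_error(effective_error(lgcm_design(0:2), -1, 10), "non-negative")
})

test_that("ICC2 matches its definition and limits", {
  expect_equal(icc2(10, 50, 5), 0.5)
  expect_equal(icc2(0, 30, 4), 0)
  expect_equal(icc2(12, 0, 4), 1)
  expect_error(icc2(1, 1, 0), ">= 1")
  expect_error(icc2(0, 0, 3), "undefined")
  # equals M * eta
  M <- 5; vi <- 7; ve <- 13
  expect_equal(icc2(vi, ve, M), M / (M + ve / vi))
})

test_that("ECR and GRR reproduce the worked examples", {
  c1 <- case1()
  se1 <- effective_error(c1$design, 90, 10)
  expect_equal(round(ecr(1.35, se1), 2), 0.64)
  expect_equal(round(grr(1.35, 10, design_sst(c1$design)$sst), 2), 0.63)
  expect_equal(round(ecr(1, 2.5), 2), 0.29)
  expect_equal(round(grr(1, 50, 10), 2), 0.17)
  expect_equal(ecr(0, 3), 0)
  expect_error(ecr(0, 0), "undefined")
  expect_error(grr(1, 50, 0), "positive")
})

test_that("precision summary is internally consistent", {
  c3 <- case3()
  ps <- precision_summary(c3$design, c3$params)
  expect_equal(ps$effective_error, 2.5)
  expect_equal(round(ps$ecr, 2), 0.29)
  expect_equal(round(ps$grr, 2), 0.17)
  expect_equal(ps$icc2, 0.5)
  expect_equal(ps$ecr,
               c3$params$var_slope / (c3$params$var_slope +
                                        ps$effective_error))
  expect_equal(ps$dispersion * (length(c3$design$times) - 1), ps$sst)
  expect_equal(ps$special_case_error, 50 / 10)
})

test_that("effective error is monotone in its inputs", {
  d <- lgcm_design(0:4)
  # non-decreasing in residual variance and in intercept variance
  ve_grid <- seq(5, 80, by = 5)
  se_ve <- vapply(ve_grid, function(v) effective_error(d, 10, v), numeric(1))
  expect_true(all(diff(se_ve) > 0))
  vi_grid <- seq(0, 100, by = 5)
  se_vi <- vapply(vi_grid, function(v) effective_error(d, v, 50), numeric(1))
  expect_true(all(diff(se_vi) >= 0))
  # adding an occasion cannot hurt precision
  expect_lte(effective_error(lgcm_design(c(0:4, 5)), 10, 50),
             effective_error(d, 10, 50))
  # stretching the time axis improves precision quadratically
  expect_lt(effective_error(scale_design(d, 2), 10, 50),
            effective_error(d, 10, 50))
})

test_that("effective error is symmetric under time sign flip", {
  set.seed(7)
  for (i in 1:10) {
    sc <- random_scenario()
    flipped <- lgcm_design(rev(-sc$design$times))
    expect_equal(effective_error(sc$design, sc$params$var_intercept,
                                 sc$params$var_residual),
                 effective_error(flipped, sc$params$var_intercept,
                                 sc$params$var_residual))
  }
})

test_that("the centered design has the largest effective error over shifts", {
  set.seed(8)
  for (i in 1:8) {
    sc <- random_scenario()
    vi <- sc$params$var_intercept
    ve <- sc$params$var_residual
    center_shift <- -mean(sc$design$times)
    se_at <- function(delta)
      effective_error(shift_design(sc$design, delta), vi, ve)
    se_centered <- se_at(center_shift)
    for (delta in center_shift + c(-3, -1, -0.25, 0.25, 1, 3))
      expect_gte(se_centered + 1e-9, se_at(delta),
                 label = sprintf("centered se %g vs shifted se %g",
                                 se_centered, se_at(delta)))
  }
})

test_that("ECR collapses to GRR in the limiting cases", {
  d <- lgcm_design(0:4)
  vs <- 1; ve <- 50
  # centered design: sum t = 0
  dc <- center_design(d)
  se_c <- effective_error(dc, 10, ve)
  expect_equal(ecr(vs, se_c), grr(vs, ve, design_sst(dc)$sst))
  # ICC2 -> 1 (residual variance negligible relative to intercept variance)
  se_icc1 <- effective_error(d, 1e9, ve)
  expect_equal(ecr(vs, se_icc1), grr(vs, ve, design_sst(d)$sst),
               tolerance = 1e-6)
  # zero intercept variance with a centered design
  expect_equal(ecr(vs, effective_error(dc, 0, ve)),
               grr(vs, ve, design_sst(dc)$sst))
})

test_that("generalized ECR equals the closed form when covariance is zero", {
  set.seed(11)
  for (i in 1:10) {
    sc <- random_scenario()
    closed <- ecr(sc$params$var_slope,
                  effective_error(sc$design, sc$params$var_intercept,
                                  sc$params$var_residual))
    expect_equal(generalized_ecr(sc$design, sc$params), closed,
                 tolerance = 1e-6)
  }
  # no slope variance: restricted model is true, ECR is 0
  p0 <- lgcm_params(var_intercept = 10, var_residual = 50)
  expect_equal(generalized_ecr(lgcm_design(0:4), p0), 0)
})

test_that("2-df ECR responds to the intercept-slope correlation", {
  d <- lgcm_design(0:2)
  base <- list(vi = 20, vs = 2, ve = 20)
  e_at <- function(r) {
    cis <- r * sqrt(base$vi * base$vs)
    generalized_ecr(d, lgcm_params(var_intercept = base$vi,
                                   var_slope = base$vs,
                                   cov_intercept_slope = cis,
                                   var_residual = base$ve),
                    test = "generalized_2df")
  }
  # positive covariance amplifies the observable change signal monotonically
  vals_pos <- vapply(c(0, 0.25, 0.5, 0.75), e_at, numeric(1))
  expect_true(all(diff(vals_pos) > 0))
  # strong covariance of either sign carries more slope information than
  # none (mildly negative covariance can transiently mask it by flattening
  # the observed variance growth, so no global |r| monotonicity holds)
  expect_gt(e_at(-0.75), e_at(0))
  expect_gt(e_at(0.75), e_at(0))
})

test_that("precision summary handles non-zero covariance via the
           generalized route", {
  p <- lgcm_params(var_intercept = 20, var_slope = 2,
                   cov_intercept_slope = 3, var_residual = 20)
  ps <- precision_summary(lgcm_design(0:2), p)
  expect_true(ps$ecr > 0 && ps$ecr < 1)
  # back-solved effective error keeps ECR = vs / (vs + s_eff) exact
  expect_equal(ps$ecr, 2 / (2 + ps$effective_error))
})
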