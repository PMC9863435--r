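test_that("the bundled five-point fit reproduces the published model", {
  pts <- example_ivivc_points()
  m <- fit_level_c(pts)
  orc <- ols_oracle(pts$arc, pts$auc)
  expect_equal(m$slope, orc$slope, tolerance = 1e-12)
  expect_equal(m$intercept, orc$intercept, tolerance = 1e-12)
  expect_equal(m$r_squared, orc$r_squared, tolerance = 1e-12)
  expect_gte(m$r_squared, 0.9)
})

test_that("collinear points give an exact fit", {
  pts <- ivivc_points(c("a", "b", "c"), "r", c(1, 2, 3), c(3, 5, 7))
  m <- fit_level_c(pts)
  expect_equal(m$slope, 2, tolerance = 1e-12)
  expect_equal(m$intercept, 1, tolerance = 1e-12)
  expect_equal(m$r_squared, 1)
})

test_that("fit matches the normal-equations oracle on arbitrary inputs", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    pts <- ivivc_points(paste0("p", 1:n), "r", runif(n, 20, 60),
                        runif(n, 50, 110))
    m <- fit_level_c(pts)
    orc <- ols_oracle(pts$arc, pts$auc)
    expect_equal(m$slope, orc$slope, tolerance = 1e-10)
    expect_equal(m$intercept, orc$intercept, tolerance = 1e-10)
    # OLS identities: residuals orthogonal to ARC, fitted mean = observed
    resid <- pts$auc - predict_auc(m, pts$arc)
    expect_equal(sum(resid * pts$arc), 0, tolerance = 1e-7)
    expect_equal(mean(predict_auc(m, pts$arc)), mean(pts$auc),
                 tolerance = 1e-10)
  }
})

test_that("degenerate point sets are rejected", {
  expect_error(fit_level_c(ivivc_points(c("a", "b"), "r", c(1, 2), c(1, 2))),
               ">= 3")
  expect_error(fit_level_c(ivivc_points(c("a", "b", "c"), "r", rep(2, 3),
                                        1:3)), "zero variance")
  expect_error(ivivc_points("a", "r", -1, 5), "arc")
})

test_that("predictions reproduce the published table at 2 decimals", {
  pts <- example_ivivc_points()
  m <- fit_level_c(pts)
  expect_equal(round(predict_auc(m, pts$arc), 2),
               c(78.40, 71.62, 79.32, 64.07, 96.89))
  ident <- fit_level_c(ivivc_points(c("a", "b", "c"), "r", c(1, 2, 3),
                                    c(1, 2, 3)))
  expect_equal(predict_auc(ident, 7.3), 7.3, tolerance = 1e-12)
  expect_error(predict_auc(m, -5), "arc")
})

test_that("two-value prediction CV", {
  expect_equal(prediction_cv(77.46, 77.46)$max_cv, 0)
  expect_equal(round(prediction_cv(77.62, 71.62)$cv, 2), 5.69)
  pts <- example_ivivc_points()
  m <- fit_level_c(pts)
  cv <- prediction_cv(pts$auc, round(predict_auc(m, pts$arc), 2))
  expect_lt(cv$max_cv, 10)
  expect_error(prediction_cv(1, -1), "> 0")
  expect_error(prediction_cv(1:2, 1:3), "equal length")
})

test_that("weighted fit honours the weights", {
  pts <- ivivc_points(paste0("p", 1:4), "r", c(1, 2, 3, 4), c(2, 4, 6, 100))
  w <- c(1, 1, 1, 0)
  m <- fit_level_c(pts, weights = w)
  expect_equal(m$slope, 2, tolerance = 1e-10)
  expect_equal(m$intercept, 0, tolerance = 1e-10)
})
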