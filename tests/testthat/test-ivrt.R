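# Build an ivrt_run whose cells have exact Higuchi profiles by inverting
# the withdrawal bookkeeping independently of the package generator.
higuchi_run <- function(slopes, times = seq(15, 90, 15), intercept = 0,
                        cell_volume = 7.9, sample_volume = 0.2,
                        orifice_diameter = 15, product = "X",
                        role = "test") {
  area <- pi * (orifice_diameter / 10)^2 / 4
  conc <- t(vapply(slopes, function(s) {
    amount <- (s * sqrt(times) + intercept) * area
    C <- numeric(length(times))
    withdrawn <- 0
    for (n in seq_along(times)) {
      C[n] <- (amount[n] - withdrawn) / cell_volume
      withdrawn <- withdrawn + C[n] * sample_volume
    }
    C
  }, numeric(length(times))))
  ivrt_run(product, role, times, conc, cell_volume, sample_volume,
           orifice_diameter)
}

test_that("cumulative release applies the withdrawal correction", {
  cell0 <- list(cell_id = "c", times = seq(15, 90, 15), conc = rep(0, 6),
                cell_volume = 7.9, sample_volume = 0.2,
                orifice_area = 1.767)
  expect_equal(cumulative_release(cell0)$Q, rep(0, 6))
  # single sample: Q1 = C1 * V_cell / area
  cell1 <- list(cell_id = "c", times = 15, conc = 1, cell_volume = 7.9,
                sample_volume = 0.2, orifice_area = 1.767)
  expect_equal(cumulative_release(cell1)$Q, 7.9 / 1.767)
  # later samples add back the withdrawn drug
  cell2 <- list(cell_id = "c", times = c(15, 30), conc = c(1, 2),
                cell_volume = 10, sample_volume = 0.5, orifice_area = 2)
  expect_equal(cumulative_release(cell2)$Q, c(10 / 2, (2 * 10 + 1 * 0.5) / 2))
  cell_bad <- cell2; cell_bad$conc <- c(1, 2, 3)
  expect_error(cumulative_release(cell_bad), "3 concentrations")
})

test_that("Higuchi fit is exact on exact data and rejects degenerate input", {
  prof <- structure(list(cell_id = "c", times = seq(15, 90, 15),
                         Q = 37.80 * sqrt(seq(15, 90, 15))),
                    class = "release_profile")
  fit <- fit_higuchi(prof)
  expect_equal(fit$slope, 37.80, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  short <- structure(list(cell_id = "c", times = c(15, 30), Q = c(1, 2)),
                     class = "release_profile")
  expect_error(fit_higuchi(short), ">= 3 points")
  flat <- structure(list(cell_id = "c", times = rep(15, 4), Q = 1:4),
                    class = "release_profile")
  expect_error(fit_higuchi(flat), "zero variance")
})

test_that("Higuchi fit agrees with the normal-equations oracle", {
  set.seed(4)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    times <- sort(sample(5:200, n))
    Q <- runif(1, 5, 50) * sqrt(times) + rnorm(n, sd = 3)
    prof <- structure(list(cell_id = "c", times = times, Q = Q),
                      class = "release_profile")
    fit <- fit_higuchi(prof)
    orc <- ols_oracle(sqrt(times), Q)
    expect_equal(fit$slope, orc$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, orc$intercept, tolerance = 1e-10)
    expect_equal(fit$r_squared, orc$r_squared, tolerance = 1e-10)
    expect_equal(fit$slope_se, orc$slope_se, tolerance = 1e-10)
  }
})

test_that("time_window restricts the points used", {
  times <- seq(15, 90, 15)
  Q <- 30 * sqrt(times)
  Q[1] <- Q[1] + 20  # burst on the first point
  prof <- structure(list(cell_id = "c", times = times, Q = Q),
                    class = "release_profile")
  full <- fit_higuchi(prof)
  windowed <- fit_higuchi(prof, time_window = c(30, 90))
  expect_equal(windowed$slope, 30, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(full$slope, 30)))
  expect_equal(windowed$n, 5)
})

test_that("run-level ARC summarises per-cell slopes", {
  slopes <- c(36, 37, 38, 39, 40, 36.8)
  res <- run_arc(higuchi_run(slopes))
  expect_equal(res$cells$slope, slopes, tolerance = 1e-9)
  expect_equal(res$arc_mean, 37.8, tolerance = 1e-9)
  expect_equal(res$arc_sd, sqrt(sum((slopes - 37.8)^2) / 5),
               tolerance = 1e-9)
  same <- run_arc(higuchi_run(rep(35, 6)))
  expect_equal(same$arc_mean, 35, tolerance = 1e-9)
  expect_equal(same$arc_sd, 0, tolerance = 1e-9)
})

test_that("ARC is scale-equivariant in the concentrations", {
  cfg <- ivrt_sim_config(true_arc = 38, seed = 8)
  run <- simulate_ivrt_run(cfg, "X")
  scaled <- run
  scaled$conc <- run$conc * 3
  expect_equal(run_arc(scaled)$arc_mean, 3 * run_arc(run)$arc_mean,
               tolerance = 1e-12)
})

test_that("ratio of a run with itself is 1 and the CI behaves", {
  run <- higuchi_run(c(36, 37, 38, 39, 40, 36.8))
  res <- run_arc(run)
  ci <- release_ratio_ci(res, res)
  expect_equal(ci$ratio, 1, tolerance = 1e-12)
  expect_lte(ci$lower, 1)
  expect_gte(ci$upper, 1)
  expect_equal(ci$level, 0.90)
  fe <- release_ratio_ci(res, res, method = "fieller")
  expect_lte(fe$lower, 1); expect_gte(fe$upper, 1)
  bad <- res
  bad$cells$slope[1] <- -1
  expect_error(release_ratio_ci(bad, res), "fieller")
  expect_error(release_ratio_ci(res, res, level = 1.1), "level")
})
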