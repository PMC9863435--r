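test_that("strip masses are post minus pre with tolerance handling", {
  s <- strip_site("P01", "A", "A", pre_weight = c(1000, 1000, 1000),
                  post_weight = c(1380, 1000, 999.5),
                  drug_amount = c(1, 2, 3))
  expect_warning(m <- strip_masses(s), "clipping")
  expect_equal(m, c(380, 0, 0))
  bad <- strip_site("P01", "A", "A", pre_weight = c(1000, 1000),
                    post_weight = c(1100, 990), drug_amount = c(1, 1))
  expect_error(strip_masses(bad), "strip 2")
  expect_error(strip_site("P01", "A", "A", pre_weight = c(1000, NA),
                          post_weight = c(1100, 1100),
                          drug_amount = c(1, 1)), "strip index 2")
})

test_that("TEWL thickness estimator inverts exact series and flags flat ones", {
  L0 <- 10
  # exact model: TEWL = C / (L0 - x), arbitrary C
  for (C in c(50, 120)) {
    mass <- cumsum(rep(200, 15))                  # ug on 4 cm^2 -> 0.5 um each
    x <- mass / (4 * 1) * 1e-2
    ser <- tewl_series("P01", mass, C / (L0 - x))
    expect_equal(estimate_sc_thickness_tewl(ser, 4, 1), L0,
                 tolerance = 1e-9)
  }
  flat <- tewl_series("P01", cumsum(rep(200, 5)), rep(8, 5))
  expect_error(estimate_sc_thickness_tewl(flat, 4, 1), "not identifiable")
  two <- tewl_series("P01", c(100, 200), c(8, 9))
  expect_error(estimate_sc_thickness_tewl(two, 4, 1), ">= 3")
})

test_that("noisy TEWL recovery: median thickness error under 5%", {
  set.seed(314)
  L0 <- 10
  mass <- cumsum(rep(200, 15))
  x <- mass / (4 * 1) * 1e-2
  errs <- replicate(500, {
    tewl <- 60 / (L0 - x) * exp(rnorm(15, sd = sqrt(log(1 + 0.05^2))))
    abs(estimate_sc_thickness_tewl(tewl_series("P", mass, tewl), 4, 1) -
          L0) / L0
  })
  expect_lt(median(errs), 0.05)
})

test_that("relative depth profile places strips at interval midpoints", {
  # 20 equal strips removing exactly L = 10 um from 4 cm^2 at density 1:
  # each strip removes 200 ug
  s <- strip_site("P01", "A", "A", pre_weight = rep(22000, 20),
                  post_weight = rep(22200, 20), drug_amount = rep(1, 20))
  prof <- relative_depth_profile(s, L = 10)
  expect_equal(prof$points$relative_depth_percent, seq(2.5, 97.5, by = 5))
  expect_equal(prof$total_depth_percent, 100)
  expect_false(any(prof$points$beyond_sc[-20]))
  # leading/trailing positions and first-strip exclusion
  lead <- relative_depth_profile(s, L = 10, position = "leading")
  expect_equal(lead$points$relative_depth_percent[1], 0)
  dropped <- relative_depth_profile(s, L = 10, drop_first_n = 2)
  expect_equal(nrow(dropped$points), 18)
  expect_equal(dropped$points$strip_index[1], 3)
  # strips past 100% of L are flagged, gross inconsistency raises
  deep <- relative_depth_profile(s, L = 8)
  expect_true(any(deep$points$beyond_sc))
  expect_error(relative_depth_profile(s, L = 6), "150%")
})

test_that("profile AUC matches the trapezoid oracle and its properties", {
  expect_equal(profile_auc(make_profile(c(0, 100), c(10, 10))), 1000)
  expect_equal(profile_auc(make_profile(seq(5, 95, 10), rep(0, 10))), 0)
  set.seed(9)
  for (i in 1:15) {
    n <- sample(4:25, 1)
    x <- sort(runif(n, 0, 100))
    y <- runif(n, 0, 20)
    p <- make_profile(x, y)
    expect_equal(profile_auc(p), trapz_oracle(x, y), tolerance = 1e-9)
    # linearity in drug amounts
    expect_equal(profile_auc(make_profile(x, 2 * y)), 2 * profile_auc(p),
                 tolerance = 1e-12)
    # inserting a collinear point changes nothing
    j <- sample(n - 1, 1)
    xm <- (x[j] + x[j + 1]) / 2
    ym <- (y[j] + y[j + 1]) / 2
    expect_equal(profile_auc(make_profile(sort(c(x, xm)),
                                          append(y, ym, after = j))),
                 profile_auc(p), tolerance = 1e-9)
  }
  expect_error(profile_auc(make_profile(c(10, 10, 20), c(1, 2, 3))),
               "increasing")
  # zero-anchoring adds the leading and trailing triangles
  p <- make_profile(c(25, 75), c(10, 10), total_depth_percent = 100)
  expect_equal(profile_auc(p, anchor_zero = TRUE), 500 + 125 + 125)
})

test_that("depth conversion conserves stripped mass", {
  cfg <- ts_sim_config(seed = 55)
  st <- simulate_tape_strip_study(cfg, "A", c(A = 0.75))
  s <- st$sites[["P03.A"]]
  prof <- relative_depth_profile(s, L = 12, sc_density = cfg$sc_density)
  # total depth (um -> cm) times area times density returns total mass (g)
  back <- prof$total_depth_um * 1e-4 * cfg$site_area * cfg$sc_density * 1e6
  expect_equal(back, sum(strip_masses(s)), tolerance = 1e-9)
})

test_that("study AUC summarises participants and handles blanks", {
  p1 <- make_profile(c(10, 30), c(4, 2), participant = "P01")
  p2 <- make_profile(c(10, 30), c(5, 3), participant = "P02")
  # AUCs: 20*(4+2)/2 = 60 and 20*(5+3)/2 = 80
  res <- study_auc(list(p1, p2))
  expect_equal(res$auc_mean, 70)
  expect_equal(res$auc_sd, sqrt((100 + 100) / 1))
  expect_equal(res$auc_sd, 14.142136, tolerance = 1e-6)
  same <- study_auc(list(p1, p1, p2))  # replicate averaged within P01
  expect_equal(same$n_participants, 2)
  expect_equal(same$auc_mean, 70)
  unaveraged <- study_auc(list(p1, p1, p2), average_replicates = FALSE)
  expect_equal(unaveraged$n_participants, 3)
  # doubling drug doubles the mean exactly
  d1 <- make_profile(c(10, 30), c(8, 4), participant = "P01")
  d2 <- make_profile(c(10, 30), c(10, 6), participant = "P02")
  expect_equal(study_auc(list(d1, d2))$auc_mean, 140)
  # blank subtraction
  blanks <- list(P01 = rep(1, 2), P02 = rep(1, 2))
  sub <- study_auc(list(p1, p2), blanks = blanks)
  expect_equal(sub$auc_mean, 50)
  expect_error(study_auc(list(p1, p2), blanks = list(P01 = rep(1, 2))),
               "P02")
  expect_error(study_auc(list(p1)), ">= 2")
  pX <- make_profile(c(10, 30), c(1, 1), product = "Y")
  expect_error(study_auc(list(p1, pX)), "several products")
})

test_that("thickness estimator error shrinks with the TEWL noise", {
  set.seed(2718)
  mass <- cumsum(rep(200, 15))
  x <- mass / (4 * 1) * 1e-2
  med_err <- vapply(c(0.10, 0.05, 0.01), function(cv) {
    median(replicate(200, {
      tewl <- 60 / (10 - x) * exp(rnorm(15, sd = sqrt(log(1 + cv^2))))
      abs(estimate_sc_thickness_tewl(tewl_series("P", mass, tewl), 4, 1) - 10)
    }))
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
  expect_lt(med_err[3], 0.05)
})
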