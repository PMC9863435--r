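test_that("config validation enforces the physical constraints", {
  expect_error(ts_sim_config(n_strips = 2), "n_strips")
  expect_error(ts_sim_config(site_area = 0), "site_area")
  expect_error(ts_sim_config(strip_mass_decay = 1.2), "strip_mass_decay")
  # stripping must not imply removing more SC than the barrier holds:
  # 400 ug/strip over 20 strips would overrun a 10 um SC on 4 cm^2
  expect_error(ts_sim_config(strip_mass_first = 400), "SC mass")
  expect_error(
    simulate_tape_strip_study(ts_sim_config(seed = 1), c("A", "B"),
                              c(A = 1)), "product_scale")
})

zero_noise_cfg <- function(seed = 5, ...)
  ts_sim_config(drug_noise_cv = 0, tewl_noise_cv = 0, strip_mass_cv = 0,
                sc_thickness_cv = 0, seed = seed, ...)

test_that("drug amounts are exactly linear in the product scale", {
  cfg <- zero_noise_cfg()
  st <- simulate_tape_strip_study(cfg, c("lo", "hi"), c(lo = 0.4, hi = 0.8))
  for (p in paste0("P", sprintf("%02d", 1:10))) {
    lo <- st$sites[[paste0(p, ".lo")]]$strips$drug_amount
    hi <- st$sites[[paste0(p, ".hi")]]$strips$drug_amount
    expect_equal(hi, 2 * lo, tolerance = 1e-12)
  }
})

test_that("zero-noise TEWL series inverts to the drawn thickness", {
  cfg <- ts_sim_config(tewl_noise_cv = 0, sc_thickness_cv = 0.2, seed = 21)
  st <- simulate_tape_strip_study(cfg, "A", c(A = 0.75))
  for (p in names(st$tewl)) {
    L_hat <- estimate_sc_thickness_tewl(st$tewl[[p]], cfg$site_area,
                                        cfg$sc_density)
    expect_equal(L_hat, unname(st$truth$sc_thickness_um[p]),
                 tolerance = 1e-9)
  }
})

test_that("zero-noise round trip: masses, amounts and depth bookkeeping", {
  cfg <- zero_noise_cfg()
  st <- simulate_tape_strip_study(cfg, "A", c(A = 0.75))
  s <- st$sites[["P01.A"]]
  expected_masses <- cfg$strip_mass_first *
    (1 - cfg$strip_mass_decay)^(0:(cfg$n_strips - 1))
  expect_equal(strip_masses(s), expected_masses, tolerance = 1e-12)
  expect_equal(s$strips$drug_amount, st$truth$drug_amounts[["P01.A"]],
               tolerance = 1e-12)
  # per-strip amounts equal the depth integral of the exported
  # concentration profile (independent numerical quadrature)
  L_um <- st$truth$sc_thickness_um[["P01"]]
  L_cm <- L_um * 1e-4
  depth_frac <- cumsum(expected_masses) * 1e-6 /
    (cfg$site_area * cfg$sc_density) / L_cm
  bounds <- c(0, depth_frac)
  amt_oracle <- vapply(seq_len(cfg$n_strips), function(i) {
    stats::integrate(function(X)
      sc_concentration_profile(X, cfg$application_time,
                               cfg$partition_surface_conc * 0.75,
                               cfg$diffusivity_ratio),
      bounds[i], bounds[i + 1], rel.tol = 1e-10)$value *
      cfg$site_area * L_cm
  }, numeric(1))
  expect_equal(s$strips$drug_amount, amt_oracle, tolerance = 1e-7)
})

test_that("mass and dose sanity at default noise", {
  cfg <- ts_sim_config(seed = 31)
  st <- simulate_tape_strip_study(cfg, names(mtz_scales), mtz_scales)
  for (key in names(st$sites)) {
    s <- st$sites[[key]]
    expect_true(all(s$strips$drug_amount >= 0))
    dose_ug <- cfg$dose_mass * 1000 * mtz_scales[[s$product_id]] / 100
    expect_lte(sum(s$strips$drug_amount), dose_ug)
  }
})

test_that("identical seeds give byte-identical datasets and files", {
  cfg <- ts_sim_config(seed = 77)
  a <- simulate_tape_strip_study(cfg, "A", c(A = 0.75))
  b <- simulate_tape_strip_study(cfg, "A", c(A = 0.75))
  expect_identical(a$sites, b$sites)
  expect_identical(a$tewl, b$tewl)
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  write_tape_strip_csv(a$sites, fa)
  write_tape_strip_csv(b$sites, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("study AUC variability sits in the plausible between-subject band", {
  # a single 10-participant draw has a noisy sample CV, so the check is
  # on the median CV over a handful of studies
  cvs <- vapply(1:5, function(seed) {
    cfg <- ts_sim_config(seed = seed)
    st <- simulate_tape_strip_study(cfg, "Reference", c(Reference = 0.75))
    L <- suppressWarnings(estimate_sc_thickness_all(
      st$tewl, cfg$site_area, cfg$sc_density,
      on_unidentifiable = "exclude"))
    profs <- lapply(Filter(function(s) s$participant_id %in% names(L),
                           st$sites),
                    function(s) relative_depth_profile(
                      s, L[[s$participant_id]], cfg$sc_density))
    res <- study_auc(profs)
    res$auc_sd / res$auc_mean
  }, numeric(1))
  expect_gt(median(cvs), 0.10)
  expect_lt(median(cvs), 0.30)
})

test_that("unidentifiable thickness excludes the participant on request", {
  flat <- tewl_series("P99", cumsum(rep(200, 5)), rep(8, 5))
  good <- tewl_series("P01", cumsum(rep(200, 10)),
                      60 / (10 - cumsum(rep(200, 10)) / 4 * 1e-2))
  expect_error(estimate_sc_thickness_all(list(good, flat), 4), "P99")
  expect_warning(
    L <- estimate_sc_thickness_all(list(good, flat), 4,
                                   on_unidentifiable = "exclude"), "P99")
  expect_named(L, "P01")
  expect_equal(unname(L), 10, tolerance = 1e-9)
})
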