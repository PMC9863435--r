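#' Configuration for a simulated tape-stripping study
#'
#' Defaults mirror the in vivo design the analysis targets: 10 healthy
#' participants, 2 x 2 cm sites, ~15 mg of cream applied for 60 min,
#' then 20 sequential pre-weighed tape strips per site, with stratum
#' corneum (SC) thickness per participant obtained from TEWL measured on
#' a blank site.
#'
#' The drug-depth profile is the transient Fickian series solution for a
#' membrane with constant surface concentration `K*Cv` and a sink at the
#' SC-viable-epidermis boundary (see [sc_concentration_profile()]), which
#' guarantees profiles decreasing in depth. The per-strip SC mass follows
#' a geometrically decaying mean with lognormal noise, the well-known
#' decline in SC removed per successive strip. TEWL is inversely
#' proportional to remaining SC thickness (Fick steady state), which is
#' what the 1/TEWL linear-extrapolation thickness estimator inverts.
#'
#' @param n_participants Number of participants.
#' @param n_strips Strips per site (>= 3).
#' @param site_area Application site area, cm^2.
#' @param dose_mass Applied cream mass, mg (used for the mass-balance
#'   sanity bound: recovered drug must not exceed the applied drug dose).
#' @param application_time Application duration, minutes.
#' @param sc_thickness_mean,sc_thickness_cv Mean (um) and CV of the
#'   per-participant SC thickness (lognormal).
#' @param strip_mass_first Mean SC mass on the first strip, ug.
#' @param strip_mass_decay Fractional decay of mean strip mass per strip.
#' @param strip_mass_cv Lognormal CV of individual strip masses.
#' @param sc_density SC density, g/cm^3.
#' @param partition_surface_conc Drug concentration in the outermost SC,
#'   `K*Cv` (partition coefficient times vehicle concentration), ug/cm^3,
#'   for a product of unit strength scale; scales the whole profile.
#' @param diffusivity_ratio `D/L^2`, 1/min. The default 0.002/min makes
#'   the 60-min profile clearly non-steady-state (characteristic time
#'   `L^2/D` = 500 min >> 60 min).
#' @param drug_noise_cv Multiplicative CV on per-strip drug amounts.
#' @param tewl_noise_cv Multiplicative CV on TEWL readings.
#' @param tewl_baseline Pre-stripping TEWL of intact SC, g/m^2/h.
#' @param seed Integer seed; local RNG scope.
#'
#' @return A validated list of class `ts_sim_config`.
#' @export
ts_sim_config <- function(n_participants = 10L,
                          n_strips = 20L,
                          site_area = 4.0,
                          dose_mass = 15,
                          application_time = 60,
                          sc_thickness_mean = 10,
                          sc_thickness_cv = 0.2,
                          strip_mass_first = 150,
                          strip_mass_decay = 0.05,
                          strip_mass_cv = 0.10,
                          sc_density = 1.0,
                          partition_surface_conc = 32500,
                          diffusivity_ratio = 0.002,
                          drug_noise_cv = 0.05,
                          tewl_noise_cv = 0.05,
                          tewl_baseline = 8,
                          seed = NULL) {
  n_participants <- check_count(n_participants, "n_participants", lower = 2L)
  n_strips <- check_count(n_strips, "n_strips", lower = 3L)
  for (f in c("site_area", "dose_mass", "application_time",
              "sc_thickness_mean", "strip_mass_first", "sc_density",
              "partition_surface_conc", "diffusivity_ratio",
              "tewl_baseline"))
    check_number(get(f), f, lower = 0, strict_lower = TRUE)
  check_number(strip_mass_decay, "strip_mass_decay", lower = 0, upper = 1)
  for (f in c("sc_thickness_cv", "strip_mass_cv", "drug_noise_cv",
              "tewl_noise_cv"))
    check_number(get(f), f, lower = 0)
  seed <- check_seed(seed)

  # The expected total SC removed must stay below the SC mass implied by
  # the mean thickness, otherwise depths overrun the barrier.
  expected_total <- if (strip_mass_decay > 0) {
    strip_mass_first * (1 - (1 - strip_mass_decay)^n_strips) / strip_mass_decay
  } else strip_mass_first * n_strips
  implied_sc_mass <- sc_thickness_mean * 1e-4 * site_area * sc_density * 1e6
  if (expected_total >= implied_sc_mass)
    stop_field("strip_mass_first",
               sprintf(paste("expected total strip mass (%.0f ug) must be",
                             "below the SC mass implied by thickness x area",
                             "x density (%.0f ug)"),
                       expected_total, implied_sc_mass))

  structure(
    list(n_participants = n_participants, n_strips = n_strips,
         site_area = site_area, dose_mass = dose_mass,
         application_time = application_time,
         sc_thickness_mean = sc_thickness_mean,
         sc_thickness_cv = sc_thickness_cv,
         strip_mass_first = strip_mass_first,
         strip_mass_decay = strip_mass_decay,
         strip_mass_cv = strip_mass_cv, sc_density = sc_density,
         partition_surface_conc = partition_surface_conc,
         diffusivity_ratio = diffusivity_ratio,
         drug_noise_cv = drug_noise_cv, tewl_noise_cv = tewl_noise_cv,
         tewl_baseline = tewl_baseline, seed = seed),
    class = "ts_sim_config")
}

#' Transient drug concentration across the stratum corneum
#'
#' Fickian diffusion into a membrane of thickness `L` with constant
#' surface concentration `K*Cv` at `x = 0` and a perfect sink at `x = L`,
#' starting from a drug-free membrane:
#' \deqn{C(x,t) = K C_v \left[(1 - x/L) - \frac{2}{\pi} \sum_{n \ge 1}
#'   \frac{1}{n} \sin(n\pi x/L)\, e^{-n^2 \pi^2 (D/L^2) t}\right]}
#' The series is truncated once the envelope of the remaining terms falls
#' below `tol`.
#'
#' @param depth_fraction Relative depth `x/L` in `[0, 1]`; vectorised.
#' @param time Time since application, minutes (> 0).
#' @param partition_surface_conc Surface concentration `K*Cv`, ug/cm^3.
#' @param diffusivity_ratio `D/L^2`, 1/min.
#' @param tol Series truncation tolerance.
#' @return Local concentration, ug/cm^3; non-negative and decreasing in
#'   depth at fixed time.
#' @export
sc_concentration_profile <- function(depth_fraction, time,
                                     partition_surface_conc,
                                     diffusivity_ratio, tol = 1e-12) {
  if (!is.numeric(depth_fraction) || any(depth_fraction < 0) ||
      any(depth_fraction > 1))
    stop("`depth_fraction` must be in [0, 1]", call. = FALSE)
  check_number(time, "time", lower = 0, strict_lower = TRUE)
  check_number(partition_surface_conc, "partition_surface_conc",
               lower = 0, strict_lower = TRUE)
  check_number(diffusivity_ratio, "diffusivity_ratio",
               lower = 0, strict_lower = TRUE)

  tau <- diffusivity_ratio * time
  out <- 1 - depth_fraction
  n <- 1L
  repeat {
    damp <- exp(-n^2 * pi^2 * tau)
    out <- out - (2 / pi) * (1 / n) * sin(n * pi * depth_fraction) * damp
    # |sum of remaining terms| <= (2/pi) * sum_{m>n} exp(-m^2 pi^2 tau)/m,
    # bounded by a geometric tail with ratio exp(-(2n+1) pi^2 tau).
    ratio <- exp(-(2 * n + 1) * pi^2 * tau)
    if (damp * ratio / (1 - ratio) * (2 / pi) < tol || n > 100000L) break
    n <- n + 1L
  }
  pmax(out, 0) * partition_surface_conc
}

# Cumulative drug amount (ug) from the surface down to relative depth X
# over an application area (cm^2), for SC thickness L_cm (cm): the
# analytic depth integral of sc_concentration_profile.
sc_cumulative_amount <- function(X, time, partition_surface_conc,
                                 diffusivity_ratio, area, L_cm,
                                 tol = 1e-14) {
  tau <- diffusivity_ratio * time
  out <- X - X^2 / 2
  n <- 1L
  repeat {
    damp <- exp(-n^2 * pi^2 * tau)
    out <- out - (2 / pi^2) * (1 / n^2) * (1 - cos(n * pi * X)) * damp
    ratio <- exp(-(2 * n + 1) * pi^2 * tau)
    if (damp * ratio / (1 - ratio) * (4 / pi^2) < tol || n > 100000L) break
    n <- n + 1L
  }
  pmax(out, 0) * partition_surface_conc * area * L_cm
}

# Mean-preserving lognormal multiplier with a given CV.
lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a tape-stripping study
#'
#' Per participant, draws an SC thickness; per product site, generates
#' decreasing strip masses, assigns each strip the depth integral of
#' [sc_concentration_profile()] over the interval it removes (converted
#' to ug via site area and SC density) scaled by the product's strength,
#' and adds multiplicative noise. A blank site per participant is
#' stripped the same way to produce a TEWL series
#' `TEWL_k = baseline * L / (L - x_k)` consistent with the drawn
#' thickness, which [estimate_sc_thickness_tewl()] inverts.
#'
#' @param config A [ts_sim_config()].
#' @param product_ids Character vector of product labels.
#' @param product_scale Named numeric: per-product strength (% w/w drug),
#'   acting as a multiplier on `partition_surface_conc`. Names must cover
#'   `product_ids`.
#' @return A list of class `ts_study`: `sites` (list of [strip_site()]),
#'   `tewl` (list of [tewl_series()], one per participant) and `truth`
#'   (drawn SC thicknesses and noise-free drug amounts, for recovery
#'   testing).
#' @export
simulate_tape_strip_study <- function(config, product_ids, product_scale) {
  if (!inherits(config, "ts_sim_config"))
    stop("`config` must be a ts_sim_config", call. = FALSE)
  missing_scale <- setdiff(product_ids, names(product_scale))
  if (length(missing_scale))
    stop("`product_scale` missing products: ",
         paste(missing_scale, collapse = ", "), call. = FALSE)

  with_seed(config$seed, {
    sdlog_L <- sqrt(log(1 + config$sc_thickness_cv^2))
    L_um <- rlnorm(config$n_participants,
                   meanlog = log(config$sc_thickness_mean) - sdlog_L^2 / 2,
                   sdlog = sdlog_L)
    names(L_um) <- paste0("P", sprintf("%02d", seq_len(config$n_participants)))

    mean_masses <- config$strip_mass_first *
      (1 - config$strip_mass_decay)^(seq_len(config$n_strips) - 1)
    tape_pre <- 22000  # ug, nominal tape weight before stripping

    sites <- list()
    tewl <- list()
    truth_drug <- list()
    drug_dose_ug <- function(scale) config$dose_mass * 1000 * scale / 100

    for (p in names(L_um)) {
      L_cm <- L_um[[p]] * 1e-4
      for (prod in product_ids) {
        masses <- mean_masses * lnorm_noise(config$n_strips,
                                            config$strip_mass_cv)
        depth_cm <- cumsum(masses) * 1e-6 /
          (config$site_area * config$sc_density)
        X <- pmin(depth_cm / L_cm, 1)
        cum_amt <- sc_cumulative_amount(
          X, config$application_time,
          config$partition_surface_conc * product_scale[[prod]],
          config$diffusivity_ratio, config$site_area, L_cm)
        amt_true <- pmax(diff(c(0, cum_amt)), 0)
        amt <- amt_true * lnorm_noise(config$n_strips, config$drug_noise_cv)
        # physical bound: cannot recover more than was applied
        total_cap <- drug_dose_ug(product_scale[[prod]])
        if (sum(amt) > total_cap) amt <- amt * total_cap / sum(amt)
        sites[[paste(p, prod, sep = ".")]] <- strip_site(
          participant_id = p, site = prod, product_id = prod,
          pre_weight = rep(tape_pre, config$n_strips),
          post_weight = tape_pre + masses,
          drug_amount = amt,
          site_area = config$site_area,
          application_time = config$application_time)
        truth_drug[[paste(p, prod, sep = ".")]] <- amt_true
      }
      # blank site: progressive stripping with TEWL after each strip;
      # masses are rescaled if a thin SC would otherwise be stripped
      # through, so the recorded masses and the TEWL stay consistent
      bm <- mean_masses * lnorm_noise(config$n_strips, config$strip_mass_cv)
      x_um <- cumsum(bm) * 1e-6 / (config$site_area * config$sc_density) * 1e4
      if (max(x_um) > 0.9 * L_um[[p]]) {
        shrink <- 0.9 * L_um[[p]] / max(x_um)
        bm <- bm * shrink
        x_um <- x_um * shrink
      }
      cum_mass <- cumsum(bm)
      tewl_true <- config$tewl_baseline * L_um[[p]] / (L_um[[p]] - x_um)
      tewl_obs <- tewl_true * lnorm_noise(config$n_strips,
                                          config$tewl_noise_cv)
      tewl[[p]] <- tewl_series(p, cum_mass, tewl_obs)
    }

    structure(list(sites = sites, tewl = tewl,
                   truth = list(sc_thickness_um = L_um,
                                drug_amounts = truth_drug),
                   config = config,
                   product_scale = product_scale[product_ids]),
              class = "ts_study")
  })
}

#' @export
print.ts_study <- function(x, ...) {
  cat(sprintf("Tape-strip study: %d participants x %d products, %d strips/site\n",
              x$config$n_participants, length(x$product_scale),
              x$config$n_strips))
  invisible(x)
}
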