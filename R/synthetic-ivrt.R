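#' Configuration for a simulated IVRT diffusion-cell run
#'
#' Defaults reproduce the vertical-diffusion-cell design the analysis
#' targets: six cells of 7.9 mL with a 15 mm orifice, 200 uL samples
#' withdrawn every 15 min for 90 min and replaced with blank medium.
#'
#' @param true_arc True apparent release constant (slope of cumulative
#'   amount released per area vs sqrt(time)), ug/cm^2/min^(1/2).
#' @param intercept_true True intercept of the release profile, ug/cm^2.
#' @param n_cells Number of diffusion cells (>= 2).
#' @param sample_times Sampling times in minutes, strictly increasing.
#' @param cell_volume Receptor volume, mL.
#' @param sample_volume Withdrawn sample volume, mL (replaced with blank
#'   medium after each draw).
#' @param orifice_diameter Orifice diameter, mm; release area is the
#'   orifice disc.
#' @param noise_cv Multiplicative CV of measured receptor concentrations.
#' @param cell_arc_cv Between-cell CV of the true per-cell slope.
#' @param seed Integer seed; the generator uses a local RNG scope.
#'
#' @return A validated list of class `ivrt_sim_config`.
#' @export
ivrt_sim_config <- function(true_arc,
                            intercept_true = 0,
                            n_cells = 6L,
                            sample_times = seq(15, 90, by = 15),
                            cell_volume = 7.9,
                            sample_volume = 0.2,
                            orifice_diameter = 15,
                            noise_cv = 0.02,
                            cell_arc_cv = 0.05,
                            seed = NULL) {
  check_number(true_arc, "true_arc", lower = 0, strict_lower = TRUE)
  check_number(intercept_true, "intercept_true", lower = 0)
  n_cells <- check_count(n_cells, "n_cells", lower = 2L)
  sample_times <- check_times(sample_times)
  check_number(cell_volume, "cell_volume", lower = 0, strict_lower = TRUE)
  check_number(sample_volume, "sample_volume", lower = 0, strict_lower = TRUE)
  if (sample_volume >= cell_volume)
    stop_field("sample_volume", "must be smaller than cell_volume")
  check_number(orifice_diameter, "orifice_diameter", lower = 0,
               strict_lower = TRUE)
  check_number(noise_cv, "noise_cv", lower = 0)
  check_number(cell_arc_cv, "cell_arc_cv", lower = 0)
  seed <- check_seed(seed)
  structure(
    list(true_arc = true_arc, intercept_true = intercept_true,
         n_cells = n_cells, sample_times = sample_times,
         cell_volume = cell_volume, sample_volume = sample_volume,
         orifice_diameter = orifice_diameter, noise_cv = noise_cv,
         cell_arc_cv = cell_arc_cv, seed = seed),
    class = "ivrt_sim_config")
}

orifice_area_cm2 <- function(diameter_mm) pi * (diameter_mm / 10)^2 / 4

#' Simulate one IVRT run
#'
#' Draws a true slope per cell, computes the true cumulative release
#' `Q(t) = slope * sqrt(t) + intercept` per unit area, and inverts the
#' withdrawal bookkeeping to obtain the receptor concentration at each
#' sampling time: each withdrawn sample removes drug that is replaced by
#' blank medium, so the measured concentration at time `t_n` reflects the
#' cumulative release minus everything already withdrawn. This inversion
#' is exact, so at zero noise [cumulative_release()] recovers the true
#' `Q(t)` to machine precision.
#'
#' @param config An [ivrt_sim_config()].
#' @param product_id Product label carried through the analysis.
#' @param role `"test"` or `"reference"`.
#'
#' @return An `ivrt_run` object: product metadata, cell geometry, and a
#'   cells-by-times concentration matrix (ug/mL). The drawn per-cell
#'   slopes are attached as attribute `"true_cell_slopes"` for
#'   recovery testing.
#' @export
simulate_ivrt_run <- function(config, product_id,
                              role = c("test", "reference")) {
  if (!inherits(config, "ivrt_sim_config"))
    stop("`config` must be an ivrt_sim_config", call. = FALSE)
  role <- match.arg(role)
  area <- orifice_area_cm2(config$orifice_diameter)
  times <- config$sample_times
  n_t <- length(times)

  with_seed(config$seed, {
    slopes <- rnorm(config$n_cells, mean = config$true_arc,
                    sd = config$cell_arc_cv * config$true_arc)
    slopes <- pmax(slopes, 1e-6)
    conc <- matrix(0, nrow = config$n_cells, ncol = n_t,
                   dimnames = list(paste0("cell", seq_len(config$n_cells)),
                                   times))
    for (j in seq_len(config$n_cells)) {
      amount <- (slopes[j] * sqrt(times) + config$intercept_true) * area
      c_true <- numeric(n_t)
      withdrawn <- 0
      for (n in seq_len(n_t)) {
        c_true[n] <- (amount[n] - withdrawn) / config$cell_volume
        withdrawn <- withdrawn + c_true[n] * config$sample_volume
      }
      noisy <- c_true * (1 + rnorm(n_t, sd = config$noise_cv))
      conc[j, ] <- pmax(noisy, 0)
    }
    structure(
      list(product_id = product_id, role = role, times = times,
           conc = conc, cell_volume = config$cell_volume,
           sample_volume = config$sample_volume, orifice_area = area,
           temperature = 32),
      true_cell_slopes = slopes,
      class = "ivrt_run")
  })
}

#' Construct an IVRT run from measured data
#'
#' @param product_id Product label.
#' @param role `"test"` or `"reference"`.
#' @param times Sampling times, minutes, strictly increasing.
#' @param conc Cells-by-times matrix of receptor concentrations (ug/mL),
#'   row names are cell ids.
#' @param cell_volume,sample_volume Receptor and withdrawal volumes, mL.
#' @param orifice_diameter Orifice diameter, mm.
#' @param temperature Receptor temperature, degrees C (metadata).
#' @return An `ivrt_run`.
#' @export
ivrt_run <- function(product_id, role, times, conc,
                     cell_volume = 7.9, sample_volume = 0.2,
                     orifice_diameter = 15, temperature = 32) {
  times <- check_times(times, "times")
  if (!is.matrix(conc) || ncol(conc) != length(times))
    stop("`conc` must be a matrix with one column per sampling time",
         call. = FALSE)
  if (nrow(conc) < 2L) stop("need >= 2 cells", call. = FALSE)
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (is.null(rownames(conc)))
    rownames(conc) <- paste0("cell", seq_len(nrow(conc)))
  check_number(cell_volume, "cell_volume", lower = 0, strict_lower = TRUE)
  check_number(sample_volume, "sample_volume", lower = 0, strict_lower = TRUE)
  structure(
    list(product_id = product_id, role = match.arg(role, c("test", "reference")),
         times = times, conc = conc, cell_volume = cell_volume,
         sample_volume = sample_volume,
         orifice_area = orifice_area_cm2(orifice_diameter),
         temperature = temperature),
    class = "ivrt_run")
}

#' @export
print.ivrt_run <- function(x, ...) {
  cat(sprintf("IVRT run: %s (%s), %d cells, %d samples (%g-%g min)\n",
              x$product_id, x$role, nrow(x$conc), length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

# Split a run into per-cell records carrying the geometry they need.
ivrt_cells <- function(run) {
  stopifnot(inherits(run, "ivrt_run"))
  lapply(rownames(run$conc), function(id) {
    list(cell_id = id, times = run$times, conc = run$conc[id, ],
         cell_volume = run$cell_volume, sample_volume = run$sample_volume,
         orifice_area = run$orifice_area)
  })
}
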