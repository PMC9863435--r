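#' Withdrawal-corrected cumulative release per unit area
#'
#' When a sample of volume `V_s` is withdrawn from the receptor and
#' replaced with blank medium, the drug it contained leaves the cell, so
#' the cumulative amount released through the membrane up to sample `n`
#' is \deqn{Q_n = \frac{C_n V_{cell} + \sum_{i<n} C_i V_{sample}}{A}}
#' with `A` the orifice area.
#'
#' @param cell A per-cell record: a list with `cell_id`, `times` (min),
#'   `conc` (ug/mL, one per time), `cell_volume` (mL), `sample_volume`
#'   (mL), `orifice_area` (cm^2). [ivrt_cells()] produces these from an
#'   `ivrt_run`, or pass an `ivrt_run` to get one profile per cell.
#' @return A `release_profile`: `cell_id`, `times`, and `Q` (ug/cm^2);
#'   for an `ivrt_run`, a list of profiles.
#' @export
cumulative_release <- function(cell) {
  if (inherits(cell, "ivrt_run"))
    return(lapply(ivrt_cells(cell), cumulative_release))
  if (length(cell$conc) != length(cell$times))
    stop(sprintf("cell %s: %d concentrations for %d sample times",
                 cell$cell_id, length(cell$conc), length(cell$times)),
         call. = FALSE)
  if (any(cell$conc < 0))
    stop(sprintf("cell %s: negative concentration", cell$cell_id),
         call. = FALSE)
  conc <- unname(cell$conc)
  withdrawn <- cell$sample_volume * cumsum(c(0, head(conc, -1)))
  q <- (conc * cell$cell_volume + withdrawn) / cell$orifice_area
  structure(list(cell_id = cell$cell_id, times = cell$times, Q = q),
            class = "release_profile")
}

#' Fit the Higuchi (square-root-of-time) release model
#'
#' Ordinary least squares of cumulative release per area `Q` on
#' `sqrt(time in minutes)`. The slope is the apparent release constant
#' (ARC); the intercept is estimated (not forced through the origin) to
#' absorb lag or burst effects.
#'
#' @param profile A `release_profile`.
#' @param time_window Optional `c(min, max)` in minutes restricting the
#'   points used.
#' @return List with `cell_id`, `slope` (ug/cm^2/min^(1/2)), `intercept`,
#'   `r_squared`, `slope_se`, `n`.
#' @export
fit_higuchi <- function(profile, time_window = NULL) {
  t <- profile$times
  q <- profile$Q
  if (!is.null(time_window)) {
    keep <- t >= time_window[1] & t <= time_window[2]
    t <- t[keep]; q <- q[keep]
  }
  if (length(t) < 3L)
    stop(sprintf("cell %s: need >= 3 points to fit (have %d)",
                 profile$cell_id, length(t)), call. = FALSE)
  x <- sqrt(t)
  if (var(x) == 0)
    stop(sprintf("cell %s: zero variance in sqrt(time)", profile$cell_id),
         call. = FALSE)
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (q - mean(q))) / sxx
  intercept <- mean(q) - slope * mean(x)
  resid <- q - intercept - slope * x
  sst <- sum((q - mean(q))^2)
  r2 <- if (sst > 0) 1 - sum(resid^2) / sst else 1
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  list(cell_id = profile$cell_id, slope = slope, intercept = intercept,
       r_squared = max(0, min(1, r2)), slope_se = se, n = n)
}

#' Apparent release constants for one IVRT run
#'
#' Fits the Higuchi model per cell and summarises the run as the
#' arithmetic mean and sample SD (n-1) of the per-cell slopes.
#'
#' @param run An `ivrt_run`.
#' @param time_window Optional `c(min, max)` passed to [fit_higuchi()].
#' @return An `arc_result`: `product_id`, `role`, a per-cell data frame
#'   (`cell_id`, `slope`, `intercept`, `r_squared`, `slope_se`),
#'   `arc_mean`, `arc_sd`, `n_cells`.
#' @export
run_arc <- function(run, time_window = NULL) {
  stopifnot(inherits(run, "ivrt_run"))
  profiles <- cumulative_release(run)
  fits <- lapply(profiles, function(p) {
    tryCatch(fit_higuchi(p, time_window),
             error = function(e) structure(list(cell_id = p$cell_id,
                                                msg = conditionMessage(e)),
                                           class = "fit_failure"))
  })
  failed <- vapply(fits, inherits, logical(1), "fit_failure")
  if (any(failed))
    stop("Higuchi fit failed for cells: ",
         paste(vapply(fits[failed], `[[`, "", "cell_id"), collapse = ", "),
         call. = FALSE)
  cells <- do.call(rbind, lapply(fits, function(f)
    data.frame(cell_id = f$cell_id, slope = f$slope,
               intercept = f$intercept, r_squared = f$r_squared,
               slope_se = f$slope_se)))
  rownames(cells) <- NULL
  structure(
    list(product_id = run$product_id, role = run$role, cells = cells,
         arc_mean = mean(cells$slope), arc_sd = sd(cells$slope),
         n_cells = nrow(cells), time_window = time_window),
    class = "arc_result")
}

#' @export
print.arc_result <- function(x, ...) {
  cat(sprintf("ARC for %s (%s): %.2f +/- %.2f ug/cm^2/min^(1/2) (n = %d cells)\n",
              x$product_id, x$role, x$arc_mean, x$arc_sd, x$n_cells))
  invisible(x)
}

#' Test/reference release-rate ratio with confidence interval
#'
#' The point estimate is the ratio of run-level mean ARCs. The default
#' interval is a Welch two-sample t interval on mean log-slopes,
#' exponentiated (standard for ratio-of-means comparisons at small n);
#' Fieller's interval on the untransformed slopes is available when
#' slopes can be non-positive.
#'
#' @param test,reference `arc_result`s carrying per-cell slopes.
#' @param level Confidence level (default 0.90).
#' @param method `"log-t"` (default) or `"fieller"`.
#' @return A `ratio_ci`: `ratio`, `lower`, `upper`, `level`, `method`.
#' @export
release_ratio_ci <- function(test, reference, level = 0.90,
                             method = c("log-t", "fieller")) {
  stopifnot(inherits(test, "arc_result"), inherits(reference, "arc_result"))
  method <- match.arg(method)
  check_number(level, "level", lower = 0, upper = 1, strict_lower = TRUE)
  if (level >= 1) stop_field("level", "must be in (0, 1)")
  st <- test$cells$slope
  sr <- reference$cells$slope
  if (length(st) < 2L || length(sr) < 2L)
    stop("need >= 2 cells per side", call. = FALSE)
  ratio <- mean(st) / mean(sr)
  alpha <- 1 - level

  if (method == "log-t") {
    if (any(st <= 0) || any(sr <= 0))
      stop("non-positive slope: the log-t interval is undefined; ",
           "use method = \"fieller\"", call. = FALSE)
    lt <- log(st); lr <- log(sr)
    se <- sqrt(var(lt) / length(lt) + var(lr) / length(lr))
    df <- se^4 / ((var(lt) / length(lt))^2 / (length(lt) - 1) +
                  (var(lr) / length(lr))^2 / (length(lr) - 1))
    d <- mean(lt) - mean(lr)
    hw <- qt(1 - alpha / 2, df) * se
    ci <- exp(c(d - hw, d + hw))
  } else {
    # Fieller interval for mean(test)/mean(reference)
    mt <- mean(st); mr <- mean(sr)
    vt <- var(st) / length(st); vr <- var(sr) / length(sr)
    df <- (vt + vr)^2 / (vt^2 / (length(st) - 1) + vr^2 / (length(sr) - 1))
    tq <- qt(1 - alpha / 2, df)
    g <- tq^2 * vr / mr^2
    if (g >= 1)
      stop("Fieller interval unbounded (reference mean not ",
           "significantly different from zero)", call. = FALSE)
    centre <- ratio / (1 - g)
    hw <- tq / (mr * (1 - g)) * sqrt(vt + ratio^2 * vr - g * vt)
    ci <- c(centre - hw, centre + hw)
  }
  structure(list(ratio = ratio, lower = min(ci[1], ratio),
                 upper = max(ci[2], ratio), level = level, method = method),
            class = "ratio_ci")
}

#' @export
print.ratio_ci <- function(x, ...) {
  cat(sprintf("ARC ratio %.2f, %d%% CI (%.2f-%.2f) [%s]\n", x$ratio,
              round(100 * x$level), x$lower, x$upper, x$method))
  invisible(x)
}
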