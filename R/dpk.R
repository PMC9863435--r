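#' Construct a tape-strip site record
#'
#' One application site on one participant: 20 (typically) sequentially
#' applied pre-weighed tape strips, re-weighed after stripping, with the
#' drug amount recovered from each strip.
#'
#' @param participant_id Participant label.
#' @param site Site label (e.g. product name or arm/position code).
#' @param product_id Product applied (`NA` for a blank site).
#' @param pre_weight,post_weight Tape weights before/after stripping, ug,
#'   in strip order.
#' @param drug_amount Drug recovered per strip, ug.
#' @param site_area Site area, cm^2.
#' @param application_time Application duration, minutes.
#' @return A `strip_site`.
#' @export
strip_site <- function(participant_id, site, product_id,
                       pre_weight, post_weight, drug_amount,
                       site_area = 4.0, application_time = 60) {
  n <- length(pre_weight)
  if (length(post_weight) != n || length(drug_amount) != n)
    stop("pre_weight, post_weight and drug_amount must have equal length",
         call. = FALSE)
  if (anyNA(pre_weight) || anyNA(post_weight))
    stop("missing strip weights at strip index ",
         paste(which(is.na(pre_weight) | is.na(post_weight)),
               collapse = ", "), call. = FALSE)
  if (any(drug_amount < 0))
    stop("drug_amount must be >= 0", call. = FALSE)
  check_number(site_area, "site_area", lower = 0, strict_lower = TRUE)
  check_number(application_time, "application_time", lower = 0,
               strict_lower = TRUE)
  structure(
    list(participant_id = participant_id, site = site,
         product_id = product_id,
         strips = data.frame(index = seq_len(n), pre_weight = pre_weight,
                             post_weight = post_weight,
                             drug_amount = drug_amount),
         site_area = site_area, application_time = application_time),
    class = "strip_site")
}

#' Stratum corneum mass removed per strip
#'
#' `mass_i = post_weight_i - pre_weight_i`. Small negative differences
#' (balance noise) within `tolerance` are clipped to zero with a warning;
#' larger negatives indicate a weighing error and raise.
#'
#' @param site A [strip_site()].
#' @param tolerance Largest tolerated negative difference, ug.
#' @return Numeric vector of per-strip SC masses, ug.
#' @export
strip_masses <- function(site, tolerance = 2) {
  stopifnot(inherits(site, "strip_site"))
  m <- site$strips$post_weight - site$strips$pre_weight
  bad <- which(m < -tolerance)
  if (length(bad))
    stop(sprintf("strip %s: post weight below pre weight by more than %g ug",
                 paste(bad, collapse = ", "), tolerance), call. = FALSE)
  neg <- which(m < 0)
  if (length(neg)) {
    warning(sprintf("clipping %d slightly negative strip mass(es) to 0",
                    length(neg)), call. = FALSE)
    m[neg] <- 0
  }
  m
}

#' Construct a TEWL series from progressive stripping of a blank site
#'
#' @param participant_id Participant label.
#' @param cum_mass Cumulative SC mass removed before each reading, ug;
#'   strictly increasing.
#' @param tewl Transepidermal water loss readings, g/m^2/h; positive.
#' @return A `tewl_series`.
#' @export
tewl_series <- function(participant_id, cum_mass, tewl) {
  if (length(cum_mass) != length(tewl))
    stop("cum_mass and tewl must have equal length", call. = FALSE)
  if (any(diff(cum_mass) <= 0))
    stop("cum_mass must be strictly increasing", call. = FALSE)
  if (any(tewl <= 0)) stop("tewl must be > 0", call. = FALSE)
  structure(list(participant_id = participant_id,
                 readings = data.frame(cum_mass = cum_mass, tewl = tewl)),
            class = "tewl_series")
}

#' Stratum corneum thickness from TEWL extrapolation
#'
#' At Fick steady state, TEWL is inversely proportional to the remaining
#' SC thickness, so `1/TEWL` falls linearly with stripped depth and
#' extrapolates to zero at the full thickness `L`. Cumulative removed
#' mass is converted to depth via `x = mass / (site_area * sc_density)`,
#' then `1/TEWL = a - b x` is fitted by least squares and `L = a / b`.
#'
#' @param series A [tewl_series()] with >= 3 readings.
#' @param site_area Stripped area, cm^2.
#' @param sc_density SC density, g/cm^3.
#' @param r2_floor Minimum R^2 of the linear fit for the thickness to be
#'   considered identifiable.
#' @return SC thickness `L`, um.
#' @export
estimate_sc_thickness_tewl <- function(series, site_area, sc_density = 1.0,
                                       r2_floor = 0.8) {
  stopifnot(inherits(series, "tewl_series"))
  if (nrow(series$readings) < 3L)
    stop("need >= 3 TEWL readings", call. = FALSE)
  check_number(site_area, "site_area", lower = 0, strict_lower = TRUE)
  check_number(sc_density, "sc_density", lower = 0, strict_lower = TRUE)
  # ug / (cm^2 * g/cm^3) = 1e-6 cm = 1e-2 um
  x <- series$readings$cum_mass / (site_area * sc_density) * 1e-2
  y <- 1 / series$readings$tewl
  sxx <- sum((x - mean(x))^2)
  b <- -sum((x - mean(x)) * (y - mean(y))) / sxx   # slope of decline
  a <- mean(y) + b * mean(x)
  fitted <- a - b * x
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum((y - fitted)^2) / sst else 0
  if (b <= 0 || r2 < r2_floor)
    stop(sprintf(paste("thickness not identifiable: 1/TEWL must decline",
                       "linearly with depth (slope %.3g, R^2 %.3f)"),
                 -b, r2), call. = FALSE)
  a / b
}

#' Estimate SC thickness for a set of participants
#'
#' Applies [estimate_sc_thickness_tewl()] to each series. When a
#' participant's thickness is not identifiable (flat or noisy 1/TEWL
#' decline, typically a thick SC of which the strips sampled only a
#' small fraction), the participant can either abort the analysis
#' (`"error"`) or be excluded with a warning (`"exclude"`), which is the
#' usual analyst's choice.
#'
#' @param series_list List of [tewl_series()] objects.
#' @param site_area,sc_density,r2_floor Passed through.
#' @param on_unidentifiable `"error"` or `"exclude"`.
#' @return Named numeric vector of thicknesses (um) by participant;
#'   excluded participants are absent.
#' @export
estimate_sc_thickness_all <- function(series_list, site_area,
                                      sc_density = 1.0, r2_floor = 0.8,
                                      on_unidentifiable = c("error",
                                                            "exclude")) {
  on_unidentifiable <- match.arg(on_unidentifiable)
  out <- lapply(series_list, function(s) {
    tryCatch(estimate_sc_thickness_tewl(s, site_area, sc_density, r2_floor),
             error = function(e) {
               if (on_unidentifiable == "error")
                 stop("participant ", s$participant_id, ": ",
                      conditionMessage(e), call. = FALSE)
               warning("excluding participant ", s$participant_id, ": ",
                       conditionMessage(e), call. = FALSE)
               NULL
             })
  })
  names(out) <- vapply(series_list, `[[`, "", "participant_id")
  unlist(Filter(Negate(is.null), out))
}

#' Drug amount versus relative stratum corneum depth
#'
#' Converts strip masses to cumulative depth and places each strip at the
#' midpoint of the depth interval it removed, expressed as a percentage
#' of the participant's SC thickness `L`.
#'
#' @param site A [strip_site()].
#' @param L SC thickness, um.
#' @param sc_density SC density, g/cm^3.
#' @param drop_first_n Number of initial strips to exclude (some
#'   protocols discard strips 1-2 as surface residue; default keeps all).
#' @param position Plotting position within each strip's removed
#'   interval: `"midpoint"` (default), `"leading"` or `"trailing"` edge.
#' @return An `sc_profile`: `points` data frame with
#'   `relative_depth_percent`, `drug_amount` (ug) and `beyond_sc` flag
#'   for strips past 100% of `L`; plus `L_um`, `total_depth_um`,
#'   `total_depth_percent`.
#' @export
relative_depth_profile <- function(site, L, sc_density = 1.0,
                                   drop_first_n = 0,
                                   position = c("midpoint", "leading",
                                                "trailing")) {
  stopifnot(inherits(site, "strip_site"))
  check_number(L, "L", lower = 0, strict_lower = TRUE)
  position <- match.arg(position)
  masses <- strip_masses(site)
  depth_um <- cumsum(masses) / (site$site_area * sc_density) * 1e-2
  total <- depth_um[length(depth_um)]
  if (total > 1.5 * L)
    stop(sprintf(paste("total stripped depth (%.1f um) exceeds 150%% of the",
                       "SC thickness (%.1f um): thickness or weighing",
                       "inconsistency"), total, L), call. = FALSE)
  lower <- c(0, head(depth_um, -1))
  pos_um <- switch(position,
                   midpoint = (lower + depth_um) / 2,
                   leading = lower,
                   trailing = depth_um)
  keep <- seq_along(masses) > drop_first_n
  pts <- data.frame(
    strip_index = site$strips$index[keep],
    relative_depth_percent = pos_um[keep] / L * 100,
    drug_amount = site$strips$drug_amount[keep],
    beyond_sc = depth_um[keep] > L)
  structure(
    list(participant_id = site$participant_id, product_id = site$product_id,
         site = site$site, points = pts, L_um = L, total_depth_um = total,
         total_depth_percent = total / L * 100,
         dropped_first_n = drop_first_n, position = position),
    class = "sc_profile")
}

#' Area under the drug-vs-relative-depth curve
#'
#' Composite trapezoidal rule over (relative depth %, drug amount per
#' strip). No extrapolation beyond the first and last plotting positions
#' by default; `anchor_zero = TRUE` additionally anchors the curve at
#' zero drug at 0% depth and at the last stripped depth.
#'
#' @param profile An `sc_profile` with >= 2 points.
#' @param anchor_zero Logical; see above.
#' @return AUC in ug.% skin depth.
#' @export
profile_auc <- function(profile, anchor_zero = FALSE) {
  stopifnot(inherits(profile, "sc_profile"))
  x <- profile$points$relative_depth_percent
  y <- profile$points$drug_amount
  if (length(x) < 2L) stop("need >= 2 profile points", call. = FALSE)
  if (any(diff(x) <= 0))
    stop("relative depths must be strictly increasing", call. = FALSE)
  if (anchor_zero) {
    x <- c(0, x, profile$total_depth_percent)
    y <- c(0, y, 0)
  }
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Study-level AUC for one product
#'
#' Computes the AUC per profile, averages replicate sites within each
#' participant (switchable), then summarises across participants with
#' the arithmetic mean and sample SD.
#'
#' @param profiles List of `sc_profile`s for one product.
#' @param blanks Optional named list (by participant) of per-strip blank
#'   drug amounts (ug) subtracted from each profile before integration.
#' @param average_replicates If `TRUE` (default), replicate sites within
#'   a participant are averaged into one AUC; otherwise each site counts
#'   as an observation.
#' @param anchor_zero Passed to [profile_auc()].
#' @return An `auc_result`: `product_id`, per-participant data frame
#'   (`participant_id`, `auc`), `auc_mean`, `auc_sd`, `n_participants`.
#' @export
study_auc <- function(profiles, blanks = NULL, average_replicates = TRUE,
                      anchor_zero = FALSE) {
  if (length(profiles) < 2L)
    stop("need >= 2 participants", call. = FALSE)
  pid <- vapply(profiles, `[[`, "", "participant_id")
  prod <- unique(vapply(profiles, function(p) as.character(p$product_id), ""))
  if (length(prod) != 1L)
    stop("profiles span several products: ",
         paste(prod, collapse = ", "), call. = FALSE)
  aucs <- vapply(profiles, function(p) {
    if (!is.null(blanks)) {
      b <- blanks[[p$participant_id]]
      if (is.null(b))
        stop("blank subtraction requested but no blank for participant ",
             p$participant_id, call. = FALSE)
      idx <- p$points$strip_index
      p$points$drug_amount <- pmax(p$points$drug_amount - b[idx], 0)
    }
    profile_auc(p, anchor_zero = anchor_zero)
  }, numeric(1))
  per <- if (average_replicates) {
    agg <- tapply(aucs, pid, mean)
    data.frame(participant_id = names(agg), auc = as.numeric(agg))
  } else {
    data.frame(participant_id = pid, auc = aucs)
  }
  if (nrow(per) < 2L) stop("need >= 2 participants", call. = FALSE)
  structure(
    list(product_id = prod, participants = per, auc_mean = mean(per$auc),
         auc_sd = sd(per$auc), n_participants = nrow(per)),
    class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC for %s: %.2f +/- %.2f ug.%% skin depth (n = %d)\n",
              x$product_id, x$auc_mean, x$auc_sd, x$n_participants))
  invisible(x)
}
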