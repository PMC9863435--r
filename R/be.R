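#' Bioequivalence acceptance windows for ARC and AUC
#'
#' The regulatory acceptance criterion of a <= 20% test/reference
#' difference translates into the 0.80-1.25 ratio window. The ARC window
#' is the pooled reference ARC (arithmetic mean of the supplied reference
#' run ARCs) times the ratio bounds; the AUC window is the ARC window
#' mapped through the fitted Level C model.
#'
#' The default ratio bounds are 0.7999 and 1.2501 (the exact working
#' values used in the reporting convention this package follows); pass
#' 0.80 and 1.25 for the round regulatory figures.
#'
#' @param model An `ivivc_model`.
#' @param reference_arcs Numeric vector of reference-run ARCs (>= 1).
#' @param lower_ratio,upper_ratio Ratio bounds; must bracket 1.
#' @param pooling `"mean"` (default) pools all reference runs; `"first"`
#'   uses only the first supplied ARC.
#' @return A `be_bounds`: ratio bounds, `pooled_reference_arc`,
#'   `arc_lower`, `arc_upper`, `auc_lower`, `auc_upper`.
#' @export
be_limits <- function(model, reference_arcs, lower_ratio = 0.7999,
                      upper_ratio = 1.2501,
                      pooling = c("mean", "first")) {
  stopifnot(inherits(model, "ivivc_model"))
  pooling <- match.arg(pooling)
  if (length(reference_arcs) < 1L || any(reference_arcs <= 0))
    stop("need >= 1 positive reference ARC", call. = FALSE)
  check_number(lower_ratio, "lower_ratio", lower = 0, strict_lower = TRUE)
  check_number(upper_ratio, "upper_ratio", lower = 0, strict_lower = TRUE)
  if (!(lower_ratio < 1 && 1 < upper_ratio))
    stop("ratio bounds must satisfy lower_ratio < 1 < upper_ratio",
         call. = FALSE)
  pooled <- switch(pooling, mean = mean(reference_arcs),
                   first = reference_arcs[1])
  arc_lower <- pooled * lower_ratio
  arc_upper <- pooled * upper_ratio
  structure(
    list(lower_ratio = lower_ratio, upper_ratio = upper_ratio,
         pooled_reference_arc = pooled, pooling = pooling,
         arc_lower = arc_lower, arc_upper = arc_upper,
         auc_lower = predict_auc(model, arc_lower),
         auc_upper = predict_auc(model, arc_upper),
         model = model),
    class = "be_bounds")
}

#' @export
print.be_bounds <- function(x, ...) {
  cat("BE limits (pooled reference ARC ",
      sprintf("%.2f", x$pooled_reference_arc), ")\n", sep = "")
  cat(sprintf("  %.4f (lower)  predicted AUC %.2f  ARC %.2f\n",
              x$lower_ratio, x$auc_lower, x$arc_lower))
  cat(sprintf("  %.4f (upper)  predicted AUC %.2f  ARC %.2f\n",
              x$upper_ratio, x$auc_upper, x$arc_upper))
  invisible(x)
}

#' Classify a product against the BE windows
#'
#' The verdict is driven by the ARC window (inclusive at both ends): a
#' product whose mean ARC lies inside it is declared bioequivalent. The
#' predicted AUC and its window membership are reported alongside;
#' because the Level C map is affine and increasing, the two windows
#' agree. A stricter mode requires the whole ARC confidence interval
#' inside the window.
#'
#' @param arc The product's mean ARC.
#' @param bounds A [be_limits()] result.
#' @param product_id Product label for reporting.
#' @param arc_ci Optional `c(lower, upper)` ARC confidence interval; when
#'   supplied with `ci_mode = TRUE`, the whole interval must lie inside
#'   the window.
#' @param ci_mode Require the CI inside the window (default `FALSE`:
#'   point-estimate windowing).
#' @return A `be_verdict`: `product_id`, `arc`, `predicted_auc`,
#'   `within_arc_window`, `within_auc_window`, `verdict` (`"BE"` or
#'   `"non-BE"`).
#' @export
classify_be <- function(arc, bounds, product_id = NA_character_,
                        arc_ci = NULL, ci_mode = FALSE) {
  stopifnot(inherits(bounds, "be_bounds"))
  check_number(arc, "arc", lower = 0, strict_lower = TRUE)
  pred <- predict_auc(bounds$model, arc)
  in_arc <- arc >= bounds$arc_lower && arc <= bounds$arc_upper
  if (ci_mode) {
    if (is.null(arc_ci) || length(arc_ci) != 2L)
      stop("ci_mode requires `arc_ci = c(lower, upper)`", call. = FALSE)
    in_arc <- in_arc && arc_ci[1] >= bounds$arc_lower &&
      arc_ci[2] <= bounds$arc_upper
  }
  in_auc <- pred >= bounds$auc_lower && pred <= bounds$auc_upper
  structure(
    list(product_id = product_id, arc = arc, predicted_auc = pred,
         within_arc_window = in_arc, within_auc_window = in_auc,
         verdict = if (in_arc) "BE" else "non-BE", ci_mode = ci_mode),
    class = "be_verdict")
}

#' @export
print.be_verdict <- function(x, ...) {
  cat(sprintf("%s: ARC %.2f, predicted AUC %.2f -> %s\n",
              x$product_id, x$arc, x$predicted_auc, x$verdict))
  invisible(x)
}
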