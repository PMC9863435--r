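#' Assemble Level C correlation points
#'
#' One point per product-and-run: the in vitro apparent release constant
#' (ARC) paired with the in vivo tape-strip AUC. A product measured in
#' several IVRT runs contributes one point per run (against its single
#' observed AUC).
#'
#' @param product_id Character vector of product labels.
#' @param run_label Character vector identifying the IVRT run.
#' @param arc ARCs, ug/cm^2/min^(1/2); positive.
#' @param auc Observed AUCs, ug.% skin depth; non-negative.
#' @param arc_sd,auc_sd Optional dispersions carried into reports.
#' @return A data frame of class `ivivc_points`.
#' @export
ivivc_points <- function(product_id, run_label, arc, auc,
                         arc_sd = NA_real_, auc_sd = NA_real_) {
  if (any(arc <= 0)) stop("arc must be > 0", call. = FALSE)
  if (any(auc < 0)) stop("auc must be >= 0", call. = FALSE)
  structure(data.frame(product_id = product_id, run_label = run_label,
                       arc = arc, auc = auc, arc_sd = arc_sd,
                       auc_sd = auc_sd),
            class = c("ivivc_points", "data.frame"))
}

#' Fit the Level C correlation
#'
#' Ordinary least squares of in vivo AUC on in vitro ARC:
#' `AUC = a * ARC + b`. An optional weighted fit is available; the
#' default is unweighted.
#'
#' @param points An [ivivc_points()] data frame (or any data frame with
#'   `arc` and `auc` columns), >= 3 rows with non-zero ARC variance.
#' @param weights Optional non-negative weights, one per point.
#' @return An `ivivc_model`: `slope`, `intercept`, `r_squared`, `n`,
#'   and the points used.
#' @export
fit_level_c <- function(points, weights = NULL) {
  if (!is.data.frame(points) || !all(c("arc", "auc") %in% names(points)))
    stop("`points` must have columns arc and auc", call. = FALSE)
  x <- points$arc
  y <- points$auc
  if (length(x) < 3L) stop("need >= 3 points", call. = FALSE)
  w <- if (is.null(weights)) rep(1, length(x)) else weights
  if (length(w) != length(x) || any(w < 0))
    stop("`weights` must be non-negative, one per point", call. = FALSE)
  mx <- sum(w * x) / sum(w)
  my <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - mx)^2)
  if (sxx == 0) stop("zero variance in ARC", call. = FALSE)
  slope <- sum(w * (x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  syy <- sum(w * (y - my)^2)
  r2 <- if (syy > 0) slope^2 * sxx / syy else 1
  structure(
    list(slope = slope, intercept = intercept,
         r_squared = max(0, min(1, r2)), n = length(x), points = points,
         weighted = !is.null(weights)),
    class = "ivivc_model")
}

#' @export
print.ivivc_model <- function(x, ...) {
  cat(sprintf("Level C IVIVC: AUC = %.4f * ARC + %.3f (R^2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Predict in vivo AUC from an ARC
#'
#' @param model An `ivivc_model`.
#' @param arc ARC value(s), > 0.
#' @return Predicted AUC(s), ug.% skin depth (full precision; round to 2
#'   decimals for reporting).
#' @export
predict_auc <- function(model, arc) {
  stopifnot(inherits(model, "ivivc_model"))
  if (any(arc <= 0)) stop("arc must be > 0", call. = FALSE)
  model$slope * arc + model$intercept
}

#' Observed-vs-predicted agreement as a two-value CV
#'
#' For each product the observed and predicted AUC form a pair; the CV of
#' the pair is the sample SD (n-1, i.e. `|obs - pred| / sqrt(2)`)
#' divided by the pair mean, in percent.
#'
#' @param observed,predicted Positive AUC vectors of equal length.
#' @return List with `cv` (per pair, %) and `max_cv`.
#' @export
prediction_cv <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  m <- (observed + predicted) / 2
  if (any(m <= 0)) stop("pair means must be > 0", call. = FALSE)
  cv <- abs(observed - predicted) / sqrt(2) / m * 100
  list(cv = cv, max_cv = max(cv))
}
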