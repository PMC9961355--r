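#' Root mean squared error of a forecast
#'
#' @param result a [forecast_result()].
#' @return `sqrt(mean((prediction - truth)^2))`.
#' @export
rmse <- function(result) {
  stopifnot(inherits(result, "forecast_result"))
  e <- result$prediction - result$truth
  sqrt(mean(e * e))
}

#' Risk-weighted RMSE
#'
#' Each squared error is weighted by the normalized BG risk score of the
#' corresponding point, so errors committed while the patient is in a
#' risky glucose state count for more:
#' `sqrt(sum(w * e^2) / sum(w))` with
#' `w = normalized_bg_risk(glucose_to_risk(truth))` by default.
#' Normalizing by `sum(w)` makes the metric reduce to the plain [rmse()]
#' under constant weights.
#'
#' @param result a glucose-scale [forecast_result()].
#' @param weight_on `"truth"` (default: weights reflect the clinical risk
#'   of the state being mis-forecast) or `"prediction"`.
#' @param params [risk_params()] for the weight transform.
#' @return the weighted RMSE.
#' @export
weighted_rmse <- function(result, weight_on = c("truth", "prediction"),
                          params = risk_params()) {
  stopifnot(inherits(result, "forecast_result"))
  weight_on <- match.arg(weight_on)
  if (result$scale != "glucose")
    stop("weighted_rmse is defined on glucose-scale results", call. = FALSE)
  basis <- if (weight_on == "truth") result$truth else result$prediction
  w <- normalized_bg_risk(glucose_to_risk(basis, params))
  # the transform never returns an exact float zero, so "all points at the
  # zero-risk glucose" is detected with a tolerance far below any real risk
  if (all(w < 1e-12))
    stop("undefined metric: every weight is zero (all points at zero-risk glucose)",
         call. = FALSE)
  e <- result$prediction - result$truth
  sqrt(sum(w * e * e) / sum(w))
}

#' Model-to-baseline RMSE ratio
#'
#' @param model_rmse,lm_rmse non-negative metrics; `lm_rmse` must be
#'   positive.
#' @return `model_rmse / lm_rmse`; values below 1 beat persistence.
#' @export
lm_ratio <- function(model_rmse, lm_rmse) {
  if (any(lm_rmse <= 0))
    stop("lm_rmse must be positive", call. = FALSE)
  model_rmse / lm_rmse
}

#' Clarke error grid zone of (reference, prediction) pairs
#'
#' Classifies each pair into the canonical five-zone Clarke error grid:
#' zone A is clinically accurate, B acceptable, C/D/E clinical errors of
#' increasing severity.  Rules are evaluated in order A, E, C, D, else B:
#'
#' * A: `r <= 70 & p <= 70`, or `|p - r| <= 0.2 r`
#' * E: `r >= 180 & p <= 70`, or `r <= 70 & p >= 180`
#' * C: `70 <= r <= 290 & p >= r + 110`, or
#'   `130 <= r <= 180 & p <= (7/5) r - 182`
#' * D: `r >= 240 & 70 <= p <= 180`, or `r <= 175/3 & 70 <= p <= 180`, or
#'   `175/3 <= r <= 70 & p >= (6/5) r`
#'
#' @param reference reference (truth) glucose, mg/dL, positive.
#' @param prediction predicted glucose, mg/dL, positive.
#' @return factor with levels A-E, one per pair.
#' @export
clarke_zone <- function(reference, prediction) {
  r <- as.numeric(reference); p <- as.numeric(prediction)
  if (length(r) != length(p))
    stop("reference and prediction must have equal length", call. = FALSE)
  if (any(!is.finite(r)) || any(!is.finite(p)) || any(r <= 0) || any(p <= 0))
    stop("clarke_zone requires positive finite glucose values", call. = FALSE)
  zone <- rep("B", length(r))
  isA <- (r <= 70 & p <= 70) | abs(p - r) <= 0.2 * r
  isE <- !isA & ((r >= 180 & p <= 70) | (r <= 70 & p >= 180))
  isC <- !isA & !isE &
    ((r >= 70 & r <= 290 & p >= r + 110) |
       (r >= 130 & r <= 180 & p <= (7 / 5) * r - 182))
  isD <- !isA & !isE & !isC &
    ((r >= 240 & p >= 70 & p <= 180) |
       (r <= 175 / 3 & p >= 70 & p <= 180) |
       (r >= 175 / 3 & r <= 70 & p >= (6 / 5) * r))
  zone[isA] <- "A"; zone[isE] <- "E"; zone[isC] <- "C"; zone[isD] <- "D"
  factor(zone, levels = c("A", "B", "C", "D", "E"))
}

#' Clarke error grid analysis of a glucose-scale forecast
#'
#' @param result a glucose-scale [forecast_result()].
#' @return a `clarke_zones` object: integer `counts` and numeric
#'   `fractions`, both named A-E; fractions sum to 1.
#' @export
clarke_analysis <- function(result) {
  stopifnot(inherits(result, "forecast_result"))
  if (result$scale != "glucose")
    stop("Clarke analysis is defined on glucose-scale results", call. = FALSE)
  z <- clarke_zone(result$truth, result$prediction)
  counts <- table(z)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(counts = counts, fractions = counts / sum(counts)),
            class = "clarke_zones")
}

#' @export
print.clarke_zones <- function(x, ...) {
  cat("<clarke_zones>\n")
  print(rbind(count = x$counts, fraction = round(x$fractions, 4)))
  invisible(x)
}

#' Per-zone count ratio between a model and the LM baseline
#'
#' @param model_counts,lm_counts `clarke_zones` objects on the same pairs.
#' @return named numeric of elementwise `model/lm` count ratios; zones
#'   where the LM count is zero are `NA` and listed in the `"undefined"`
#'   attribute rather than silently dropped.
#' @export
zone_ratio <- function(model_counts, lm_counts) {
  stopifnot(inherits(model_counts, "clarke_zones"),
            inherits(lm_counts, "clarke_zones"))
  m <- model_counts$counts; l <- lm_counts$counts
  out <- ifelse(l > 0, m / l, NA_real_)
  names(out) <- names(m)
  attr(out, "undefined") <- names(m)[l == 0]
  out
}

#' Convert a forecast result between scales
#'
#' xi-scale results convert to glucose via the inverse risk transform
#' (predictions outside the sensor-representable band are clipped to it,
#' see [xi_to_glucose()]); glucose-scale results convert to xi via the
#' forward transform.
#'
#' @param result a [forecast_result()].
#' @param scale target scale.
#' @param params [risk_params()].
#' @return a [forecast_result()] on the requested scale.
#' @export
convert_result <- function(result, scale = c("glucose", "xi"),
                           params = risk_params()) {
  stopifnot(inherits(result, "forecast_result"))
  scale <- match.arg(scale)
  if (result$scale == scale) return(result)
  f <- if (scale == "glucose") {
    function(v) xi_to_glucose(v, params)
  } else {
    function(v) glucose_to_xi(v, params)
  }
  forecast_result(truth = f(result$truth), prediction = f(result$prediction),
                  scale = scale, horizon_minutes = result$horizon_minutes,
                  model_name = result$model_name,
                  individual_id = result$individual_id)
}

#' All three standard metrics of one forecast
#'
#' Computes the xi RMSE, the CGM (glucose) RMSE, and the risk-weighted CGM
#' RMSE of one forecast, converting scale as needed.
#'
#' @param result a [forecast_result()] on either scale.
#' @param params [risk_params()].
#' @return named numeric: `xi_rmse`, `cgm_rmse`, `weighted_cgm_rmse`.
#' @export
forecast_metrics <- function(result, params = risk_params()) {
  glu <- convert_result(result, "glucose", params)
  xi <- convert_result(result, "xi", params)
  c(xi_rmse = rmse(xi),
    cgm_rmse = rmse(glu),
    weighted_cgm_rmse = weighted_rmse(glu, params = params))
}
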