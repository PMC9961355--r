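#' Kovatchev risk-scale parameters
#'
#' The symmetrizing transform `y = gamma * ((ln x)^alpha - beta)` maps
#' glucose `x` (mg/dL) to the blood-glucose (BG) risk variable `y`.  The
#' constants were fitted by Kovatchev and colleagues so that the clinically
#' asymmetric glucose range (hypoglycemia is compressed below ~70 mg/dL,
#' hyperglycemia stretched above ~180 mg/dL) becomes symmetric about the
#' zero-risk glucose `exp(beta^(1/alpha))` (about 112.5 mg/dL).
#'
#' @param alpha,beta,gamma positive transform constants.
#' @return a `risk_params` object.
#' @export
risk_params <- function(alpha = 1.084, beta = 5.381, gamma = 1.509) {
  stopifnot(alpha > 0, beta > 0, gamma > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "risk_params")
}

#' Glucose to BG-risk variable
#'
#' `y = gamma * ((ln x)^alpha - beta)`, strictly increasing in `x`.
#'
#' @param x glucose in mg/dL; must exceed 1 so that `ln x > 0` and the
#'   power is real.
#' @param params a [risk_params()].
#' @return risk variable `y`, same length as `x`.
#' @export
glucose_to_risk <- function(x, params = risk_params()) {
  if (any(!is.finite(x)) || any(x <= 1))
    stop("glucose must be finite and > 1 mg/dL for the risk transform",
         call. = FALSE)
  params$gamma * (log(x)^params$alpha - params$beta)
}

#' BG-risk variable to glucose (exact inverse)
#'
#' `x = exp((y/gamma + beta)^(1/alpha))`.
#'
#' @param y risk variable; `y/gamma + beta` must be positive.
#' @inheritParams glucose_to_risk
#' @return glucose in mg/dL.
#' @export
risk_to_glucose <- function(y, params = risk_params()) {
  z <- y / params$gamma + params$beta
  if (any(!is.finite(z)) || any(z <= 0))
    stop("risk value outside the invertible domain (y/gamma + beta <= 0)",
         call. = FALSE)
  exp(z^(1 / params$alpha))
}

#' Realized bounds of the risk variable over the CGM range
#'
#' With the printed constants, `y` over glucose \[39, 400\] spans roughly
#' \[-1.95, 2.39\] (and the standardized variable `xi = y/10` roughly
#' \[-0.195, 0.239\]) — comfortably inside the active region of `tanh`.
#'
#' @inheritParams glucose_to_risk
#' @return named numeric `c(lower, upper)` of `y` at glucose 39 and 400.
#' @export
risk_bounds <- function(params = risk_params()) {
  b <- glucose_to_risk(c(GLUCOSE_MIN, GLUCOSE_MAX), params)
  c(lower = b[1], upper = b[2])
}

#' BG risk score
#'
#' `BG(y) = 10 * y^2`: a symmetric, non-negative penalty that is zero only
#' at the zero-risk glucose and grows quadratically toward both
#' hypoglycemia and hyperglycemia.
#'
#' @param y risk variable.
#' @return risk score, `>= 0`.
#' @export
bg_risk_score <- function(y) 10 * y^2

#' Normalized BG risk score
#'
#' `y^2 / 10`, i.e. [bg_risk_score()] / 100; used as the weight in the
#' risk-weighted RMSE.
#'
#' @param y risk variable.
#' @return normalized score.
#' @export
normalized_bg_risk <- function(y) y^2 / 10

#' Map a fully imputed CGM series to the risk scale
#'
#' Produces the risk variable `y` and the standardized variable
#' `xi = y / 10` used as the networks' input/output scale (its magnitude
#' stays well below 1, where `tanh` has useful gradient).
#'
#' @param series a fully valid `cgm_series` (see [impute_series()]).
#' @inheritParams glucose_to_risk
#' @return a `risk_series` with fields `id`, `t0`, `dt`, `y`, `xi`.
#' @export
risk_series <- function(series, params = risk_params()) {
  stopifnot(inherits(series, "cgm_series"))
  if (!all(series$valid))
    stop("risk_series requires a fully imputed series", call. = FALSE)
  y <- glucose_to_risk(series$values, params)
  structure(list(id = series$id, t0 = series$t0, dt = series$dt,
                 y = y, xi = y / 10, params = params),
            class = "risk_series")
}

#' @export
length.risk_series <- function(x) length(x$y)

#' @export
print.risk_series <- function(x, ...) {
  cat(sprintf("<risk_series> id=%s  n=%d  xi in [%.3f, %.3f]\n",
              x$id, length(x$y), min(x$xi), max(x$xi)))
  invisible(x)
}

#' Standardize / destandardize the risk variable
#'
#' @param y risk variable values.
#' @return `standardize_risk()`: `y / 10`; `destandardize_risk()`: `xi * 10`.
#' @export
standardize_risk <- function(y) y / 10

#' @rdname standardize_risk
#' @param xi standardized values.
#' @export
destandardize_risk <- function(xi) xi * 10

#' Convert standardized predictions back to glucose
#'
#' Inverts the transform chain `glucose -> y -> xi`.  Values outside the
#' band representable by a CGM sensor (glucose in \[39, 400\]) are clipped
#' to the band edge first: a forecast outside the sensor range carries no
#' extra clinical meaning and the inverse transform is undefined for
#' `xi <= -gamma*beta/10`.
#'
#' @param xi standardized predictions.
#' @inheritParams glucose_to_risk
#' @param clip clip `xi` into the glucose-representable band (default TRUE).
#' @return glucose in mg/dL.
#' @export
xi_to_glucose <- function(xi, params = risk_params(), clip = TRUE) {
  if (clip) {
    b <- risk_bounds(params) / 10
    xi <- pmin(pmax(xi, b[["lower"]]), b[["upper"]])
  }
  risk_to_glucose(destandardize_risk(xi), params)
}

#' @rdname xi_to_glucose
#' @param x glucose in mg/dL; clipped into \[39, 400\] when `clip = TRUE`.
#' @export
glucose_to_xi <- function(x, params = risk_params(), clip = TRUE) {
  if (clip) x <- pmin(pmax(x, GLUCOSE_MIN), GLUCOSE_MAX)
  standardize_risk(glucose_to_risk(x, params))
}
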