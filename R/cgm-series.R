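#' Construct a CGM series on a regular time grid
#'
#' A `cgm_series` holds one individual's continuous glucose monitor (CGM)
#' trace as a regular grid of slots spaced `dt` minutes apart, together with
#' a validity mask.  Slots may carry a glucose reading in mg/dL, a sensor
#' error code, or nothing (`NA`); the mask records which slots currently
#' count as usable in-range measurements.
#'
#' @param values numeric vector of glucose readings (mg/dL); `NA` marks an
#'   empty slot.
#' @param valid logical mask, same length as `values`.  Defaults to
#'   `!is.na(values)`, i.e. a raw series where every recorded number is
#'   provisionally valid.
#' @param t0 timestamp of the first slot (`POSIXct`, timezone-naive by
#'   convention: only relative time matters downstream).
#' @param dt grid spacing in minutes (default 5, the typical CGM cadence).
#' @param id individual identifier string.
#'
#' @return An object of class `cgm_series` with fields `id`, `t0`, `dt`,
#'   `values`, `valid`.
#' @seealso [read_cgm_csv()], [clean_series()], [impute_series()]
#' @export
cgm_series <- function(values, valid = NULL,
                       t0 = as.POSIXct("2020-01-01 00:00:00", tz = "UTC"),
                       dt = 5, id = "individual") {
  values <- as.numeric(values)
  if (is.null(valid)) valid <- !is.na(values)
  valid <- as.logical(valid)
  if (length(values) != length(valid))
    stop("`values` and `valid` must have equal length", call. = FALSE)
  if (length(values) < 1L)
    stop("a cgm_series needs at least one slot", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number of minutes", call. = FALSE)
  structure(
    list(id = as.character(id), t0 = t0, dt = as.numeric(dt),
         values = values, valid = valid),
    class = "cgm_series"
  )
}

#' Validate a CGM series against its invariants
#'
#' A clean (non-raw) series must have every valid slot finite and inside
#' the CGM reporting range \[39, 400\] mg/dL.  Raw series (fresh from a
#' device export, before [clean_series()]) are only checked structurally.
#'
#' @param x a `cgm_series`.
#' @param raw if `TRUE`, skip the range check on valid slots.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_cgm_series <- function(x, raw = FALSE) {
  stopifnot(inherits(x, "cgm_series"))
  if (length(x$values) != length(x$valid))
    stop("values/valid length mismatch", call. = FALSE)
  if (length(x$values) < 2L)
    stop("cgm_series must have length >= 2", call. = FALSE)
  if (x$dt <= 0) stop("dt must be positive", call. = FALSE)
  if (!raw) {
    v <- x$values[x$valid]
    if (anyNA(v) || any(!is.finite(v)) || any(v < GLUCOSE_MIN | v > GLUCOSE_MAX))
      stop("valid slots must be finite and in [", GLUCOSE_MIN, ", ",
           GLUCOSE_MAX, "] mg/dL", call. = FALSE)
  }
  invisible(x)
}

# CGM sensors report interstitial glucose clipped to this range (mg/dL);
# anything outside is an error code or an out-of-range flag.
GLUCOSE_MIN <- 39
GLUCOSE_MAX <- 400

#' @export
length.cgm_series <- function(x) length(x$values)

#' @export
print.cgm_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<cgm_series> id=%s  n=%d slots  dt=%g min  invalid=%d (%.1f%%)\n",
              x$id, n, x$dt, sum(!x$valid), 100 * mean(!x$valid)))
  invisible(x)
}

#' Grid timestamps of a CGM series
#'
#' @param x a `cgm_series`.
#' @return `POSIXct` vector, one per slot.
#' @export
series_times <- function(x) {
  stopifnot(inherits(x, "cgm_series"))
  x$t0 + (seq_along(x$values) - 1L) * x$dt * 60
}
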