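#' Mark unusable CGM entries invalid
#'
#' Applies the standard CGM cleaning rule: any entry that is missing,
#' non-finite, or not a positive number (sensor error codes are typically 0
#' or negative) is marked invalid, as is any reading outside the sensor
#' reporting range \[39, 400\] mg/dL.  Values themselves are left untouched;
#' only the mask changes.  Invalid slots are later filled by
#' [impute_series()].
#'
#' @param series a raw `cgm_series` on the grid.
#' @return the series with an updated validity mask.
#' @export
clean_series <- function(series) {
  stopifnot(inherits(series, "cgm_series"))
  v <- series$values
  bad <- is.na(v) | !is.finite(v) | v <= 0 | v < GLUCOSE_MIN | v > GLUCOSE_MAX
  series$valid <- series$valid & !bad
  series
}

#' Trim leading and trailing invalid slots
#'
#' Gap imputation needs an anchor on both sides of every gap, so a series
#' must start and end with an in-range reading.  Removes invalid slots from
#' both ends; the interior is untouched.
#'
#' @param series a cleaned `cgm_series`.
#' @return the trimmed series, whose first and last slots are valid.
#' @export
trim_ends <- function(series) {
  stopifnot(inherits(series, "cgm_series"))
  idx <- which(series$valid)
  if (length(idx) == 0L)
    stop("empty series: no valid slot remains after cleaning", call. = FALSE)
  lo <- idx[1]; hi <- idx[length(idx)]
  series$values <- series$values[lo:hi]
  series$valid <- series$valid[lo:hi]
  series$t0 <- series$t0 + (lo - 1L) * series$dt * 60
  series
}

#' Locate maximal gap runs in a cleaned, trimmed series
#'
#' @param series a `cgm_series` whose first and last slots are valid.
#' @return a list of `gap_run` objects, each with 0-based `start_index`,
#'   `length`, and the flanking valid readings `left_anchor` /
#'   `right_anchor`; disjoint and in series order.  Empty list if the
#'   series has no invalid slot.
#' @export
find_gaps <- function(series) {
  stopifnot(inherits(series, "cgm_series"))
  if (!series$valid[1] || !series$valid[length(series$valid)])
    stop("find_gaps requires a trimmed series (valid endpoints)", call. = FALSE)
  r <- rle(series$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k]) next
    out[[length(out) + 1L]] <- gap_run(
      start_index = starts[k] - 1L,
      length = r$lengths[k],
      left_anchor = series$values[starts[k] - 1L],
      right_anchor = series$values[ends[k] + 1L]
    )
  }
  out
}

#' @rdname find_gaps
#' @param start_index 0-based grid slot of the first invalid point.
#' @param length number of consecutive invalid slots (>= 1).
#' @param left_anchor,right_anchor flanking valid glucose values (mg/dL).
#' @export
gap_run <- function(start_index, length, left_anchor, right_anchor) {
  stopifnot(length >= 1)
  structure(list(start_index = as.integer(start_index),
                 length = as.integer(length),
                 left_anchor = as.numeric(left_anchor),
                 right_anchor = as.numeric(right_anchor)),
            class = "gap_run")
}

#' Impute one gap run between two anchors
#'
#' Two readings of the floor-mean interpolation rule are provided:
#'
#' * `"recursive_floor"` (default) fills the run from its rightmost slot
#'   leftward: with in-run positions `1..length` and position `length + 1`
#'   standing for the right anchor, the value at position `n` is
#'   `floor((value at n+1 + left_anchor) / 2)`.  The midpoint rule for a
#'   single missing point, `floor((left + right)/2)`, is the `length = 1`
#'   special case.  This recursion decays geometrically toward the left
#'   anchor rather than following the straight line.
#' * `"linear_floor"`: position `n` gets
#'   `floor(left + n * (right - left) / (length + 1))` — the floor of the
#'   straight line between the anchors.
#'
#' Both rules keep every imputed value inside the closed interval spanned
#' by the anchors (for integer anchors), so imputation can never create an
#' out-of-range reading.
#'
#' @param gap a [gap_run()].
#' @param mode `"recursive_floor"` or `"linear_floor"`.
#' @return numeric vector of `gap$length` imputed glucose values.
#' @export
impute_gap <- function(gap, mode = c("recursive_floor", "linear_floor")) {
  mode <- match.arg(mode)
  stopifnot(inherits(gap, "gap_run"))
  a <- gap$left_anchor; b <- gap$right_anchor
  if (a < GLUCOSE_MIN || a > GLUCOSE_MAX || b < GLUCOSE_MIN || b > GLUCOSE_MAX)
    stop("gap anchors must lie in [", GLUCOSE_MIN, ", ", GLUCOSE_MAX, "]",
         call. = FALSE)
  n <- gap$length
  if (mode == "recursive_floor") {
    out <- numeric(n)
    nxt <- b
    for (i in seq(n, 1L)) {
      out[i] <- floor((nxt + a) / 2)
      nxt <- out[i]
    }
    out
  } else {
    floor(a + seq_len(n) * (b - a) / (n + 1))
  }
}

#' Fill every gap in a cleaned, trimmed series
#'
#' Applies [impute_gap()] independently to each maximal invalid run; valid
#' slots are bit-identical afterwards and every slot is valid.
#'
#' @param series a cleaned + trimmed `cgm_series`.
#' @param mode imputation rule, see [impute_gap()].
#' @return a fully valid `cgm_series`.
#' @export
impute_series <- function(series, mode = c("recursive_floor", "linear_floor")) {
  mode <- match.arg(mode)
  gaps <- find_gaps(series)
  for (g in gaps) {
    idx <- g$start_index + seq_len(g$length)  # 1-based slots of the run
    series$values[idx] <- impute_gap(g, mode)
    series$valid[idx] <- TRUE
  }
  validate_cgm_series(series)
  series
}

#' Clean, trim and impute in one call
#'
#' Convenience wrapper: [clean_series()], [trim_ends()], [impute_series()].
#'
#' @inheritParams impute_series
#' @param series a raw `cgm_series`.
#' @return a fully valid `cgm_series`.
#' @export
preprocess_series <- function(series, mode = c("recursive_floor", "linear_floor")) {
  mode <- match.arg(mode)
  impute_series(trim_ends(clean_series(series)), mode = mode)
}
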