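#' Window specification for supervised forecasting
#'
#' Two model families consume different input layouts:
#'
#' * `"recurrent"` (RNN/GRU/LSTM): 10 input points spaced one prediction
#'   horizon apart, so a window with base index `t` reads
#'   `t, t+h, ..., t+9h` and targets `t + 10h`, where
#'   `h = horizon_minutes / dt` grid steps.
#' * `"lattice"` (CNN): 16 consecutive points `t .. t+15` arranged
#'   row-major into a 4x4 lattice (earliest reading at position (1,1),
#'   time increasing along rows), targeting `t + 15 + h`.
#'
#' In both families the target sits exactly one horizon after the most
#' recent input point, so the model forecasts `horizon_minutes` ahead.
#'
#' @param family `"recurrent"` or `"lattice"`.
#' @param horizon_minutes prediction horizon, one of 15 / 30 / 60 minutes
#'   in the standard protocol (any multiple of `dt` is accepted).
#' @param dt grid spacing in minutes.
#' @param stride base-index advance between consecutive windows.
#' @param scale which signal the windows carry: `"xi"` (standardized risk)
#'   or `"glucose"` (mg/dL).
#' @param lattice_fill `"row"` (default) or `"col"` temporal fill order of
#'   the 4x4 lattice.
#' @return a `window_spec` object; `input_len` is fixed by the family
#'   (10 for recurrent, 16 for lattice).
#' @export
window_spec <- function(family = c("recurrent", "lattice"),
                        horizon_minutes = 30, dt = 5, stride = 1L,
                        scale = c("xi", "glucose"),
                        lattice_fill = c("row", "col")) {
  family <- match.arg(family)
  scale <- match.arg(scale)
  lattice_fill <- match.arg(lattice_fill)
  if (horizon_minutes %% dt != 0)
    stop("horizon_minutes must be divisible by dt", call. = FALSE)
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  structure(list(
    family = family,
    horizon_minutes = horizon_minutes,
    horizon_steps = as.integer(horizon_minutes / dt),
    input_len = if (family == "recurrent") 10L else 16L,
    stride = as.integer(stride),
    scale = scale,
    lattice_fill = lattice_fill
  ), class = "window_spec")
}

# pull the signal named by spec$scale out of either series class
series_signal <- function(series, scale) {
  if (inherits(series, "risk_series")) {
    if (scale == "xi") series$xi else risk_to_glucose(series$y, series$params)
  } else if (inherits(series, "cgm_series")) {
    if (!all(series$valid))
      stop("windowing requires a fully imputed series", call. = FALSE)
    if (scale == "glucose") series$values else glucose_to_xi(series$values)
  } else if (is.numeric(series)) {
    as.numeric(series)
  } else stop("unsupported series type", call. = FALSE)
}

series_id <- function(series) {
  if (is.list(series) && !is.null(series$id)) series$id else "series"
}

#' Build supervised windows
#'
#' `make_windows()` dispatches on `spec$family`;
#' `make_recurrent_windows()` and `make_lattice_windows()` are the
#' family-specific constructors.  Inputs are returned as a matrix with one
#' window per row (time increasing along the row; for the lattice family
#' the row is the row-major flattening of the 4x4 lattice) and targets as
#' a vector aligned to the rows.
#'
#' @param series a `risk_series`, a fully imputed `cgm_series`, or a bare
#'   numeric vector already on the spec's scale.
#' @param spec a [window_spec()].
#' @return a `window_set`: list with `inputs` (n x input_len matrix),
#'   `targets` (length n), `target_index` (1-based series index of each
#'   target), `spec`, `source_id`.  Too-short series yield an empty set
#'   with a warning.
#' @export
make_windows <- function(series, spec) {
  stopifnot(inherits(spec, "window_spec"))
  if (spec$family == "recurrent") make_recurrent_windows(series, spec)
  else make_lattice_windows(series, spec)
}

#' @rdname make_windows
#' @export
make_recurrent_windows <- function(series, spec) {
  stopifnot(inherits(spec, "window_spec"), spec$family == "recurrent")
  x <- series_signal(series, spec$scale)
  L <- length(x)
  h <- spec$horizon_steps
  n_base <- max(0L, L - 10L * h)  # base t (1-based) ranges over 1..n_base
  base <- seq_len(n_base)
  if (spec$stride > 1L) base <- base[seq(1L, length(base), by = spec$stride)]
  if (length(base) == 0L) {
    warning("series too short for any recurrent window", call. = FALSE)
    return(empty_window_set(spec, series_id(series)))
  }
  offs <- (0:9) * h
  inputs <- outer(base, offs, `+`)
  inputs[] <- x[inputs]
  tgt_idx <- base + 10L * h
  window_set(inputs, x[tgt_idx], tgt_idx, spec, series_id(series))
}

#' @rdname make_windows
#' @export
make_lattice_windows <- function(series, spec) {
  stopifnot(inherits(spec, "window_spec"), spec$family == "lattice")
  x <- series_signal(series, spec$scale)
  L <- length(x)
  h <- spec$horizon_steps
  n_base <- max(0L, L - 15L - h)
  base <- seq_len(n_base)
  if (spec$stride > 1L) base <- base[seq(1L, length(base), by = spec$stride)]
  if (length(base) == 0L) {
    warning("series too short for any lattice window", call. = FALSE)
    return(empty_window_set(spec, series_id(series)))
  }
  offs <- 0:15
  if (spec$lattice_fill == "col") {
    # row-major flattening of a column-major-filled lattice
    offs <- as.vector(t(matrix(0:15, 4, 4)))
  }
  inputs <- outer(base, offs, `+`)
  inputs[] <- x[inputs]
  tgt_idx <- base + 15L + h
  window_set(inputs, x[tgt_idx], tgt_idx, spec, series_id(series))
}

window_set <- function(inputs, targets, target_index, spec, source_id) {
  stopifnot(nrow(inputs) == length(targets))
  structure(list(inputs = inputs, targets = as.numeric(targets),
                 target_index = as.integer(target_index),
                 spec = spec, source_id = source_id),
            class = "window_set")
}

empty_window_set <- function(spec, source_id) {
  window_set(matrix(numeric(0), 0, spec$input_len), numeric(0), integer(0),
             spec, source_id)
}

#' @export
length.window_set <- function(x) nrow(x$inputs)

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %s  n=%d  input_len=%d  horizon=%d min  scale=%s\n",
              x$spec$family, nrow(x$inputs), x$spec$input_len,
              x$spec$horizon_minutes, x$spec$scale))
  invisible(x)
}

#' Combine window sets with identical specs
#'
#' Used to pool the training windows of several individuals.
#'
#' @param ... `window_set` objects sharing one spec.
#' @return a pooled `window_set` (source_id = comma-joined ids).
#' @export
bind_windows <- function(...) {
  ws <- list(...)
  if (length(ws) == 1L && is.list(ws[[1]]) && !inherits(ws[[1]], "window_set"))
    ws <- ws[[1]]
  stopifnot(length(ws) >= 1L, all(vapply(ws, inherits, TRUE, "window_set")))
  spec <- ws[[1]]$spec
  for (w in ws) stopifnot(identical(w$spec, spec))
  window_set(do.call(rbind, lapply(ws, `[[`, "inputs")),
             unlist(lapply(ws, `[[`, "targets")),
             unlist(lapply(ws, `[[`, "target_index")),
             spec,
             paste(vapply(ws, `[[`, "", "source_id"), collapse = ","))
}

#' Truncate a series to its first `max_len` grid points
#'
#' The training protocol fixes each individual's sample to 1e4
#' measurements (roughly 34 days at the 5-minute cadence).
#'
#' @param series a `cgm_series` or `risk_series`.
#' @param max_len maximum number of grid points kept (default 10000).
#' @return the truncated series (unchanged if already short enough).
#' @export
truncate_series <- function(series, max_len = 10000L) {
  stopifnot(max_len >= 1)
  if (inherits(series, "cgm_series")) {
    n <- min(length(series$values), max_len)
    series$values <- series$values[seq_len(n)]
    series$valid <- series$valid[seq_len(n)]
  } else if (inherits(series, "risk_series")) {
    n <- min(length(series$y), max_len)
    series$y <- series$y[seq_len(n)]
    series$xi <- series$xi[seq_len(n)]
  } else stop("unsupported series type", call. = FALSE)
  series
}
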