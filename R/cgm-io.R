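#' Read a CGM series from CSV onto a regular grid
#'
#' Reads a two-column CSV (`timestamp,glucose`, ISO-8601 timestamps, empty
#' glucose field for missing readings) and aligns the readings onto a
#' regular grid of spacing `dt` minutes anchored at the first timestamp.
#' Each raw timestamp is snapped to its nearest slot,
#' `round((t - t0) / dt)`; when two rows land on the same slot the first
#' (in file order) wins and a warning is issued.  Grid slots with no
#' reading, or with a non-numeric/missing glucose field, are marked
#' invalid.
#'
#' An optional header comment `# dt_minutes=<dt>` records the grid spacing;
#' an explicit `dt` argument overrides it.
#'
#' @param path CSV file path.
#' @param dt grid spacing in minutes; default taken from the file header
#'   comment, else 5.
#' @return a raw [cgm_series()] (no range filtering is applied here; see
#'   [clean_series()]).
#' @export
read_cgm_csv <- function(path, dt = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  header_dt <- NA_real_
  comment <- grep("^#", lines, value = TRUE)
  m <- regmatches(comment, regexec("dt_minutes=([0-9.]+)", comment))
  m <- Filter(function(g) length(g) == 2L, m)
  if (length(m) > 0) header_dt <- as.numeric(m[[1]][2])
  if (is.null(dt)) dt <- if (is.finite(header_dt)) header_dt else 5

  body <- lines[!grepl("^#", lines)]
  df <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n"),
                    colClasses = c("character", "character"),
                    strip.white = TRUE),
    error = function(e) stop("unparseable CGM CSV: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (!all(c("timestamp", "glucose") %in% names(df)))
    stop("CGM CSV must have header columns `timestamp,glucose`", call. = FALSE)
  if (nrow(df) < 2L)
    stop("insufficient data: need at least 2 rows", call. = FALSE)

  ts <- parse_iso_times(df$timestamp)
  if (anyNA(ts))
    stop("unparseable timestamp(s), e.g. `",
         df$timestamp[which(is.na(ts))[1]], "`", call. = FALSE)
  glucose <- suppressWarnings(as.numeric(df$glucose))

  t0 <- ts[1]
  slot <- as.integer(round(as.numeric(difftime(ts, t0, units = "mins")) / dt))
  if (any(slot < 0)) {
    # rows out of chronological order before the anchor: re-anchor at min
    t0 <- t0 + min(slot) * dt * 60
    slot <- slot - min(slot)
  }
  if (anyDuplicated(slot)) {
    warning(sum(duplicated(slot)),
            " reading(s) mapped to an already-occupied grid slot; keeping the first",
            call. = FALSE)
    keep <- !duplicated(slot)
    slot <- slot[keep]; glucose <- glucose[keep]
  }
  n <- max(slot) + 1L
  values <- rep(NA_real_, n)
  values[slot + 1L] <- glucose
  cgm_series(values, valid = !is.na(values), t0 = t0, dt = dt,
             id = sub("\\.csv$", "", basename(path)))
}

#' Write a CGM series to CSV
#'
#' Inverse of [read_cgm_csv()] on the grid representation: one row per grid
#' slot, invalid slots written with an empty glucose field, `dt` recorded in
#' a `# dt_minutes=` header comment.  `read_cgm_csv(write_cgm_csv(s))`
#' reproduces the grid, the mask, and every valid value exactly.
#'
#' @param series a `cgm_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cgm_csv <- function(series, path) {
  stopifnot(inherits(series, "cgm_series"))
  times <- format(series_times(series), "%Y-%m-%dT%H:%M:%S")
  glu <- ifelse(series$valid, format_glucose(series$values), "")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path, call. = FALSE))
  on.exit(close(con))
  writeLines(c(sprintf("# dt_minutes=%g", series$dt),
               "timestamp,glucose",
               paste(times, glu, sep = ",")), con)
  invisible(path)
}

format_glucose <- function(v) {
  out <- character(length(v))
  ok <- !is.na(v)
  # full precision so that roundtrip is exact
  out[ok] <- vapply(v[ok], function(x) format(x, digits = 17, scientific = FALSE),
                    character(1))
  out
}

parse_iso_times <- function(x) {
  x <- sub("T", " ", x, fixed = TRUE)
  tryCatch(
    as.POSIXct(x, tz = "UTC",
               tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                              "%Y-%m-%d")),
    error = function(e) rep(as.POSIXct(NA), length(x))
  )
}
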