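# Independent oracles and fixture builders used across the suite.
# Each oracle is written directly from the defining rule, with a different
# structure than the implementation it checks.

# Naive top-down recursion of the floor-mean imputation rule: the value at
# in-run position n (1-based) is floor((value at n+1 + left)/2), where
# position length+1 is the right anchor.
oracle_impute_recursive <- function(left, right, len) {
  val <- function(k) {
    if (k == len + 1L) return(right)
    floor((val(k + 1L) + left) / 2)
  }
  vapply(seq_len(len), val, numeric(1))
}

# Brute-force persistence RMSE: explicit loop, no vectorized shift.
oracle_lm_rmse <- function(x, h) {
  se <- 0
  n <- 0L
  for (t in (h + 1L):length(x)) {
    se <- se + (x[t] - x[t - h])^2
    n <- n + 1L
  }
  sqrt(se / n)
}

# Hand-coded scalar Clarke EGA classifier, written point-by-point from the
# canonical zone description (checked in a different rule order than the
# implementation: the non-overlapping zone bodies make order irrelevant
# except for A taking precedence).
oracle_clarke_point <- function(r, p) {
  within20 <- abs(p - r) <= 0.2 * r
  if ((r <= 70 && p <= 70) || within20) return("A")
  if (r >= 180 && p <= 70) return("E")
  if (r <= 70 && p >= 180) return("E")
  upperC <- r >= 70 && r <= 290 && p >= r + 110
  lowerC <- r >= 130 && r <= 180 && p <= (7 / 5) * r - 182
  if (upperC || lowerC) return("C")
  upperD <- r <= 175 / 3 && p >= 70 && p <= 180
  upperD2 <- r >= 175 / 3 && r <= 70 && p >= (6 / 5) * r
  lowerD <- r >= 240 && p >= 70 && p <= 180
  if (upperD || upperD2 || lowerD) return("D")
  "B"
}

# Exhaustive in-bounds window enumeration for stride-1 window counts.
oracle_window_count <- function(L, h, family) {
  n <- 0L
  for (t in seq_len(L)) {
    last_in <- if (family == "recurrent") t + 9L * h else t + 15L
    target <- last_in + h
    if (target <= L) n <- n + 1L
  }
  n
}

sample_skewness <- function(v) mean(((v - mean(v)) / stats::sd(v))^3)

# Fixtures -------------------------------------------------------------

# noiseless sinusoidal glucose series: period 4 h (48 steps at 5 min),
# range 80-200 mg/dL
sine_series <- function(L = 5000L) {
  glucose <- 140 + 60 * sin(2 * pi * (0:(L - 1)) / 48)
  cgm_series(glucose, dt = 5, id = "sine")
}

constant_series <- function(L = 2000L, level = 120) {
  cgm_series(rep(level, L), dt = 5, id = "const")
}

write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
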