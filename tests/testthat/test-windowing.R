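test_that("window counts match the closed formulas and exhaustive enumeration", {
  # spec'd boundary cases at h = 6 (30 min)
  expect_length(make_recurrent_windows(seq_len(100) / 100,
                                       window_spec("recurrent", 30)), 40)
  expect_length(make_recurrent_windows(seq_len(61) / 100,
                                       window_spec("recurrent", 30)), 1)
  expect_warning(
    w0 <- make_recurrent_windows(seq_len(60) / 100, window_spec("recurrent", 30)),
    "too short")
  expect_length(w0, 0)

  expect_length(make_lattice_windows(seq_len(100) / 100,
                                     window_spec("lattice", 30)), 79)
  expect_warning(
    l0 <- make_lattice_windows(seq_len(21) / 100, window_spec("lattice", 30)),
    "too short")
  expect_length(l0, 0)

  set.seed(404)
  for (i in 1:20) {
    L <- sample(20:300, 1)
    h <- sample(c(3, 6, 12), 1)
    x <- runif(L, -0.2, 0.25)
    for (family in c("recurrent", "lattice")) {
      expected <- oracle_window_count(L, h, family)
      spec <- window_spec(family, h * 5)
      w <- if (expected == 0)
        suppressWarnings(make_windows(x, spec)) else make_windows(x, spec)
      expect_length(w, expected)
    }
  }
})

test_that("recurrent windows stride inputs by the horizon and target one horizon ahead", {
  x <- seq_len(200)  # ramp: value equals index
  h <- 6
  w <- make_recurrent_windows(x, window_spec("recurrent", 30, scale = "glucose"))
  expect_equal(w$inputs[1, ], 1 + (0:9) * h)
  expect_equal(w$targets[1], 1 + 10 * h)
  expect_equal(w$inputs[5, ], 5 + (0:9) * h)
  # target is exactly one horizon after the last input, for every window
  expect_equal(w$targets, w$inputs[, 10] + h)
  expect_equal(w$target_index, w$inputs[, 10] + h)
})

test_that("lattice windows are row-major consecutive segments, target one horizon ahead", {
  x <- seq_len(100)
  h <- 6
  w <- make_lattice_windows(x, window_spec("lattice", 30, scale = "glucose"))
  expect_equal(w$inputs[1, ], 1:16)          # row-major ramp segment
  expect_equal(w$targets, w$inputs[, 16] + h)
  wc <- make_lattice_windows(x, window_spec("lattice", 30, scale = "glucose",
                                            lattice_fill = "col"))
  expect_equal(wc$inputs[1, ], as.vector(t(matrix(1:16, 4, 4))))
  expect_equal(wc$targets, w$targets)
})

test_that("no window references an index outside the series; stride-1 windows reconstruct it", {
  set.seed(405)
  for (i in 1:10) {
    L <- sample(80:250, 1)
    h <- sample(c(3, 6), 1)
    x <- runif(L)
    for (family in c("recurrent", "lattice")) {
      w <- suppressWarnings(make_windows(x, window_spec(family, h * 5,
                                                        scale = "glucose")))
      if (length(w) == 0) next
      expect_true(all(w$target_index >= 1 & w$target_index <= L))
      expect_true(all(is.finite(w$inputs)))
      # base indices step by 1, so column 1 walks the series prefix
      expect_equal(w$inputs[, 1], x[seq_len(nrow(w$inputs))])
      # reconstruct: targets + first column cover exactly their index sets
      expect_equal(w$targets, x[w$target_index])
    }
  }
})

test_that("xi-scale windows stay in (-1, 1)", {
  s <- cgm_series(round(runif(150, 39, 400)))
  rs <- risk_series(s)
  w <- make_windows(rs, window_spec("recurrent", 30, scale = "xi"))
  expect_true(all(abs(w$inputs) < 1) && all(abs(w$targets) < 1))
})

test_that("series truncation keeps the first max_len points", {
  s <- cgm_series(round(runif(12000, 39, 400)))
  t1 <- truncate_series(s)
  expect_length(t1, 10000)
  expect_equal(t1$values, s$values[1:10000])
  expect_length(truncate_series(cgm_series(round(runif(5000, 39, 400)))), 5000)
  # 1e4 points at 5-min cadence span 34 whole days
  expect_equal(floor(10000 * 5 / 1440), 34)
  rs <- risk_series(cgm_series(round(runif(400, 39, 400))))
  expect_length(truncate_series(rs, 100), 100)
})

test_that("window spec validates the horizon/dt relationship", {
  expect_error(window_spec("recurrent", 17), "divisible")
  expect_equal(window_spec("recurrent", 60)$horizon_steps, 12L)
  expect_equal(window_spec("recurrent", 30)$input_len, 10L)
  expect_equal(window_spec("lattice", 30)$input_len, 16L)
})

test_that("bind_windows pools sets and refuses mismatched specs", {
  spec <- window_spec("recurrent", 30, scale = "glucose")
  w1 <- make_windows(seq_len(100), spec)
  w2 <- make_windows(seq_len(80) + 200, spec)
  b <- bind_windows(w1, w2)
  expect_length(b, length(w1) + length(w2))
  expect_equal(b$inputs[length(w1) + 1, ], w2$inputs[1, ])
  w3 <- make_windows(seq_len(100), window_spec("recurrent", 15, scale = "glucose"))
  expect_error(bind_windows(w1, w3))
})
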