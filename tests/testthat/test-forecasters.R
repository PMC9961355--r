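test_that("model specs derive scale, loss and activation from the architecture", {
  s0 <- model_spec("RNN0")
  expect_equal(s0[c("activation", "scale", "loss", "train_k")],
               list(activation = "identity", scale = "glucose",
                    loss = "MSE", train_k = 1L))
  for (arch in c("RNN", "GRU", "LSTM", "CNN", "CNN10")) {
    s <- model_spec(arch)
    expect_equal(s$activation, "tanh")
    expect_equal(s$scale, "xi")
    expect_equal(s$loss, "MAE")
  }
  expect_equal(model_spec("CNN10")$train_k, 10L)
  expect_equal(model_spec("CNN")$window_family, "lattice")
  expect_equal(model_spec("GRU")$window_family, "recurrent")
  expect_error(model_spec("VGG"))
})

test_that("training is bit-reproducible from the seed and logs one loss per epoch", {
  rs <- risk_series(sine_series(800))
  ms <- model_spec("RNN", horizon_minutes = 30, seed = 99, epochs = 5)
  ws <- make_windows(rs, window_spec_for(ms))
  m1 <- train_model(build_model(ms), ws)
  m2 <- train_model(build_model(ms), ws)
  expect_identical(m1$training_log, m2$training_log)
  expect_identical(m1$params, m2$params)
  expect_length(m1$training_log, 5)
  expect_true(all(is.finite(m1$training_log)))
  # a different seed gives a different trajectory
  ms3 <- model_spec("RNN", horizon_minutes = 30, seed = 100, epochs = 5)
  m3 <- train_model(build_model(ms3), ws)
  expect_false(identical(m1$training_log, m3$training_log))
  # training does not disturb the global RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(train_model(build_model(ms), ws))
  expect_equal(runif(1), before)
})

test_that("training contract errors are raised", {
  rs <- risk_series(sine_series(800))
  ms <- model_spec("RNN", horizon_minutes = 30, seed = 1, epochs = 1)
  ws <- make_windows(rs, window_spec_for(ms))
  empty <- suppressWarnings(make_windows(rs$xi[1:20], window_spec_for(ms)))
  expect_error(train_model(build_model(ms), empty), "empty")
  wrong_scale <- make_windows(seq(80, 200, length.out = 800),
                              window_spec("recurrent", 30, scale = "glucose"))
  expect_error(train_model(build_model(ms), wrong_scale), "scale")
  wrong_family <- make_windows(rs, window_spec("lattice", 30, scale = "xi"))
  expect_error(train_model(build_model(ms), wrong_family), "family")
})

test_that("predictions align with targets; xi predictions stay in (-1, 1)", {
  rs <- risk_series(sine_series(600))
  ms <- model_spec("GRU", horizon_minutes = 30, seed = 3, epochs = 2)
  ws <- make_windows(rs, window_spec_for(ms))
  m <- train_model(build_model(ms), ws)
  fc <- predict(m, ws)
  expect_length(fc$prediction, length(ws))
  expect_equal(fc$truth, ws$targets)
  expect_true(all(abs(fc$prediction) < 1))
  expect_equal(fc$scale, "xi")
  # glucose conversion goes through the inverse risk transform
  glu <- convert_result(fc, "glucose")
  expect_equal(glu$prediction, xi_to_glucose(fc$prediction))
})

test_that("LM baseline matches hand arithmetic and the brute-force oracle", {
  fc <- lm_predict(c(100, 110, 120, 130), 1, scale = "glucose")
  expect_equal(fc$prediction, c(100, 110, 120))
  expect_equal(fc$truth, c(110, 120, 130))
  expect_equal(rmse(fc), 10)
  expect_length(fc$truth, 4 - 1)

  const <- lm_predict(rep(0.1, 50), 6, scale = "glucose")
  expect_equal(rmse(const), 0)

  set.seed(505)
  for (i in 1:30) {
    L <- sample(20:200, 1)
    h <- sample(1:12, 1)
    if (L <= h) next
    x <- runif(L, 39, 400)
    expect_equal(rmse(lm_predict(x, h, scale = "glucose")),
                 oracle_lm_rmse(x, h))
  }
  expect_error(lm_predict(c(1, 2), 5, scale = "glucose"), "too short")
})

test_that("windowed LM predicts each window's most recent input", {
  x <- seq_len(100)
  w <- make_windows(x, window_spec("recurrent", 30, scale = "glucose"))
  lm_fc <- lm_predict_windows(w)
  expect_equal(lm_fc$prediction, w$inputs[, 10])
  expect_equal(lm_fc$truth, w$targets)
  # equals the series-level persistence restricted to the window targets
  full <- lm_predict(x, 6, scale = "glucose")
  expect_equal(lm_fc$prediction,
               full$prediction[w$target_index - 6])
})

test_that("training-set selection takes the CV argmax plus a seeded random rest", {
  mk <- function(id, values) cgm_series(values, id = id)
  set.seed(7)
  cohort <- list(
    mk("low", rnorm(200, 150, 10)),   # CV ~ 0.07
    mk("high", rnorm(200, 150, 60)),  # CV ~ 0.40
    mk("mid", rnorm(200, 150, 30))    # CV ~ 0.20
  )
  cohort <- lapply(cohort, function(s) {
    s$values <- pmin(pmax(s$values, 39), 400); s
  })
  expect_equal(select_training_individuals(cohort, 1), "high")
  all3 <- select_training_individuals(cohort, 3, seed = 1)
  expect_setequal(all3, c("low", "high", "mid"))
  expect_equal(all3[1], "high")
  expect_identical(select_training_individuals(cohort, 2, seed = 5),
                   select_training_individuals(cohort, 2, seed = 5))
  expect_error(select_training_individuals(cohort, 4), "cohort size")
})

test_that("replicas of one cell differ only in seed and reproduce", {
  rs <- risk_series(sine_series(500))
  ws <- make_windows(rs, window_spec("recurrent", 30, scale = "xi"))
  seeds <- c(11, 12, 13)
  logs <- lapply(seeds, function(sd) {
    ms <- model_spec("RNN", horizon_minutes = 30, seed = sd, epochs = 3)
    train_model(build_model(ms), ws)$training_log
  })
  expect_length(unique(logs), 3)  # distinct trajectories
  relogs <- lapply(seeds, function(sd) {
    ms <- model_spec("RNN", horizon_minutes = 30, seed = sd, epochs = 3)
    train_model(build_model(ms), ws)$training_log
  })
  expect_identical(logs, relogs)
})
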