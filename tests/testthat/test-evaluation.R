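test_that("rmse matches hand arithmetic and is permutation-invariant", {
  perfect <- forecast_result(c(1, 2, 3), c(1, 2, 3), "glucose")
  expect_equal(rmse(perfect), 0)
  fc <- forecast_result(c(0, 0), c(3, 4), "xi")
  expect_equal(rmse(fc), sqrt(25 / 2))
  set.seed(606)
  t <- runif(50, 40, 400); p <- runif(50, 40, 400)
  o <- sample(50)
  expect_equal(rmse(forecast_result(t, p, "glucose")),
               rmse(forecast_result(t[o], p[o], "glucose")))
})

test_that("weighted rmse follows sqrt(sum(w e^2) / sum(w))", {
  # one effectively nonzero weight -> |error| at that point
  t <- c(112.5, 50)  # ~zero-risk point and a risky point
  p <- c(120, 60)
  fc <- forecast_result(t, p, "glucose")
  w <- normalized_bg_risk(glucose_to_risk(t))
  e <- p - t
  expect_equal(weighted_rmse(fc), sqrt(sum(w * e^2) / sum(w)))

  # hand case with explicit weights: errors (10, 0), weights (0.1, 0.4)
  expect_equal(sqrt((0.1 * 100 + 0.4 * 0) / 0.5), sqrt(20))

  # all-zero weights is an undefined metric
  zero_g <- risk_to_glucose(0)
  fcz <- forecast_result(rep(zero_g, 3), rep(zero_g, 3) + 5, "glucose")
  expect_error(weighted_rmse(fcz), "zero")

  # prediction-weighted variant runs and differs in general
  expect_false(isTRUE(all.equal(weighted_rmse(fc),
                                weighted_rmse(fc, weight_on = "prediction"))))

  expect_error(weighted_rmse(forecast_result(c(0.1), c(0.2), "xi")),
               "glucose-scale")
})

test_that("weighted rmse equals plain rmse under constant weights", {
  set.seed(607)
  for (i in 1:50) {
    g <- runif(1, 45, 350)
    n <- sample(3:40, 1)
    t <- rep(g, n)
    p <- t + rnorm(n, 0, 15)
    fc <- forecast_result(t, pmax(p, 1.5), "glucose")
    expect_equal(weighted_rmse(fc), rmse(fc), tolerance = 1e-12)
  }
})

test_that("lm_ratio is a guarded quotient", {
  expect_equal(lm_ratio(10, 10), 1)
  expect_equal(lm_ratio(8, 10), 0.8)
  expect_error(lm_ratio(1, 0), "positive")
})

test_that("Clarke zones match the rule table on hand cases", {
  expect_equal(as.character(clarke_zone(100, 100)), "A")
  expect_equal(as.character(clarke_zone(200, 60)), "E")
  expect_equal(as.character(clarke_zone(100, 215)), "C")
  expect_equal(as.character(clarke_zone(60, 65)), "A")    # both hypo
  expect_equal(as.character(clarke_zone(250, 100)), "D")
  expect_equal(as.character(clarke_zone(50, 100)), "D")
  expect_equal(as.character(clarke_zone(150, 25)), "C")
  expect_equal(as.character(clarke_zone(100, 130)), "B")
  expect_error(clarke_zone(-5, 100), "positive")
  expect_error(clarke_zone(100, c(90, 80)), "equal length")
})

test_that("every grid point maps to exactly one zone, matching the scalar oracle", {
  g <- seq(6, 600, by = 6)  # 100 x 100 sweep of (0, 600]^2
  grid <- expand.grid(r = g, p = g)
  z <- clarke_zone(grid$r, grid$p)
  expect_false(anyNA(z))  # total partition
  oz <- mapply(oracle_clarke_point, grid$r, grid$p)
  expect_equal(as.character(z), unname(oz))
})

test_that("clarke_analysis counts and fractions are consistent", {
  set.seed(608)
  t <- runif(500, 40, 400)
  p <- pmax(t + rnorm(500, 0, 60), 1)
  fc <- forecast_result(t, p, "glucose")
  cz <- clarke_analysis(fc)
  expect_equal(sum(cz$counts), 500)
  expect_equal(sum(cz$fractions), 1, tolerance = 1e-12)
  expect_named(cz$counts, c("A", "B", "C", "D", "E"))
  perfect <- clarke_analysis(forecast_result(t, t, "glucose"))
  expect_equal(unname(perfect$fractions["A"]), 1)
  expect_error(clarke_analysis(forecast_result(c(0.1), c(0.1), "xi")),
               "glucose-scale")
})

test_that("zone ratios are elementwise and flag undefined zones", {
  set.seed(609)
  t <- runif(300, 40, 400)
  fc <- forecast_result(t, t * runif(300, 0.85, 1.15), "glucose")
  cz <- clarke_analysis(fc)
  expect_equal(unname(zone_ratio(cz, cz)[!is.na(zone_ratio(cz, cz))]),
               rep(1, sum(cz$counts > 0)))
  lm <- clarke_analysis(forecast_result(t, t, "glucose"))  # all zone A
  zr <- zone_ratio(cz, lm)
  expect_equal(unname(zr["A"]), unname(cz$counts["A"] / lm$counts["A"]))
  expect_true(all(c("B", "C", "D", "E") %in% attr(zr, "undefined")))
  expect_true(all(is.na(zr[attr(zr, "undefined")])))
})

test_that("xi and glucose metrics chain consistently", {
  set.seed(610)
  xi_t <- runif(200, -0.15, 0.2)
  xi_p <- xi_t + rnorm(200, 0, 0.02)
  fc <- forecast_result(xi_t, xi_p, "xi", horizon_minutes = 30)
  met <- forecast_metrics(fc)
  manual_glu <- forecast_result(xi_to_glucose(xi_t), xi_to_glucose(xi_p),
                                "glucose")
  expect_equal(unname(met["cgm_rmse"]), rmse(manual_glu))
  expect_equal(unname(met["xi_rmse"]), rmse(fc))
  expect_equal(unname(met["weighted_cgm_rmse"]), weighted_rmse(manual_glu))
  # converting a glucose result to xi and back is the identity inside the band
  glu <- convert_result(fc, "glucose")
  back <- convert_result(glu, "xi")
  expect_equal(back$prediction, fc$prediction, tolerance = 1e-9)
})
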