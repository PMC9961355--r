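#' Synthetic CGM simulation configuration
#'
#' The generator emulates the gross structure of donated CGM exports: a
#' right-skewed glucose distribution over the sensor range, meal-like
#' excursions, sensor error codes, out-of-range readings, and multi-point
#' dropout runs.  The latent trajectory is a mean-reverting (AR(1) /
#' discretized Ornstein-Uhlenbeck) process *in risk space*; pushing
#' symmetric risk-space noise through the convex inverse risk transform
#' produces the right skew characteristic of real CGM histograms with a
#' single mechanism.  Meal excursions (Poisson arrivals, linear rise then
#' exponential decay) add further right skew.  The mean-reversion center
#' is chosen so that the long-run mean glucose, including the expected
#' meal uplift, sits at `basal_glucose`.
#'
#' @param n_individuals cohort size.
#' @param series_len grid points per individual.
#' @param dt grid spacing, minutes.
#' @param basal_glucose target long-run mean glucose, mg/dL.
#' @param reversion_rate per-step mean-reversion rate theta in (0, 1].
#' @param noise_sd innovation standard deviation, in risk units per step.
#'   The default 0.1, with `reversion_rate = 0.05`, gives a stationary
#'   glucose spread of roughly 20-30 mg/dL — ordinary glycemic
#'   variability.
#' @param meal_rate meal events per day.
#' @param meal_amplitude two-element range (mg/dL) of the uniform meal
#'   peak height; \[40, 120\] covers small snacks to large meals.
#' @param meal_rise_steps grid steps of linear rise to the meal peak
#'   (default 4 = 20 min).
#' @param meal_decay_steps exponential decay time constant in grid steps
#'   (default 12 = 1 h).
#' @param invalid_frac target fraction of slots replaced by artifacts, in
#'   \[0, 0.3\].
#' @param artifact_mix proportions (summing to 1) of the four artifact
#'   types: non-positive error codes, below-39 readings, above-400
#'   readings, missing values.
#' @param seed master RNG seed.
#' @return a `sim_config`.
#' @export
sim_config <- function(n_individuals = 10L, series_len = 2000L, dt = 5,
                       basal_glucose = 120, reversion_rate = 0.05,
                       noise_sd = 0.1, meal_rate = 3,
                       meal_amplitude = c(40, 120),
                       meal_rise_steps = 4L, meal_decay_steps = 12L,
                       invalid_frac = 0.02,
                       artifact_mix = c(nonpositive = 0.25, below = 0.25,
                                        above = 0.25, missing = 0.25),
                       seed = 1L) {
  stopifnot(n_individuals >= 1, series_len >= 2,
            reversion_rate > 0, reversion_rate <= 1,
            noise_sd >= 0, meal_rate >= 0,
            length(meal_amplitude) == 2, meal_amplitude[1] <= meal_amplitude[2],
            meal_rise_steps >= 1, meal_decay_steps >= 1,
            invalid_frac >= 0, invalid_frac <= 0.3,
            length(artifact_mix) == 4)
  if (abs(sum(artifact_mix) - 1) > 1e-8)
    stop("artifact_mix proportions must sum to 1", call. = FALSE)
  structure(list(n_individuals = as.integer(n_individuals),
                 series_len = as.integer(series_len), dt = dt,
                 basal_glucose = basal_glucose,
                 reversion_rate = reversion_rate, noise_sd = noise_sd,
                 meal_rate = meal_rate, meal_amplitude = meal_amplitude,
                 meal_rise_steps = as.integer(meal_rise_steps),
                 meal_decay_steps = as.integer(meal_decay_steps),
                 invalid_frac = invalid_frac, artifact_mix = artifact_mix,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# expected mean uplift (mg/dL) contributed by meal bumps
meal_uplift <- function(config) {
  steps_per_day <- 1440 / config$dt
  rate_per_step <- config$meal_rate / steps_per_day
  amp_mean <- mean(config$meal_amplitude)
  amp_mean * (config$meal_rise_steps / 2 + config$meal_decay_steps) * rate_per_step
}

#' Simulate one individual's raw CGM series
#'
#' See [sim_config()] for the generative model.  Artifacts replace a
#' random `invalid_frac` of slots, placed in runs with geometric lengths
#' (mean 2) so that multi-point gaps exercise the recursive branch of the
#' imputation rule.  The latent glucose is clipped to the sensor range
#' \[39, 400\] before artifact injection, so with `invalid_frac = 0` the
#' series is already fully valid.
#'
#' @param config a [sim_config()].
#' @param id individual identifier.
#' @param seed per-individual seed (defaults to `config$seed`).
#' @return a raw [cgm_series()] (artifacts present; run [clean_series()]
#'   etc. downstream).
#' @export
simulate_individual <- function(config, id = "sim-1", seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    L <- config$series_len
    theta <- config$reversion_rate
    target <- max(config$basal_glucose - meal_uplift(config), GLUCOSE_MIN + 1)
    mu <- glucose_to_risk(target)
    y <- numeric(L)
    y[1] <- mu + stats::rnorm(1, 0, config$noise_sd / sqrt(2 * theta))
    innov <- stats::rnorm(L - 1, 0, config$noise_sd)
    for (t in 2:L) y[t] <- y[t - 1] + theta * (mu - y[t - 1]) + innov[t - 1]
    glucose <- risk_to_glucose(pmin(pmax(y, -5), 5))

    # meal bumps: Poisson arrivals, linear rise then exponential decay
    p_meal <- config$meal_rate * config$dt / 1440
    onsets <- which(stats::runif(L) < p_meal)
    if (length(onsets) > 0) {
      rise <- config$meal_rise_steps
      decay <- config$meal_decay_steps
      tail_len <- rise + 6L * decay
      shape <- c(seq_len(rise) / rise, exp(-(seq_len(6L * decay)) / decay))
      bump <- numeric(L)
      for (on in onsets) {
        amp <- stats::runif(1, config$meal_amplitude[1], config$meal_amplitude[2])
        idx <- on + seq_len(tail_len) - 1L
        keep <- idx <= L
        bump[idx[keep]] <- bump[idx[keep]] + amp * shape[keep]
      }
      glucose <- glucose + bump
    }
    glucose <- pmin(pmax(glucose, GLUCOSE_MIN), GLUCOSE_MAX)
    values <- round(glucose)  # CGM devices report integer mg/dL

    # artifact injection in geometric runs (mean length 2)
    n_bad <- round(config$invalid_frac * L)
    if (n_bad > 0) {
      bad <- logical(L)
      guard <- 0L
      while (sum(bad) < n_bad && guard < 10L * L) {
        guard <- guard + 1L
        start <- sample.int(L, 1L)
        len <- min(stats::rgeom(1, 0.5) + 1L, n_bad - sum(bad))
        idx <- start:min(start + len - 1L, L)
        bad[idx] <- TRUE
      }
      idx_bad <- which(bad)
      kinds <- sample(names(config$artifact_mix), length(idx_bad),
                      replace = TRUE, prob = config$artifact_mix)
      values[idx_bad] <- vapply(kinds, function(k) {
        switch(k,
               nonpositive = sample(c(0, -1), 1L),
               below = round(stats::runif(1, 20, 38)),
               above = round(stats::runif(1, 401, 500)),
               missing = NA_real_)
      }, numeric(1))
    }
    cgm_series(values, valid = !is.na(values), dt = config$dt, id = id)
  })
}

#' Simulate a cohort of independent individuals
#'
#' Per-individual sub-seeds are derived deterministically from the master
#' seed; basal glucose and noise level are jittered across individuals so
#' that coefficients of variation differ and the CV-argmax training
#' selector has a meaningful target.
#'
#' @param config a [sim_config()].
#' @return list of raw `cgm_series`, ids `"sim-1" .. "sim-n"`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  jit <- with_seed(config$seed, list(
    basal = stats::rnorm(config$n_individuals, 0, 10),
    noise = stats::runif(config$n_individuals, 0.7, 1.5)
  ))
  lapply(seq_len(config$n_individuals), function(i) {
    ci <- config
    ci$basal_glucose <- max(90, min(180, config$basal_glucose + jit$basal[i]))
    ci$noise_sd <- config$noise_sd * jit$noise[i]
    # sub-seed: deterministic, distinct, and < 2^31
    sub_seed <- (config$seed + i * 7919L) %% .Machine$integer.max
    simulate_individual(ci, id = paste0("sim-", i), seed = sub_seed)
  })
}

#' Write a simulated cohort to per-individual CSVs plus a manifest
#'
#' @param cohort list of `cgm_series` (e.g. from [simulate_cohort()]).
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- vapply(cohort, function(s) {
    f <- file.path(dir, paste0(s$id, ".csv"))
    write_cgm_csv(s, f)
    basename(f)
  }, character(1))
  manifest <- file.path(dir, "cohort.json")
  jsonlite::write_json(
    list(n_individuals = length(cohort),
         files = files,
         ids = vapply(cohort, `[[`, "", "id")),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing per-individual CSVs (and optionally a
#'   `cohort.json` manifest; without one, every `*.csv` file is read).
#' @return list of raw `cgm_series`.
#' @export
read_cohort <- function(dir) {
  manifest <- file.path(dir, "cohort.json")
  files <- if (file.exists(manifest)) {
    file.path(dir, jsonlite::read_json(manifest, simplifyVector = TRUE)$files)
  } else {
    list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  }
  if (length(files) == 0) stop("no cohort CSVs found in ", dir, call. = FALSE)
  lapply(files, read_cgm_csv)
}
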