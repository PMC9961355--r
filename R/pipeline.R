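#' Experiment configuration
#'
#' Describes a full simulate/load -> preprocess -> transform -> train ->
#' evaluate experiment.  Replica seeds are derived deterministically from
#' the master `seed` unless given explicitly.
#'
#' @param source either a [sim_config()] (cohort is simulated) or a
#'   directory path of per-individual CSVs (see [read_cohort()]).
#' @param horizons prediction horizons in minutes, subset of
#'   `c(15, 30, 60)` by convention.
#' @param arches architecture prefixes, subset of
#'   `c("RNN0","RNN","GRU","LSTM","CNN","CNN10")`.
#' @param replicas replicas per (arch, horizon) cell; replicas differ only
#'   in their seed.
#' @param seeds optional explicit replica seeds (length `replicas`).
#' @param seed master seed: drives the cohort simulation, the training-set
#'   selection and the derived replica seeds.
#' @param impute_mode gap imputation rule, see [impute_gap()].
#' @param max_len per-individual truncation length (default 10000 points,
#'   about 34 days at 5-minute cadence).
#' @param hidden,epochs,lr,batch forwarded to [model_spec()].
#' @param out_dir optional directory; when set, the report CSV and config
#'   JSON are written there.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(source,
                              horizons = c(30),
                              arches = c("RNN0", "RNN", "GRU", "LSTM", "CNN", "CNN10"),
                              replicas = 1L, seeds = NULL, seed = 1L,
                              impute_mode = "recursive_floor",
                              max_len = 10000L,
                              hidden = 16L, epochs = 50L, lr = 1e-3,
                              batch = 64L, out_dir = NULL) {
  arches <- match.arg(arches, several.ok = TRUE)
  if (is.null(seeds)) seeds <- (seed * 1000L + seq_len(replicas)) %% .Machine$integer.max
  if (length(seeds) != replicas)
    stop("need exactly `replicas` seeds", call. = FALSE)
  structure(list(source = source, horizons = horizons, arches = arches,
                 replicas = as.integer(replicas), seeds = as.integer(seeds),
                 seed = as.integer(seed), impute_mode = impute_mode,
                 max_len = as.integer(max_len), hidden = as.integer(hidden),
                 epochs = as.integer(epochs), lr = lr,
                 batch = as.integer(batch), out_dir = out_dir),
            class = "experiment_config")
}

#' Run a full forecasting experiment
#'
#' For each (arch, horizon, replica): selects training individuals by the
#' CV rule (`k = 10` for CNN10, else 1), pools their windows, trains for
#' the configured number of epochs, and evaluates on every held-out
#' individual.  Each held-out individual also gets one persistence (LM)
#' row per (arch, horizon) cell, computed on exactly the same
#' (input, target) pairs as the model's predictions; model `lm_ratio` is
#' the CGM-RMSE ratio against that aligned LM forecast.
#'
#' @param config an [experiment_config()].
#' @return an `evaluation_report`: list with `report` (one data.frame row
#'   per individual x model x horizon, columns `individual_id`, `arch`,
#'   `model_name`, `horizon`, `xi_rmse`, `cgm_rmse`, `weighted_cgm_rmse`,
#'   `lm_ratio`), `summary` (cohort median/quartiles per model x horizon),
#'   `train_ids` (per arch), and `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))

  cohort <- if (inherits(config$source, "sim_config")) {
    simulate_cohort(config$source)
  } else if (is.character(config$source)) {
    read_cohort(config$source)
  } else stop("unsupported experiment source", call. = FALSE)

  prepped <- lapply(cohort, function(s)
    truncate_series(preprocess_series(s, mode = config$impute_mode),
                    max_len = config$max_len))
  names(prepped) <- vapply(prepped, `[[`, "", "id")
  risk <- lapply(prepped, risk_series)

  rows <- list()
  train_ids_by_k <- list()
  for (arch in config$arches) {
    spec0 <- model_spec(arch, horizon_minutes = config$horizons[1],
                        hidden = config$hidden, seed = 1L)
    k <- spec0$train_k
    kk <- as.character(k)
    if (is.null(train_ids_by_k[[kk]]))
      train_ids_by_k[[kk]] <- select_training_individuals(prepped, k,
                                                          seed = config$seed)
    train_ids <- train_ids_by_k[[kk]]
    test_ids <- setdiff(names(prepped), train_ids)
    for (horizon in config$horizons) {
      for (r in seq_len(config$replicas)) {
        mspec <- model_spec(arch, horizon_minutes = horizon,
                            hidden = config$hidden, dt = prepped[[1]]$dt,
                            seed = config$seeds[r], epochs = config$epochs,
                            lr = config$lr, batch = config$batch)
        wspec <- window_spec_for(mspec)
        series_for <- function(id)
          if (mspec$scale == "xi") risk[[id]] else prepped[[id]]
        train_windows <- bind_windows(lapply(train_ids, function(id)
          make_windows(series_for(id), wspec)))
        model <- train_model(build_model(mspec), train_windows)
        model_name <- paste0(arch, "_", r)
        for (id in test_ids) {
          w <- make_windows(series_for(id), wspec)
          if (nrow(w$inputs) == 0L) next
          w$source_id <- id
          fc <- stats::predict(model, w)
          fc$model_name <- model_name
          lm_fc <- lm_predict_windows(w)
          met <- forecast_metrics(fc)
          lm_met <- forecast_metrics(lm_fc)
          rows[[length(rows) + 1L]] <- data.frame(
            individual_id = id, arch = arch, model_name = model_name,
            horizon = horizon,
            xi_rmse = met[["xi_rmse"]], cgm_rmse = met[["cgm_rmse"]],
            weighted_cgm_rmse = met[["weighted_cgm_rmse"]],
            lm_ratio = lm_ratio(met[["cgm_rmse"]], lm_met[["cgm_rmse"]]),
            stringsAsFactors = FALSE)
          if (r == 1L) {
            rows[[length(rows) + 1L]] <- data.frame(
              individual_id = id, arch = arch, model_name = "LM",
              horizon = horizon,
              xi_rmse = lm_met[["xi_rmse"]], cgm_rmse = lm_met[["cgm_rmse"]],
              weighted_cgm_rmse = lm_met[["weighted_cgm_rmse"]],
              lm_ratio = lm_ratio(lm_met[["cgm_rmse"]], lm_met[["cgm_rmse"]]),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  report <- do.call(rbind, rows)
  out <- structure(list(report = report,
                        summary = summarize_report(report),
                        train_ids = train_ids_by_k,
                        config = config),
                   class = "evaluation_report")
  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
    utils::write.csv(report, file.path(config$out_dir, "report.csv"),
                     row.names = FALSE)
    cfg <- config
    cfg$source <- if (inherits(cfg$source, "sim_config"))
      unclass(cfg$source) else cfg$source
    jsonlite::write_json(unclass(cfg),
                         file.path(config$out_dir, "experiment.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' Cohort summary of a per-individual report
#'
#' @param report the per-row data.frame of an `evaluation_report`.
#' @return data.frame of median and quartiles of each metric per
#'   (model_name, horizon).
#' @export
summarize_report <- function(report) {
  split_by <- interaction(report$model_name, report$horizon, drop = TRUE)
  do.call(rbind, lapply(split(report, split_by), function(d) {
    q <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    qc <- q(d$cgm_rmse); qx <- q(d$xi_rmse); ql <- q(d$lm_ratio)
    data.frame(model_name = d$model_name[1], horizon = d$horizon[1],
               n_individuals = nrow(d),
               cgm_rmse_q1 = qc[1], cgm_rmse_med = qc[2], cgm_rmse_q3 = qc[3],
               xi_rmse_med = qx[2], lm_ratio_med = ql[2],
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d rows (%d individuals, %d model cells)\n",
              nrow(x$report), length(unique(x$report$individual_id)),
              length(unique(paste(x$report$model_name, x$report$horizon)))))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
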