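# Forecast accuracy metrics and the model / wavelet-basis comparison
# harnesses.

#' Forecast accuracy metrics
#'
#' MSE, MAE, RMSE and the coefficient of determination
#' R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2), computed on
#' physical-unit predictions.
#'
#' @param actual,predicted numeric vectors of equal length, n >= 2.
#' @return object of class \code{forecast_metrics}: list with \code{mse},
#'   \code{mae}, \code{rmse}, \code{r2}, \code{n}.
#' @examples
#' forecast_metrics(c(0, 2), c(1, 1))   # mse = mae = rmse = 1, r2 = 0
#' @export
forecast_metrics <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted))
  if (length(actual) < 2L) stop("need at least 2 observations")
  if (any(!is.finite(actual)) || any(!is.finite(predicted)))
    stop("non-finite values in metrics input")
  sst <- sum((actual - mean(actual))^2)
  if (sst == 0) stop("R2 undefined: actual series is constant")
  err <- actual - predicted
  mse <- mean(err^2)
  structure(list(mse = mse, mae = mean(abs(err)), rmse = sqrt(mse),
                 r2 = 1 - sum(err^2) / sst, n = length(actual)),
            class = "forecast_metrics")
}

#' @export
print.forecast_metrics <- function(x, ...) {
  cat(sprintf("MSE %.4f  MAE %.4f  RMSE %.4f  R2 %.4f  (n = %d)\n",
              x$mse, x$mae, x$rmse, x$r2, x$n))
  invisible(x)
}

#' Percentage error reductions against a baseline variant
#'
#' Adds, per (target, basis, seed) group, the columns \code{dmse_pct},
#' \code{dmae_pct}, \code{drmse_pct}: the percentage decrease of each error
#' metric relative to the baseline row of that group,
#' e.g. dMSE\% = (MSE_base - MSE_variant) / MSE_base x 100.
#'
#' @param tbl data.frame with a \code{variant} column and metric columns
#'   \code{mse}, \code{mae}, \code{rmse}.
#' @param baseline variant name serving as reference (default \code{"gru"}).
#' @return \code{tbl} with the delta columns appended.
#' @examples
#' tbl <- data.frame(variant = c("gru", "wavelet_eca_gru"),
#'                   mse = c(0.3660, 0.1857),
#'                   mae = c(0.5064, 0.3326),
#'                   rmse = c(0.6050, 0.4309))
#' metric_deltas(tbl)$dmse_pct[2]   # 49.26
#' @export
metric_deltas <- function(tbl, baseline = "gru") {
  stopifnot(all(c("variant", "mse", "mae", "rmse") %in% names(tbl)))
  keys <- intersect(c("target", "seed"), names(tbl))
  grp <- if (length(keys)) interaction(tbl[keys], drop = TRUE)
         else factor(rep(1L, nrow(tbl)))
  for (m in c("mse", "mae", "rmse")) tbl[[paste0("d", m, "_pct")]] <- NA_real_
  for (g in levels(grp)) {
    rows <- which(grp == g)
    base <- rows[tbl$variant[rows] == baseline]
    if (length(base) != 1L) next
    for (m in c("mse", "mae", "rmse"))
      tbl[[paste0("d", m, "_pct")]][rows] <-
        (tbl[[m]][base] - tbl[[m]][rows]) / tbl[[m]][base] * 100
  }
  tbl
}

#' Train and evaluate several model variants on identical splits
#'
#' Each (target, variant, seed) combination is fitted on the same
#' chronological split of the same series and scored on the held-out test
#' windows in physical units, yielding a comparison table with
#' percentage-change columns against the \code{gru} baseline.
#'
#' @param series an [aligned_series] ready for [wecagru()].
#' @param targets indicators to model (default both \code{"td"} and
#'   \code{"thi"}).
#' @param variants model variants to compare.
#' @param seeds integer seeds; every variant is run once per seed.
#' @param baseline reference variant for the delta columns.
#' @param ... further arguments passed to [wecagru()] (e.g.
#'   \code{hidden_dim}, \code{max_epochs}).
#' @return data.frame with one row per (target, variant, seed):
#'   \code{variant}, \code{target}, \code{basis}, \code{mse}, \code{mae},
#'   \code{rmse}, \code{r2}, \code{n}, \code{seed} plus delta columns.
#' @export
compare_models <- function(series, targets = c("td", "thi"),
                           variants = .variants, seeds = 1L,
                           baseline = "gru", ...) {
  rows <- list()
  dots <- list(...)
  basis <- if (!is.null(dots$wavelet)) dots$wavelet$basis else wavelet_config()$basis
  for (tg in targets) for (sd in seeds) for (v in variants) {
    fit <- wecagru(series, target = tg, variant = v, seed = sd, ...)
    p <- predict(fit)
    m <- forecast_metrics(p$actual, p$predicted)
    rows[[length(rows) + 1L]] <- data.frame(
      variant = v, target = tg,
      basis = if (fit$use_wavelet) basis else NA_character_,
      mse = m$mse, mae = m$mae, rmse = m$rmse, r2 = m$r2, n = m$n, seed = sd)
  }
  metric_deltas(do.call(rbind, rows), baseline = baseline)
}

#' Compare wavelet bases under an otherwise fixed model
#'
#' Re-fits the same wavelet variant varying only the wavelet basis, all
#' other parameters unchanged.
#'
#' @param series an [aligned_series] ready for [wecagru()].
#' @param targets indicators to model.
#' @param bases wavelet bases to compare (default db2, db4, sym4).
#' @param variant wavelet model variant (default \code{"wavelet_eca_gru"}).
#' @param seeds integer seeds.
#' @param levels,window wavelet decomposition depth and window length.
#' @param ... further arguments passed to [wecagru()].
#' @return data.frame with one row per (target, basis, seed).
#' @export
compare_wavelet_bases <- function(series, targets = c("td", "thi"),
                                  bases = c("db2", "db4", "sym4"),
                                  variant = "wavelet_eca_gru", seeds = 1L,
                                  levels = 3L, window = 56L, ...) {
  rows <- list()
  for (tg in targets) for (sd in seeds) for (bs in bases) {
    fit <- wecagru(series, target = tg, variant = variant, seed = sd,
                   wavelet = wavelet_config(basis = bs, levels = levels,
                                            window = window), ...)
    p <- predict(fit)
    m <- forecast_metrics(p$actual, p$predicted)
    rows[[length(rows) + 1L]] <- data.frame(
      variant = variant, target = tg, basis = bs,
      mse = m$mse, mae = m$mae, rmse = m$rmse, r2 = m$r2, n = m$n, seed = sd)
  }
  do.call(rbind, rows)
}

#' Synthetic forecasting benchmark at reduced scale
#'
#' Simulates one multi-source scenario, runs the full preprocessing chain,
#' then trains each variant once per model seed on identical splits and
#' scores the held-out test windows. The reduced scale (14 days, hidden
#' width 32, 5 model seeds, early-stopped training) keeps the benchmark
#' desk-sized while preserving the study's acquisition conditions.
#'
#' @param target \code{"td"} or \code{"thi"}.
#' @param variants variants to benchmark.
#' @param data_seed seed of the simulated scenario.
#' @param model_seeds one training run per seed.
#' @param days simulated duration, days.
#' @param hidden_dim reduced hidden width of every backbone.
#' @param max_epochs epoch cap; early stopping (patience 20 on the
#'   chronological validation tail) ends training long before it in
#'   practice.
#' @param config optional [scenario_config()] overriding the default
#'   benchmark scenario.
#' @param quiet suppress progress messages.
#' @return list with \code{table} (per-run metrics), \code{median_rmse}
#'   (named per variant), \code{noise_sd} (the generator's injected
#'   temperature noise sd) and \code{n} (test windows per run).
#' @export
synthetic_benchmark <- function(target = "td",
                                variants = c("wavelet_eca_gru", "gru"),
                                data_seed = 101L, model_seeds = 1:5,
                                days = 14L, hidden_dim = 32L,
                                max_epochs = 200L, config = NULL,
                                quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  if (is.null(config))
    config <- scenario_config(duration_days = days, seed = data_seed)
  say("benchmark: simulating ", config$duration_days, " days")
  sim <- simulate_house(config)
  ser <- prepare_series(sim$records, start_age = config$start_age,
                        schedule = sim$schedule)
  rm(sim)
  rows <- list()
  for (v in variants) for (sd in model_seeds) {
    say("benchmark: ", v, " seed ", sd)
    fit <- wecagru(ser, target = target, variant = v,
                   hidden_dim = hidden_dim, max_epochs = max_epochs,
                   seed = sd)
    p <- predict(fit)
    m <- forecast_metrics(p$actual, p$predicted)
    rows[[length(rows) + 1L]] <- data.frame(variant = v, seed = sd,
                                            mse = m$mse, mae = m$mae,
                                            rmse = m$rmse, r2 = m$r2,
                                            n = m$n)
  }
  tbl <- do.call(rbind, rows)
  med <- tapply(tbl$rmse, tbl$variant, stats::median)
  list(table = tbl, median_rmse = med[variants],
       noise_sd = config$noise_sd_temp, n = tbl$n[1])
}
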