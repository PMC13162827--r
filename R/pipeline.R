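# End-to-end pipeline plumbing: configuration, staged artifacts, a
# one-call driver. Each stage reads the previous stage's artifact from the
# output directory, writes its own, and embeds the configuration hash so
# mismatched artifacts are caught.

#' Standard preprocessing chain from raw records to a model-ready series
#'
#' Alignment to the 3-s grid, sensor-range filtering and 5-min aggregation,
#' flock context (age, target temperature), linear gap interpolation, and
#' the TD and THI indicators.
#'
#' @param records raw record data.frame (see [align_sources()]).
#' @param start_age broiler age on the first day of the records.
#' @param schedule an [age_schedule()].
#' @param indoor indoor source policy, \code{"all"} or \code{"robot"}.
#' @param step alignment grid spacing, seconds.
#' @param flock_start optional POSIXct flock start instant.
#' @return an [aligned_series] with Tin, RHin, Vin, CO2, Tout, RHout, Vout,
#'   Age, Ttarget, TD, THI and no missing cells.
#' @export
prepare_series <- function(records, start_age = 1L,
                           schedule = default_age_schedule(),
                           indoor = c("all", "robot"), step = 3,
                           flock_start = NULL) {
  indoor <- match.arg(indoor)
  ser <- align_sources(records, step = step)
  ser <- aggregate_5min(ser, indoor = indoor)
  ser <- add_flock_context(ser, start_age = start_age, schedule = schedule,
                           flock_start = flock_start)
  ser <- interpolate_missing(ser)
  ser <- compute_td(ser)
  add_thi(ser)
}

#' Default pipeline configuration
#'
#' One nested list drives every stage; all randomness hangs off the single
#' top-level seed. Unknown keys in a user configuration are rejected.
#'
#' @param seed top-level integer seed.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  scenario <- unclass(scenario_config())
  scenario <- scenario[setdiff(names(scenario), "seed")]
  list(
    seed = as.integer(seed),
    scenario = scenario,
    preprocessing = list(indoor = "all", start_age = 15L),
    wavelet = list(basis = "db4", levels = 3L, window = 56L),
    model = list(variant = "wavelet_eca_gru", hidden_dim = 128L, L = 36L,
                 H = 6L, lr = 0.001, batch_size = 32L, max_epochs = 200L,
                 patience = 20L, val_fraction = 0.1, split_ratio = 0.8),
    warning = list(td_threshold = 2.5))
}

check_config_keys <- function(cfg, ref = default_pipeline_config(), path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste0(path, extra, collapse = ", "))
  for (k in names(cfg))
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])))
      check_config_keys(cfg[[k]], ref[[k]], paste0(path, k, "."))
  invisible(TRUE)
}

merge_config <- function(user, ref = default_pipeline_config()) {
  for (k in names(user)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && is.list(user[[k]]))
      ref[[k]] <- merge_config(user[[k]], ref[[k]])
    else ref[[k]] <- user[[k]]
  }
  ref
}

#' Load and validate a pipeline configuration
#'
#' @param config \code{NULL} (defaults), a nested list, or a path to a YAML
#'   file; partial configurations are merged over the defaults, unknown keys
#'   rejected.
#' @param seed optional seed override.
#' @return validated configuration list with a \code{hash} attribute.
#' @export
load_pipeline_config <- function(config = NULL, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("configuration file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  check_config_keys(config)
  cfg <- merge_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

# small polynomial rolling hash of the serialized configuration; enough to
# detect artifact/config mismatches, not cryptographic
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

read_stage <- function(path, what) {
  if (!file.exists(path))
    stop("missing upstream artifact '", path, "'; run the ", what,
         " stage first")
  path
}

#' Run the simulate / preprocess / train / evaluate / warn pipeline
#'
#' A staged driver over the package's functions: \code{simulate} writes the
#' synthetic raw streams, \code{preprocess} the aligned indexed series,
#' \code{train} the TD and THI model checkpoints, \code{evaluate} the
#' model-comparison table, \code{warn} the rolling warning log and the
#' distribution statistics. Every artifact lands in \code{out_dir} together
#' with the configuration hash that produced it.
#'
#' @param config see [load_pipeline_config()].
#' @param out_dir artifact directory.
#' @param stages subset of
#'   \code{c("simulate", "preprocess", "train", "evaluate", "warn")} in
#'   pipeline order, or \code{"all"}.
#' @param seed optional seed override.
#' @param variants variants for the \code{evaluate} stage (default: the
#'   configured model variant and the \code{gru} baseline).
#' @param quiet suppress progress messages.
#' @return invisibly, the list of artifact paths.
#' @export
run_pipeline <- function(config = NULL, out_dir = "pipeline-out",
                         stages = "all", seed = NULL, variants = NULL,
                         quiet = FALSE) {
  cfg <- load_pipeline_config(config, seed)
  all_stages <- c("simulate", "preprocess", "train", "evaluate", "warn")
  if (identical(stages, "all")) stages <- all_stages
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  paths <- list(raw = file.path(out_dir, "raw.csv"),
                series = file.path(out_dir, "series.csv"),
                td_model = file.path(out_dir, "model_td.rds"),
                thi_model = file.path(out_dir, "model_thi.rds"),
                metrics = file.path(out_dir, "metrics.csv"),
                warnings = file.path(out_dir, "warnings.csv"),
                stats = file.path(out_dir, "warning_stats.json"),
                meta = file.path(out_dir, "run_meta.json"))
  schedule <- default_age_schedule()

  if ("simulate" %in% stages) {
    say("simulate: ", cfg$scenario$duration_days, " days")
    sc <- do.call(scenario_config, c(cfg$scenario, list(seed = cfg$seed)))
    sim <- simulate_house(sc, schedule)
    write_simulation(sim, out_dir)
  }
  if ("preprocess" %in% stages) {
    read_stage(paths$raw, "simulate")
    say("preprocess: align, aggregate, index")
    rec <- read_records_csv(paths$raw)
    ser <- prepare_series(rec, start_age = cfg$preprocessing$start_age,
                          schedule = schedule,
                          indoor = cfg$preprocessing$indoor)
    write_series_csv(ser, paths$series)
  }
  if ("train" %in% stages) {
    read_stage(paths$series, "preprocess")
    ser <- read_series_csv(paths$series)
    wcfg <- do.call(wavelet_config, cfg$wavelet)
    for (tg in c("td", "thi")) {
      say("train: ", cfg$model$variant, " for ", toupper(tg))
      fit <- do.call(wecagru, c(list(series = ser, target = tg,
                                     variant = cfg$model$variant,
                                     wavelet = wcfg, seed = cfg$seed),
                                cfg$model[setdiff(names(cfg$model), "variant")]))
      fit$config_hash <- attr(cfg, "hash")
      write_model(fit, paths[[paste0(tg, "_model")]])
    }
  }
  if ("evaluate" %in% stages) {
    read_stage(paths$series, "preprocess")
    ser <- read_series_csv(paths$series)
    if (is.null(variants)) variants <- unique(c(cfg$model$variant, "gru"))
    say("evaluate: ", paste(variants, collapse = ", "))
    wcfg <- do.call(wavelet_config, cfg$wavelet)
    tbl <- do.call(compare_models,
                   c(list(series = ser, variants = variants,
                          seeds = cfg$seed, wavelet = wcfg),
                     cfg$model[setdiff(names(cfg$model), "variant")]))
    data.table::fwrite(tbl, paths$metrics)
  }
  if ("warn" %in% stages) {
    read_stage(paths$series, "preprocess")
    for (p in c(paths$td_model, paths$thi_model)) read_stage(p, "train")
    say("warn: rolling dual-indicator warnings")
    ser <- read_series_csv(paths$series)
    tdm <- read_model(paths$td_model)
    thim <- read_model(paths$thi_model)
    h <- attr(cfg, "hash")
    if (!is.null(tdm$config_hash) && !identical(tdm$config_hash, h))
      warning("model was trained under a different configuration hash")
    lg <- rolling_warn(tdm, thim, ser, threshold = cfg$warning$td_threshold)
    # restrict the report to the test span of the TD model
    test_times <- predict(tdm)$time
    lg <- lg[lg$time %in% test_times, , drop = FALSE]
    data.table::fwrite(lg, paths$warnings)
    rep <- warning_report(ser, lg, threshold = cfg$warning$td_threshold)
    jsonlite::write_json(
      list(td = unclass(rep$td), thi = unclass(rep$thi)), paths$stats,
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(list(hash = attr(cfg, "hash"), seed = cfg$seed,
                            stages = stages,
                            timestamp = format(Sys.time(), tz = "UTC")),
                       paths$meta, auto_unbox = TRUE)
  invisible(paths)
}
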