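# Seeded synthetic broiler-house sensor streams.
#
# The generator emulates the acquisition system the pipeline was designed
# for: an inspection robot sampling every 3 s along a cyclic 16-channel
# route, 12 fixed indoor points and one outdoor point. Indoor temperature
# follows a first-order relaxation toward the age-dependent target
# temperature with diurnal outdoor forcing and square-pulse equipment
# disturbances; relative humidity is negatively coupled to temperature; CO2
# follows ventilation-driven diurnal dynamics. Observation noise, missing
# CO2 records and out-of-range invalid values are injected at configured
# rates. Everything is deterministic under a fixed seed.

#' Scenario configuration for the synthetic house
#'
#' @param duration_days length of the simulated period, days (>= 1).
#' @param start_age broiler age (days) at the start of the simulation.
#' @param n_channels number of inspection channels in the robot route.
#' @param n_fixed_points number of fixed indoor monitoring points.
#' @param robot_speed inspection speed, m/s.
#' @param robot_sample_interval sampling interval of every terminal, seconds.
#' @param house_length channel length travelled per pass, m.
#' @param turn_time seconds lost turning between channels (brings one full
#'   16-channel cycle to roughly 96 min at 0.3 m/s).
#' @param missing_co2_rate fraction of indoor records whose CO2 cell is
#'   dropped (default 0.0226).
#' @param invalid_rate fraction of records carrying one injected
#'   out-of-sensor-range value (marked in the hidden \code{injected_invalid}
#'   column so the aggregation filter can be exercised).
#' @param disturbance_rate equipment start-stop events per day; each is a
#'   square pulse of 0.5-1.5 degC on the equilibrium temperature lasting
#'   10-30 min.
#' @param noise_sd_temp measurement noise sd of temperature sensors, degC.
#'   Latent process noise and spatial biases scale with it, so 0 gives a
#'   fully deterministic thermal path.
#' @param noise_sd_rh measurement noise sd of humidity sensors, percentage
#'   points.
#' @param tout_mean,tout_amplitude mean and diurnal amplitude of outdoor
#'   temperature, degC (amplitude 0 gives constant outdoor forcing).
#' @param tau_minutes thermal time constant of the house, minutes.
#' @param k_out coupling of indoor equilibrium to outdoor temperature
#'   anomaly.
#' @param jitter_sd sd of recording-timestamp jitter, seconds (truncated at
#'   +-1.4 s so records stay matchable to their 3-s grid point).
#' @param flock_start POSIXct start instant (UTC) of the simulation.
#' @param seed integer seed; identical configs give bit-identical streams.
#' @return object of class \code{scenario_config}.
#' @export
scenario_config <- function(duration_days = 7L, start_age = 15L,
                            n_channels = 16L, n_fixed_points = 12L,
                            robot_speed = 0.3, robot_sample_interval = 3,
                            house_length = 101, turn_time = 24,
                            missing_co2_rate = 0.0226, invalid_rate = 0.002,
                            disturbance_rate = 8, noise_sd_temp = 0.3,
                            noise_sd_rh = 2, tout_mean = 24,
                            tout_amplitude = 6, tau_minutes = 30,
                            k_out = 0.15, jitter_sd = 0.2,
                            flock_start = as.POSIXct("2025-06-01 00:00:00", tz = "UTC"),
                            seed = 1L) {
  cfg <- list(duration_days = as.integer(duration_days),
              start_age = as.integer(start_age),
              n_channels = as.integer(n_channels),
              n_fixed_points = as.integer(n_fixed_points),
              robot_speed = robot_speed,
              robot_sample_interval = robot_sample_interval,
              house_length = house_length, turn_time = turn_time,
              missing_co2_rate = missing_co2_rate,
              invalid_rate = invalid_rate,
              disturbance_rate = disturbance_rate,
              noise_sd_temp = noise_sd_temp, noise_sd_rh = noise_sd_rh,
              tout_mean = tout_mean, tout_amplitude = tout_amplitude,
              tau_minutes = tau_minutes, k_out = k_out,
              jitter_sd = jitter_sd, flock_start = as_utc(flock_start),
              seed = as.integer(seed))
  if (cfg$duration_days < 1L) stop("duration_days must be >= 1")
  if (cfg$start_age < 1L) stop("start_age must be >= 1")
  for (r in c("missing_co2_rate", "invalid_rate"))
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop(r, " must be in [0, 1]")
  if (cfg$disturbance_rate < 0) stop("disturbance_rate must be >= 0")
  if (cfg$noise_sd_temp < 0 || cfg$noise_sd_rh < 0) stop("noise sds must be >= 0")
  if (cfg$robot_speed <= 0 || cfg$robot_sample_interval <= 0)
    stop("robot speed and sample interval must be positive")
  structure(cfg, class = "scenario_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

ar1 <- function(n, phi, sd) {
  if (sd == 0 || n == 0L) return(numeric(n))
  as.numeric(stats::filter(stats::rnorm(n, 0, sd), phi, method = "recursive"))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# minute-resolution latent house dynamics
simulate_latent <- function(config, schedule) {
  nmin <- config$duration_days * 1440L
  minute <- seq_len(nmin) - 1L
  tod_h <- (minute %% 1440L) / 60
  age <- config$start_age + minute %/% 1440L
  ttarget <- target_temperature(schedule, age)

  s_temp <- config$noise_sd_temp
  tout <- config$tout_mean +
    config$tout_amplitude * sin(2 * pi * (tod_h - 9) / 24) +
    ar1(nmin, 0.99, s_temp / 6)

  # equipment start-stop square pulses on the equilibrium temperature
  pulse <- numeric(nmin)
  n_pulse <- stats::rpois(1L, config$disturbance_rate * config$duration_days)
  if (n_pulse > 0L) {
    p_start <- sort(stats::runif(n_pulse, 0, nmin))
    p_dur <- stats::runif(n_pulse, 10, 30)
    p_amp <- stats::runif(n_pulse, 0.5, 1.5) * sample(c(-1, 1), n_pulse, replace = TRUE)
    for (i in seq_len(n_pulse)) {
      idx <- which(minute >= p_start[i] & minute < p_start[i] + p_dur[i])
      pulse[idx] <- pulse[idx] + p_amp[i]
    }
  }

  teq <- ttarget + config$k_out * (tout - config$tout_mean) + pulse
  eps <- stats::rnorm(nmin, 0, s_temp / 15)
  tin <- numeric(nmin)
  tin[1L] <- ttarget[1L]
  a <- 1 / config$tau_minutes
  for (i in seq.int(2L, nmin))
    tin[i] <- tin[i - 1L] + a * (teq[i] - tin[i - 1L]) + eps[i]

  hb <- age_band(schedule, "humidity", age)
  rh_mid <- (hb$low + hb$high) / 2
  rhin <- clamp(rh_mid - 1.5 * (tin - ttarget) + ar1(nmin, 0.98, config$noise_sd_rh / 10),
                2, 99.5)
  rhout <- clamp(60 - 1.5 * (tout - config$tout_mean) +
                   ar1(nmin, 0.98, config$noise_sd_rh / 8), 2, 99.5)

  wb <- age_band(schedule, "wind", age)
  vin <- clamp(pmax((wb$low + wb$high) / 2, 0.12) + ar1(nmin, 0.95, 0.02), 0.1, 5)
  vout <- clamp(1.2 + 0.6 * sin(2 * pi * (tod_h - 12) / 24) + ar1(nmin, 0.98, 0.05),
                0.1, 4.9)

  # ventilation-driven CO2: higher at night and with bird age
  co2 <- clamp(700 + 8 * age + 350 * cos(2 * pi * tod_h / 24) + ar1(nmin, 0.99, 10),
               320, 4900)

  data.frame(minute = minute, age = age, ttarget = ttarget, tin = tin,
             rhin = rhin, vin = vin, co2 = co2, tout = tout, rhout = rhout,
             vout = vout)
}

#' Simulate multi-source environmental sensor streams
#'
#' Produces the raw record stream of the whole acquisition system (robot,
#' fixed indoor points, outdoor point) at the configured sampling interval,
#' plus the noise-free latent minute-scale dynamics that generated it.
#'
#' @param config a [scenario_config()].
#' @param schedule an [age_schedule()].
#' @return object of class \code{house_simulation}: a list with
#'   \code{records} (data.frame: \code{timestamp}, \code{source_id},
#'   \code{source_kind}, \code{channel}, \code{cage}, \code{temp_c},
#'   \code{rh_pct}, \code{wind_ms}, \code{co2_ppm},
#'   \code{injected_invalid}), \code{latent} (minute-scale truth),
#'   \code{config} and \code{schedule}.
#' @export
simulate_house <- function(config = scenario_config(),
                           schedule = default_age_schedule()) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$seed, {
    latent <- simulate_latent(config, schedule)
    iv <- config$robot_sample_interval
    ticks <- seq(0, config$duration_days * 86400 - iv, by = iv)
    mi <- pmin(ticks %/% 60, nrow(latent) - 1L) + 1L  # minute index per tick
    t0 <- as.numeric(config$flock_start)
    s_temp <- config$noise_sd_temp
    s_rh <- config$noise_sd_rh
    nt <- length(ticks)

    jitter <- function(n) {
      if (config$jitter_sd == 0) numeric(n)
      else clamp(stats::rnorm(n, 0, config$jitter_sd), -1.4, 1.4)
    }
    obs <- function(lat_col, sd, bias = 0)
      latent[[lat_col]][mi] + bias + (if (sd > 0) stats::rnorm(nt, 0, sd) else 0)

    # robot: cyclic channel route with per-channel spatial temperature offsets
    dwell <- config$house_length / config$robot_speed + config$turn_time
    cyc <- (ticks %% (config$n_channels * dwell)) / dwell
    channel <- pmin(floor(cyc) + 1L, config$n_channels)
    frac <- cyc - floor(cyc)
    cage <- pmin(floor(frac * 73) + 1L, 73L)
    ch_bias <- (s_temp / 2) * sin(2 * pi * (seq_len(config$n_channels) - 1) /
                                    config$n_channels)
    robot <- data.table::data.table(
      timestamp = t0 + ticks + jitter(nt),
      source_id = "robot-01", source_kind = "robot",
      channel = channel, cage = cage,
      temp_c = obs("tin", s_temp, ch_bias[channel]),
      rh_pct = clamp(obs("rhin", s_rh), 0, 100),
      wind_ms = clamp(obs("vin", 0.05), 0.1, 5),
      co2_ppm = clamp(obs("co2", 25), 300, 5000))

    # fixed indoor points: persistent per-point calibration-scale biases
    fx_tbias <- stats::rnorm(config$n_fixed_points, 0, s_temp / 2)
    fx_rhbias <- stats::rnorm(config$n_fixed_points, 0, s_rh / 4)
    fixed <- data.table::rbindlist(lapply(seq_len(config$n_fixed_points), function(p) {
      data.table::data.table(
        timestamp = t0 + ticks + jitter(nt),
        source_id = sprintf("fixed-%02d", p), source_kind = "fixed",
        channel = NA_integer_, cage = NA_integer_,
        temp_c = obs("tin", s_temp, fx_tbias[p]),
        rh_pct = clamp(obs("rhin", s_rh, fx_rhbias[p]), 0, 100),
        wind_ms = clamp(obs("vin", 0.05), 0.1, 5),
        co2_ppm = clamp(obs("co2", 25), 300, 5000))
    }))

    outdoor <- data.table::data.table(
      timestamp = t0 + ticks + jitter(nt),
      source_id = "outdoor-01", source_kind = "outdoor",
      channel = NA_integer_, cage = NA_integer_,
      temp_c = obs("tout", s_temp),
      rh_pct = clamp(obs("rhout", s_rh), 0, 100),
      wind_ms = clamp(obs("vout", 0.05), 0.1, 5),
      co2_ppm = NA_real_)

    rec <- data.table::rbindlist(list(robot, fixed, outdoor))
    data.table::setorderv(rec, c("timestamp", "source_id"))

    # missing CO2 cells on indoor sources
    if (config$missing_co2_rate > 0) {
      ind <- which(rec$source_kind != "outdoor")
      drop <- ind[stats::runif(length(ind)) < config$missing_co2_rate]
      if (length(drop)) data.table::set(rec, drop, "co2_ppm", NA_real_)
    }

    # out-of-range invalid values, flagged in the hidden truth column
    rec[, injected_invalid := FALSE]
    if (config$invalid_rate > 0) {
      hit <- which(stats::runif(nrow(rec)) < config$invalid_rate)
      if (length(hit)) {
        bad_value <- c(temp_c = 999, rh_pct = 150, wind_ms = 99, co2_ppm = 99999)
        pick <- sample(names(bad_value), length(hit), replace = TRUE)
        # never corrupt a cell that is absent for that source
        pick[pick == "co2_ppm" & is.na(rec$co2_ppm[hit])] <- "temp_c"
        for (v in unique(pick)) {
          rows <- hit[pick == v]
          data.table::set(rec, rows, v, bad_value[[v]])
        }
        data.table::set(rec, hit, "injected_invalid", TRUE)
      }
    }

    rec[, timestamp := as_utc(timestamp)]
    structure(list(records = as.data.frame(rec), latent = latent,
                   config = config, schedule = schedule),
              class = "house_simulation")
  })
}

#' Noise-free latent 5-minute series of a simulation
#'
#' Aggregates the latent minute-scale dynamics onto the same 5-min grid the
#' observed records are aggregated to, for parameter-recovery and
#' ground-truth tests. TD is the latent indoor temperature minus the target
#' temperature at the age of the window start; THI is computed from the
#' latent 5-min means.
#'
#' @param sim a \code{house_simulation}.
#' @return an [aligned_series] with Tin, RHin, Vin, CO2, Tout, RHout, Vout,
#'   Age, Ttarget, TD, THI.
#' @export
ground_truth_series <- function(sim) {
  stopifnot(inherits(sim, "house_simulation"))
  lat <- sim$latent
  w <- lat$minute %/% 5L
  agg <- function(v) as.numeric(tapply(v, w, mean))
  first <- function(v) as.numeric(tapply(v, w, function(z) z[1L]))
  ws <- sort(unique(w))
  df <- data.frame(Tin = agg(lat$tin), RHin = agg(lat$rhin), Vin = agg(lat$vin),
                   CO2 = agg(lat$co2), Tout = agg(lat$tout),
                   RHout = agg(lat$rhout), Vout = agg(lat$vout),
                   Age = first(lat$age), Ttarget = first(lat$ttarget))
  df$TD <- df$Tin - df$Ttarget
  df$THI <- compute_thi(df$Tin, df$RHin)
  aligned_series(as.numeric(sim$config$flock_start) + ws * 300, df, step = 300)
}

#' Write a simulation to CSV with a metadata sidecar
#'
#' \code{raw.csv} carries the public record schema (ISO-8601 UTC timestamps,
#' empty cell = missing); \code{truth.csv} the latent 5-min series including
#' the indicators; \code{metadata.json} the seed and scenario configuration.
#' The hidden \code{injected_invalid} column goes to \code{invalid_truth.csv}
#' so filter tests have labels without leaking them into the raw schema.
#'
#' @param sim a \code{house_simulation}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "house_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  raw <- data.table::as.data.table(sim$records)
  raw[, timestamp := format(timestamp, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")]
  paths <- c(raw = file.path(dir, "raw.csv"),
             truth = file.path(dir, "truth.csv"),
             invalid = file.path(dir, "invalid_truth.csv"),
             meta = file.path(dir, "metadata.json"))
  data.table::fwrite(raw[, !"injected_invalid"], paths["raw"])
  write_series_csv(ground_truth_series(sim), paths["truth"])
  data.table::fwrite(raw[injected_invalid == TRUE,
                         .(timestamp, source_id)], paths["invalid"])
  cfg <- sim$config
  cfg$flock_start <- format(cfg$flock_start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  jsonlite::write_json(unclass(cfg), paths["meta"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read/write an aligned series as CSV
#'
#' @param series an [aligned_series].
#' @param path CSV path; timestamps are ISO-8601 UTC.
#' @export
write_series_csv <- function(series, path) {
  df <- as.data.frame(series)
  df$time <- format(df$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  data.table::fwrite(df, path)
  invisible(path)
}

#' @param step grid spacing of the stored series, seconds.
#' @rdname write_series_csv
#' @export
read_series_csv <- function(path, step = 300) {
  df <- as.data.frame(data.table::fread(path))
  df$time <- as.POSIXct(df$time, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  aligned_series(df$time, df[setdiff(names(df), "time")], step = step)
}

#' Read raw records from CSV
#'
#' @param path CSV in the raw record schema written by [write_simulation()].
#' @return data.frame of records with POSIXct timestamps.
#' @export
read_records_csv <- function(path) {
  dt <- data.table::fread(path, na.strings = c("", "NA"))
  dt[, timestamp := as.POSIXct(timestamp, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")]
  as.data.frame(dt)
}

#' @export
print.house_simulation <- function(x, ...) {
  cat(sprintf("Synthetic house simulation: %d days from age %d, seed %d\n",
              x$config$duration_days, x$config$start_age, x$config$seed))
  cat(sprintf("  %d records from %d sources at %gs interval\n",
              nrow(x$records), length(unique(x$records$source_id)),
              x$config$robot_sample_interval))
  invisible(x)
}
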