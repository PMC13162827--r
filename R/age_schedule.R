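#' Age-dependent suitable environmental ranges for broilers
#'
#' An age schedule maps broiler age (days) to the suitable band of each
#' environmental variable and to the target temperature used for the
#' temperature-deviation (TD) indicator. Bands are stored per variable as
#' age intervals; the last interval of each variable is open-ended so the
#' schedule covers every age >= 1.
#'
#' @param temperature,humidity,wind data.frames with columns
#'   \code{from}, \code{to}, \code{low}, \code{high} (ages in days; \code{to}
#'   may be \code{Inf}).
#' @param co2_max single upper CO2 limit in ppm (only an upper threshold is
#'   defined for CO2).
#' @param t_target optional data.frame with columns \code{from}, \code{to},
#'   \code{target} overriding the default target temperature (the midpoint of
#'   the suitable temperature band at that age).
#' @return An object of class \code{age_schedule}.
#' @seealso [default_age_schedule()], [target_temperature()], [age_band()]
#' @export
age_schedule <- function(temperature, humidity, wind, co2_max = 1500,
                         t_target = NULL) {
  check_bands <- function(df, nm) {
    stopifnot(is.data.frame(df), all(c("from", "to", "low", "high") %in% names(df)))
    if (any(df$low > df$high))
      stop("age schedule: low > high in ", nm, " band")
    if (df$from[1] > 1) stop("age schedule: ", nm, " bands must start at age 1")
    if (is.finite(df$to[nrow(df)]))
      stop("age schedule: last ", nm, " band must be open-ended")
    if (nrow(df) > 1 && any(df$from[-1] != df$to[-nrow(df)] + 1))
      stop("age schedule: ", nm, " bands must be contiguous")
    df
  }
  temperature <- check_bands(temperature, "temperature")
  humidity <- check_bands(humidity, "humidity")
  wind <- check_bands(wind, "wind")
  stopifnot(is.numeric(co2_max), length(co2_max) == 1L, co2_max > 0)
  if (is.null(t_target)) {
    t_target <- data.frame(from = temperature$from, to = temperature$to,
                           target = (temperature$low + temperature$high) / 2)
  }
  # target must stay inside the suitable temperature band of its age
  for (i in seq_len(nrow(t_target))) {
    ages <- c(t_target$from[i], min(t_target$to[i], 200))
    bl <- band_lookup(temperature, ages)
    if (any(t_target$target[i] < bl$low | t_target$target[i] > bl$high))
      stop("age schedule: target temperature outside the suitable band")
  }
  structure(list(temperature = temperature, humidity = humidity, wind = wind,
                 co2_max = co2_max, t_target = t_target),
            class = "age_schedule")
}

band_lookup <- function(df, age) {
  i <- findInterval(age, df$from)
  if (any(i < 1L)) stop("age ", min(age), " not covered by schedule (age >= 1 required)")
  df[i, , drop = FALSE]
}

#' Default broiler age schedule
#'
#' The standard suitable ranges for cage-reared broilers: temperature bands
#' from 34-35 degC in days 1-3 down to 22-23 degC from day 40 on; relative
#' humidity from 65-70\% down to 50-55\%; air velocity from 0-0.20 m/s up to
#' 1.5-2.5 m/s; CO2 capped at 1500 ppm at all ages. The target temperature
#' defaults to the midpoint of the suitable temperature band.
#'
#' @return An \code{age_schedule} object.
#' @examples
#' sch <- default_age_schedule()
#' target_temperature(sch, 20)   # 28.5
#' age_band(sch, "temperature", 20)
#' @export
default_age_schedule <- function() {
  age_schedule(
    temperature = data.frame(
      from = c(1, 4, 8, 16, 24, 32, 40),
      to   = c(3, 7, 15, 23, 31, 39, Inf),
      low  = c(34, 32, 30, 28, 26, 24, 22),
      high = c(35, 33, 31, 29, 27, 25, 23)),
    humidity = data.frame(
      from = c(1, 11, 31, 46),
      to   = c(10, 30, 45, Inf),
      low  = c(65, 60, 55, 50),
      high = c(70, 65, 60, 55)),
    wind = data.frame(
      from = c(1, 15, 22, 29),
      to   = c(14, 21, 28, Inf),
      low  = c(0, 0, 0, 1.5),
      high = c(0.20, 0.51, 1.02, 2.5)),
    co2_max = 1500)
}

#' Suitable band of a variable at a given age
#'
#' @param schedule an \code{age_schedule}.
#' @param variable one of \code{"temperature"}, \code{"humidity"},
#'   \code{"wind"}, \code{"co2"}.
#' @param age broiler age in days (vectorized).
#' @return data.frame with columns \code{low} and \code{high} (for CO2,
#'   \code{low} is 0 and \code{high} the upper limit).
#' @export
age_band <- function(schedule, variable = c("temperature", "humidity", "wind", "co2"),
                     age) {
  stopifnot(inherits(schedule, "age_schedule"))
  variable <- match.arg(variable)
  if (variable == "co2")
    return(data.frame(low = rep(0, length(age)),
                      high = rep(schedule$co2_max, length(age))))
  b <- band_lookup(schedule[[variable]], age)
  data.frame(low = b$low, high = b$high)
}

#' Target temperature at a given age
#'
#' @inheritParams age_band
#' @return numeric vector of target temperatures (degC).
#' @export
target_temperature <- function(schedule, age) {
  stopifnot(inherits(schedule, "age_schedule"))
  band_lookup(schedule$t_target, age)$target
}

#' @export
print.age_schedule <- function(x, ...) {
  cat("Broiler age schedule\n")
  cat("  temperature bands:", nrow(x$temperature),
      sprintf("(%g-%g degC at age 1, %g-%g degC open-ended)",
              x$temperature$low[1], x$temperature$high[1],
              x$temperature$low[nrow(x$temperature)],
              x$temperature$high[nrow(x$temperature)]), "\n")
  cat("  humidity bands:   ", nrow(x$humidity), "\n")
  cat("  wind bands:       ", nrow(x$wind), "\n")
  cat("  CO2 upper limit:  ", x$co2_max, "ppm\n")
  invisible(x)
}
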