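# From raw multi-source sensor records to aligned, aggregated, gap-filled,
# indexed and normalized 5-minute series and supervised learning windows.

#' Sensor measurement ranges
#'
#' The measurement range of each sensor; values outside these ranges are
#' invalid and excluded before aggregation.
#'
#' @return data.frame with columns \code{variable}, \code{low}, \code{high}
#'   for temperature (degC), relative humidity (\%), wind speed (m/s) and
#'   CO2 (ppm).
#' @export
sensor_ranges <- function() {
  data.frame(variable = c("temp_c", "rh_pct", "wind_ms", "co2_ppm"),
             low = c(-20, 0, 0.1, 300),
             high = c(50, 100, 5, 5000))
}

.record_vars <- c("temp_c", "rh_pct", "wind_ms", "co2_ppm")

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = "UTC"))
  as.POSIXct(x, tz = "UTC")
}

#' Align raw records from all sources onto a common 3-second grid
#'
#' Every source is mapped onto a shared grid of \code{step}-second instants.
#' For each grid point the record of that source with the minimal absolute
#' time offset is used; a grid cell with no record within \code{step/2}
#' seconds stays missing (no row). Ties are deterministic: among equidistant
#' records the earlier one wins, and a record exactly halfway between two
#' grid points goes to the earlier point. Exact duplicate records collapse to
#' one; records sharing (source_id, timestamp) but disagreeing on values are
#' resolved last-write-wins.
#'
#' @param records data.frame of raw records with columns \code{timestamp}
#'   (POSIXct), \code{source_id}, \code{source_kind} (robot/fixed/outdoor),
#'   optional \code{channel}, \code{cage}, and the measurements
#'   \code{temp_c}, \code{rh_pct}, \code{wind_ms}, \code{co2_ppm} (NA =
#'   missing).
#' @param step grid spacing in seconds (default 3).
#' @return data.table with one row per occupied (grid time, source) cell:
#'   \code{time}, \code{source_id}, \code{source_kind}, measurements.
#' @export
align_sources <- function(records, step = 3) {
  cols <- c("time", "source_id", "source_kind", .record_vars)
  if (is.null(records) || nrow(records) == 0L) {
    empty <- data.table::data.table(time = as_utc(numeric(0)), source_id = character(0),
                                    source_kind = character(0))
    for (v in .record_vars) empty[[v]] <- numeric(0)
    return(empty[])
  }
  stopifnot(all(c("timestamp", "source_id", "source_kind") %in% names(records)))
  dt <- data.table::as.data.table(records)
  ts <- as.numeric(as_utc(dt$timestamp))
  if (!all(is.finite(ts))) stop("non-finite timestamps in records")
  dt[, `:=`(.ts = ts)]
  for (v in .record_vars) if (is.null(dt[[v]])) dt[[v]] <- NA_real_
  # collapse exact duplicates, then last-write-wins per (source_id, timestamp)
  dt <- unique(dt, by = c("source_id", ".ts", .record_vars))
  dt <- dt[!duplicated(dt, by = c("source_id", ".ts"), fromLast = TRUE)]
  t0 <- floor(min(dt$.ts) / step) * step
  # nearest grid point; exact halfway goes to the earlier point
  rel <- (dt$.ts - t0) / step
  g <- floor(rel + 0.5)
  half <- abs(rel - floor(rel) - 0.5) < 1e-9
  g[half] <- floor(rel[half])
  dt[, `:=`(.grid = t0 + g * step)]
  dt[, `:=`(.off = abs(.ts - .grid))]
  dt <- dt[.off <= step / 2 + 1e-9]
  # per (source, grid point): minimal offset, earlier record wins ties
  data.table::setorderv(dt, c("source_id", ".grid", ".off", ".ts"))
  dt <- dt[!duplicated(dt, by = c("source_id", ".grid"))]
  out <- dt[, c("source_id", ".grid", "source_kind", .record_vars), with = FALSE]
  data.table::setnames(out, ".grid", "time")
  out[, time := as_utc(time)]
  data.table::setorderv(out, c("time", "source_id"))
  out[]
}

#' Aggregate a 3-second multi-source series into 5-minute means
#'
#' Each half-open window [t, t + window) is summarized by the arithmetic mean
#' of the valid in-range values of each variable; the window start labels the
#' window. Values outside the sensor measurement range are excluded; a window
#' with zero valid values yields a missing cell. Indoor variables (Tin, RHin,
#' Vin, CO2) average over all indoor sources (robot and fixed points, or
#' robot only); outdoor variables (Tout, RHout, Vout) come from the outdoor
#' source.
#'
#' When given an already aggregated [aligned_series] the operation is
#' idempotent: each window contains exactly one row and the series is
#' returned unchanged.
#'
#' @param x output of [align_sources()] (or an \code{aligned_series}).
#' @param ranges sensor validity ranges, see [sensor_ranges()].
#' @param window aggregation window in seconds (default 300).
#' @param indoor which sources define the house-level indoor value:
#'   \code{"all"} (robot + fixed, the default) or \code{"robot"}.
#' @return an [aligned_series] with columns \code{time}, \code{Tin},
#'   \code{RHin}, \code{Vin}, \code{CO2}, \code{Tout}, \code{RHout},
#'   \code{Vout}.
#' @export
aggregate_5min <- function(x, ranges = sensor_ranges(), window = 300,
                           indoor = c("all", "robot")) {
  indoor <- match.arg(indoor)
  if (inherits(x, "aligned_series")) {
    df <- as.data.frame(x)
    ts <- as.numeric(as_utc(df$time))
    w <- floor(ts / window) * window
    vars <- setdiff(names(df), "time")
    agg <- stats::aggregate(df[vars], by = list(.w = w),
                            FUN = function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    return(aligned_series(as_utc(agg$.w), agg[vars], step = window))
  }
  dt <- data.table::as.data.table(x)
  stopifnot(all(c("time", "source_kind") %in% names(dt)))
  if (nrow(dt) == 0L) stop("no records to aggregate")
  ts <- as.numeric(as_utc(dt$time))
  dt[, `:=`(.w = floor(ts / window) * window)]
  # invalidate out-of-range values
  for (i in seq_len(nrow(ranges))) {
    v <- ranges$variable[i]
    bad <- !is.na(dt[[v]]) & (dt[[v]] < ranges$low[i] | dt[[v]] > ranges$high[i])
    if (any(bad)) data.table::set(dt, which(bad), v, NA_real_)
  }
  kinds_in <- if (indoor == "all") c("robot", "fixed") else "robot"
  mean_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  din <- dt[source_kind %in% kinds_in,
            .(Tin = mean_na(temp_c), RHin = mean_na(rh_pct),
              Vin = mean_na(wind_ms), CO2 = mean_na(co2_ppm)), by = .w]
  dout <- dt[source_kind == "outdoor",
             .(Tout = mean_na(temp_c), RHout = mean_na(rh_pct),
               Vout = mean_na(wind_ms)), by = .w]
  grid <- data.table::data.table(.w = seq(min(dt$.w), max(dt$.w), by = window))
  out <- merge(merge(grid, din, by = ".w", all.x = TRUE), dout,
               by = ".w", all.x = TRUE)
  data.table::setorderv(out, ".w")
  aligned_series(as_utc(out$.w), as.data.frame(out)[setdiff(names(out), ".w")],
                 step = window)
}

#' Equally spaced multivariate environmental series
#'
#' A data.frame with a strictly increasing \code{time} column at a fixed
#' spacing (attribute \code{step}, seconds) plus named variable columns;
#' \code{NA} marks missing cells.
#'
#' @param time POSIXct vector.
#' @param variables data.frame or named list of numeric columns.
#' @param step grid spacing in seconds.
#' @return object of classes \code{aligned_series} and \code{data.frame}.
#' @export
aligned_series <- function(time, variables, step = 300) {
  time <- as_utc(time)
  if (length(time) > 1L) {
    d <- diff(as.numeric(time))
    if (any(abs(d - step) > 1e-6))
      stop("time grid is not equally spaced at ", step, " s")
  }
  df <- data.frame(time = time, as.data.frame(variables, optional = TRUE))
  structure(df, step = step, class = c("aligned_series", "data.frame"))
}

series_step <- function(series) {
  s <- attr(series, "step")
  if (is.null(s)) 300 else s
}

# rebuild the class/attributes after data.frame surgery
as_aligned <- function(df, step) {
  structure(as.data.frame(df), step = step,
            class = c("aligned_series", "data.frame"))
}

#' Fill missing cells by linear interpolation in time
#'
#' Interior gaps are filled linearly; leading/trailing gaps take the nearest
#' valid value (linear interpolation is undefined there). The output has no
#' missing cells.
#'
#' @param series an [aligned_series].
#' @return the series with every \code{NA} replaced.
#' @export
interpolate_missing <- function(series) {
  stopifnot(inherits(series, "aligned_series"))
  ts <- as.numeric(series$time)
  for (v in setdiff(names(series), "time")) {
    col <- series[[v]]
    if (!anyNA(col)) next
    ok <- !is.na(col)
    if (!any(ok)) stop("variable '", v, "' has no valid values to interpolate from")
    if (sum(ok) == 1L) {
      series[[v]] <- rep(col[ok], length(col))
    } else {
      series[[v]] <- stats::approx(ts[ok], col[ok], xout = ts, method = "linear",
                                   rule = 2)$y
    }
  }
  series
}

#' Attach broiler age and target temperature to a series
#'
#' Age at time t is computed from the flock start instant; fractional days
#' are floored. \code{Ttarget} is the schedule's target temperature at that
#' age.
#'
#' @param series an [aligned_series].
#' @param start_age broiler age (days) on the flock start date.
#' @param schedule an [age_schedule()].
#' @param flock_start POSIXct instant the flock was at \code{start_age}
#'   (default: the first grid time of the series).
#' @return the series with \code{Age} and \code{Ttarget} columns added.
#' @export
add_flock_context <- function(series, start_age = 1L,
                              schedule = default_age_schedule(),
                              flock_start = NULL) {
  stopifnot(inherits(series, "aligned_series"))
  if (is.null(flock_start)) flock_start <- series$time[1L]
  elapsed <- as.numeric(series$time) - as.numeric(as_utc(flock_start))
  age <- start_age + floor(elapsed / 86400)
  series$Age <- age
  series$Ttarget <- target_temperature(schedule, age)
  series
}

#' Temperature deviation from the age-dependent target
#'
#' Adds \code{TD = Tin - Ttarget} to the series. Requires \code{Tin} and
#' \code{Age}/\code{Ttarget} (see [add_flock_context()]).
#'
#' @param series an [aligned_series] with \code{Tin}, \code{Age} and
#'   \code{Ttarget}.
#' @param schedule optional [age_schedule()] used to (re)compute
#'   \code{Ttarget} from \code{Age} when the column is absent.
#' @return the series with a \code{TD} column.
#' @export
compute_td <- function(series, schedule = NULL) {
  stopifnot(inherits(series, "aligned_series"))
  if (is.null(series$Tin)) stop("series has no Tin column")
  if (is.null(series$Ttarget)) {
    if (is.null(series$Age) || is.null(schedule))
      stop("series needs Age and a schedule to derive Ttarget")
    series$Ttarget <- target_temperature(schedule, series$Age)
  }
  series$TD <- series$Tin - series$Ttarget
  series
}

#' Temperature-humidity index
#'
#' \deqn{THI = (1.8 T + 32) - (0.55 - 0.0055 RH)(1.8 T - 26)}
#' with dry-bulb temperature T in degC and relative humidity RH in percent.
#' THI is strictly increasing in T at any RH, and increasing in RH iff
#' T > 26/1.8 degC.
#'
#' @param temp_c dry-bulb temperature, degC (vectorized).
#' @param rh_pct relative humidity in [0, 100] (vectorized).
#' @return dimensionless THI values.
#' @examples
#' compute_thi(25, 60)   # 72.82
#' @export
compute_thi <- function(temp_c, rh_pct) {
  if (any(!is.na(rh_pct) & (rh_pct < 0 | rh_pct > 100)))
    stop("relative humidity outside [0, 100]")
  (1.8 * temp_c + 32) - (0.55 - 0.0055 * rh_pct) * (1.8 * temp_c - 26)
}

#' @param series an [aligned_series] with \code{Tin} and \code{RHin}.
#' @rdname compute_thi
#' @export
add_thi <- function(series) {
  stopifnot(inherits(series, "aligned_series"))
  if (is.null(series$Tin) || is.null(series$RHin))
    stop("series needs Tin and RHin for THI")
  series$THI <- compute_thi(series$Tin, series$RHin)
  series
}

#' Chronological train/test split
#'
#' The first \code{floor(ratio * n)} rows form the training span, the
#' remainder the test span; no shuffling.
#'
#' @param series an [aligned_series] (or any data.frame).
#' @param ratio training fraction in (0, 1), default 0.8.
#' @return list with elements \code{train}, \code{test} and \code{n_train}.
#' @export
chronological_split <- function(series, ratio = 0.8) {
  n <- nrow(series)
  if (n < 2L) stop("need at least 2 rows to split")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be strictly inside (0, 1)")
  n_train <- floor(ratio * n)
  if (n_train < 1L || n_train >= n) stop("split leaves an empty partition")
  step <- series_step(series)
  list(train = as_aligned(series[seq_len(n_train), , drop = FALSE], step),
       test = as_aligned(series[seq.int(n_train + 1L, n), , drop = FALSE], step),
       n_train = n_train)
}

#' Min-max normalizer fitted on training rows only
#'
#' \code{fit_normalizer} records per-variable \code{min}/\code{max} from the
#' training rows; \code{normalize} maps \code{x} to \code{(x - min)/(max -
#' min)} (training rows land in [0, 1]; test values outside the training
#' range are NOT clipped, so extremes the warning engine must detect survive
#' normalization); \code{denormalize} inverts the affine map.
#'
#' @param train training-span [aligned_series] (or data.frame).
#' @param variables character vector of columns to fit (default: all numeric
#'   columns except \code{time}).
#' @param constant what to do with a constant column, for which min-max
#'   scaling is undefined: \code{"error"} (the default contract, naming the
#'   variable) or \code{"zero"} (store the degenerate range \code{[x, x+1]}
#'   so the channel maps to 0; used for input channels such as \code{Age}
#'   that may legitimately be constant over a short training span).
#' @return object of class \code{minmax_normalizer}.
#' @export
fit_normalizer <- function(train, variables = NULL,
                           constant = c("error", "zero")) {
  constant <- match.arg(constant)
  df <- as.data.frame(train)
  if (is.null(variables))
    variables <- setdiff(names(df)[vapply(df, is.numeric, logical(1))], "time")
  missing_v <- setdiff(variables, names(df))
  if (length(missing_v)) stop("variables not in data: ", paste(missing_v, collapse = ", "))
  stats <- lapply(variables, function(v) {
    x <- df[[v]]
    if (all(is.na(x))) stop("variable '", v, "' is all-missing")
    r <- range(x, na.rm = TRUE)
    if (r[1] == r[2]) {
      if (constant == "error")
        stop("variable '", v, "' is constant on the training set; min-max scaling undefined")
      r[2] <- r[1] + 1
    }
    c(min = r[1], max = r[2])
  })
  names(stats) <- variables
  structure(stats, class = "minmax_normalizer")
}

#' @param normalizer a fitted \code{minmax_normalizer}.
#' @param x data.frame/aligned series (all fitted columns transformed) or a
#'   numeric vector (requires \code{variable}).
#' @param variable variable name when \code{x} is a numeric vector.
#' @rdname fit_normalizer
#' @export
normalize <- function(normalizer, x, variable = NULL) {
  stopifnot(inherits(normalizer, "minmax_normalizer"))
  if (is.numeric(x)) {
    s <- normalizer[[variable]]
    if (is.null(s)) stop("no normalizer stats for '", variable, "'")
    return((x - s[["min"]]) / (s[["max"]] - s[["min"]]))
  }
  for (v in intersect(names(normalizer), names(x)))
    x[[v]] <- (x[[v]] - normalizer[[v]]["min"]) /
      (normalizer[[v]]["max"] - normalizer[[v]]["min"])
  x
}

#' @rdname fit_normalizer
#' @export
denormalize <- function(normalizer, x, variable = NULL) {
  stopifnot(inherits(normalizer, "minmax_normalizer"))
  if (is.numeric(x)) {
    s <- normalizer[[variable]]
    if (is.null(s)) stop("no normalizer stats for '", variable, "'")
    return(x * (s[["max"]] - s[["min"]]) + s[["min"]])
  }
  for (v in intersect(names(normalizer), names(x)))
    x[[v]] <- x[[v]] * (normalizer[[v]]["max"] - normalizer[[v]]["min"]) +
      normalizer[[v]]["min"]
  x
}

#' Persist / restore a normalizer as JSON
#'
#' @param normalizer a \code{minmax_normalizer}.
#' @param path file path.
#' @rdname fit_normalizer
#' @export
write_normalizer <- function(normalizer, path) {
  jsonlite::write_json(lapply(normalizer, as.list), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname fit_normalizer
#' @export
read_normalizer <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(lapply(raw, function(s) c(min = s$min, max = s$max)),
            class = "minmax_normalizer")
}

#' Pearson correlation coefficient
#'
#' Sample Pearson correlation; errors on constant input where the
#' correlation is undefined.
#'
#' @param x,y numeric vectors of equal length, n >= 2.
#' @return correlation in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("need at least 2 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant series")
  stats::cor(x, y)
}

#' Qualitative correlation strength classes
#'
#' |r| < 0.30 negligible; [0.30, 0.50) low; [0.50, 0.70) moderate;
#' [0.70, 0.90) high; >= 0.90 very high.
#'
#' @param r Pearson correlation(s) in [-1, 1].
#' @return character vector of classes.
#' @export
classify_correlation <- function(r) {
  if (any(abs(r) > 1 + 1e-12)) stop("|r| > 1")
  cut(abs(r), breaks = c(-Inf, 0.30, 0.50, 0.70, 0.90, Inf), right = FALSE,
      labels = c("negligible", "low", "moderate", "high", "very_high")) |>
    as.character()
}

#' Input feature sets for the TD and THI forecasters
#'
#' The default sets are the correlation-screened inputs: for TD the
#' variables Age, TD, Tout, CO2 and Ttarget; for THI the variables Age, THI,
#' Tin and Ttarget. In \code{mode = "screen"} the set is recomputed on a
#' training series: the target itself plus every candidate whose |r| with
#' the target is at least \code{threshold}, ordered by decreasing |r|.
#'
#' @param target \code{"td"} or \code{"thi"}.
#' @param train training-span [aligned_series] (screen mode only).
#' @param mode \code{"default"} or \code{"screen"}.
#' @param threshold minimum |r| for inclusion in screen mode (default 0.50,
#'   the moderate-correlation cutoff).
#' @return ordered character vector of variable names.
#' @export
select_features <- function(target = c("td", "thi"), train = NULL,
                            mode = c("default", "screen"), threshold = 0.50) {
  target <- match.arg(target)
  mode <- match.arg(mode)
  tvar <- if (target == "td") "TD" else "THI"
  if (mode == "default") {
    return(if (target == "td") c("Age", "TD", "Tout", "CO2", "Ttarget")
           else c("Age", "THI", "Tin", "Ttarget"))
  }
  stopifnot(!is.null(train))
  df <- as.data.frame(train)
  cand <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                  c("time", tvar))
  r <- vapply(cand, function(v) {
    if (stats::sd(df[[v]], na.rm = TRUE) == 0) return(0)
    pearson_r(df[[v]], df[[tvar]])
  }, numeric(1))
  keep <- cand[abs(r) >= threshold]
  c(tvar, keep[order(-abs(r[keep]))])
}

#' Sliding supervised windows over a normalized series
#'
#' Sample i (1-based, offset s = (i-1) stride) has input rows
#' (s+1) .. (s+L) and target row s+L+H; its anchor is row s+L, and the input
#' uses only observations at times <= the anchor.
#'
#' @param x numeric matrix (n rows, C channels) in normalized space.
#' @param y numeric target vector of length n (normalized).
#' @param L input window length in time steps (default 36).
#' @param H forecast horizon in time steps (default 6).
#' @param stride window step (default 1).
#' @return list with \code{X} (array N x L x C), \code{y} (length N),
#'   \code{anchor} (anchor row per sample) and \code{target_row}
#'   (= anchor + H). N = floor((n - L - H)/stride) + 1, or 0 (with a
#'   warning) when n < L + H.
#' @export
make_windows <- function(x, y, L = 36L, H = 6L, stride = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(y) == n, L >= 1L, H >= 1L, stride >= 1L)
  if (n < L + H) {
    warning("series length ", n, " < L + H = ", L + H, "; no samples")
    return(list(X = array(numeric(0), dim = c(0L, L, ncol(x))),
                y = numeric(0), anchor = integer(0), target_row = integer(0)))
  }
  offsets <- seq.int(0L, n - L - H, by = stride)
  N <- length(offsets)
  X <- array(NA_real_, dim = c(N, L, ncol(x)),
             dimnames = list(NULL, NULL, colnames(x)))
  for (i in seq_len(N))
    X[i, , ] <- x[offsets[i] + seq_len(L), , drop = FALSE]
  list(X = X, y = y[offsets + L + H], anchor = offsets + L,
       target_row = offsets + L + H)
}

#' Missing-value summary of a series
#'
#' Counts missing cells per variable and their share of the rows, the
#' bookkeeping reported after aggregation and before interpolation.
#'
#' @param series an [aligned_series] (or data.frame).
#' @return data.frame with columns \code{variable}, \code{n}, \code{missing},
#'   \code{missing_pct} (percent of rows, 2 d.p.).
#' @export
missing_summary <- function(series) {
  df <- as.data.frame(series)
  vars <- setdiff(names(df), "time")
  data.frame(variable = vars,
             n = nrow(df),
             missing = vapply(df[vars], function(v) sum(is.na(v)), integer(1)),
             missing_pct = round(vapply(df[vars], function(v) 100 * mean(is.na(v)),
                                        numeric(1)), 2),
             row.names = NULL)
}

#' @export
print.aligned_series <- function(x, ...) {
  cat(sprintf("Aligned series: %d steps of %gs, %s to %s\n", nrow(x),
              series_step(x), format(x$time[1]), format(x$time[nrow(x)])))
  cat("  variables:", paste(setdiff(names(x), "time"), collapse = ", "), "\n")
  miss <- sum(is.na(as.matrix(x[setdiff(names(x), "time")])))
  if (miss > 0) cat("  missing cells:", miss, "\n")
  invisible(x)
}
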