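# Real-time environmental state identification and the rolling
# dual-indicator TD/THI early-warning strategy.

#' Age-dependent environmental state of a monitored value
#'
#' Classifies a monitored value against the suitable band for the broiler
#' age: \code{Low} below the lower limit, \code{High} above the upper limit,
#' \code{Normal} inside (boundaries inclusive). CO2 has only an upper limit;
#' its states are \code{Normal} / \code{OverLimit}.
#'
#' @param value monitored value(s).
#' @param variable \code{"temperature"}, \code{"humidity"}, \code{"wind"} or
#'   \code{"co2"}.
#' @param age broiler age in days (scalar or same length as \code{value}).
#' @param schedule an [age_schedule()].
#' @return character vector of state labels.
#' @examples
#' sch <- default_age_schedule()
#' classify_env_state(28.5, "temperature", 20, sch)  # Normal
#' classify_env_state(1600, "co2", 20, sch)          # OverLimit
#' @export
classify_env_state <- function(value, variable, age,
                               schedule = default_age_schedule()) {
  variable <- match.arg(variable, c("temperature", "humidity", "wind", "co2"))
  if (length(age) == 1L) age <- rep(age, length(value))
  stopifnot(length(age) == length(value))
  b <- age_band(schedule, variable, age)
  if (variable == "co2")
    return(ifelse(value > b$high, "OverLimit", "Normal"))
  ifelse(value < b$low, "Low", ifelse(value > b$high, "High", "Normal"))
}

#' THI thermal-risk level
#'
#' Bands: THI < 70 Comfort; 70 <= THI < 76 Warning; 76 <= THI < 81 Danger;
#' THI >= 81 Emergency (lower bounds inclusive).
#'
#' @param thi numeric THI value(s).
#' @return character vector of levels.
#' @export
thi_risk_level <- function(thi) {
  if (any(!is.finite(thi))) stop("non-finite THI")
  as.character(cut(thi, breaks = c(-Inf, 70, 76, 81, Inf), right = FALSE,
                   labels = c("Comfort", "Warning", "Danger", "Emergency")))
}

#' TD deviation warning state
#'
#' Heat deviation when TD exceeds +2.5 degC, cold deviation below -2.5 degC,
#' otherwise normal; the boundaries themselves (exactly +-2.5) are normal
#' (strict inequalities).
#'
#' @param td temperature deviation(s), degC.
#' @param threshold deviation threshold, degC (default 2.5).
#' @return character vector in \{ColdDeviation, Normal, HeatDeviation\}.
#' @export
td_warning_state <- function(td, threshold = 2.5) {
  if (any(!is.finite(td))) stop("non-finite TD")
  ifelse(td > threshold, "HeatDeviation",
         ifelse(td < -threshold, "ColdDeviation", "Normal"))
}

#' Rolling dual-indicator early warnings
#'
#' Applies the fitted TD and THI forecasters to a series in rolling fashion
#' (one prediction per 5-min step after the L-step warm-up), labels each
#' predicted instant with the TD deviation state and the THI risk level, and
#' emits one warning record per step. When both indicators trigger at the
#' same instant, both warnings appear in the same record.
#'
#' @param td_model,thi_model fitted [wecagru()] models for TD and THI.
#' @param series an aligned, gap-free series carrying both models' inputs.
#' @param threshold TD deviation threshold, degC.
#' @return data.frame of class \code{warning_log}: \code{time},
#'   \code{td_pred}, \code{thi_pred}, \code{td_state}, \code{thi_level}.
#' @export
rolling_warn <- function(td_model, thi_model, series, threshold = 2.5) {
  stopifnot(inherits(td_model, "wecagru"), inherits(thi_model, "wecagru"),
            td_model$target == "td", thi_model$target == "thi")
  ptd <- predict(td_model, series)
  pthi <- predict(thi_model, series)
  m <- merge(ptd[c("time", "predicted")], pthi[c("time", "predicted")],
             by = "time", suffixes = c("_td", "_thi"))
  out <- data.frame(time = m$time, td_pred = m$predicted_td,
                    thi_pred = m$predicted_thi)
  out$td_state <- td_warning_state(out$td_pred, threshold)
  out$thi_level <- thi_risk_level(out$thi_pred)
  class(out) <- c("warning_log", "data.frame")
  out
}

#' Distribution statistics of predicted vs actual warning states
#'
#' Per-state proportions (percent of n, 2 d.p.) of the actual and predicted
#' state streams, plus for TD: the overheating frequency deviation
#' |n_pred_heat - n_act_heat| / n_act_heat x 100 (not applicable when no
#' actual heat state occurs) and the state distribution consistency
#' (n - |n_pred_heat - n_act_heat| - |n_pred_cold - n_act_cold|) / n x 100.
#' For THI the consistency is the distribution overlap
#' (n - sum_l |n_pred_l - n_act_l| / 2) / n x 100 over the four risk levels.
#'
#' @param actual,predicted equal-length character vectors of TD states
#'   (\code{ColdDeviation}/\code{Normal}/\code{HeatDeviation}) or THI levels
#'   (\code{Comfort}/\code{Warning}/\code{Danger}/\code{Emergency}).
#' @param indicator \code{"td"} or \code{"thi"}.
#' @return object of class \code{warning_stats}: list with \code{n},
#'   \code{counts} (actual/predicted per state), \code{proportions}
#'   (percent, 2 d.p.), \code{consistency_pct} and, for TD,
#'   \code{overheat_freq_deviation_pct}.
#' @examples
#' act <- rep(c("HeatDeviation", "Normal"), c(38, 558))
#' prd <- rep(c("HeatDeviation", "Normal"), c(40, 556))
#' warning_stats(act, prd, "td")  # deviation 5.26%, consistency 99.66%
#' @export
warning_stats <- function(actual, predicted, indicator = c("td", "thi")) {
  indicator <- match.arg(indicator)
  n <- length(actual)
  if (length(predicted) != n) stop("actual and predicted lengths differ")
  if (n < 1L) stop("empty state streams")
  states <- if (indicator == "td") c("ColdDeviation", "Normal", "HeatDeviation")
            else c("Comfort", "Warning", "Danger", "Emergency")
  bad <- setdiff(unique(c(actual, predicted)), states)
  if (length(bad)) stop("unknown state labels: ", paste(bad, collapse = ", "))
  cnt <- function(x) {
    tab <- table(factor(x, levels = states))
    as.integer(tab)
  }
  ca <- cnt(actual); cp <- cnt(predicted)
  names(ca) <- names(cp) <- states
  prop <- function(cc) round(100 * cc / n, 2)
  out <- list(indicator = indicator, n = n,
              counts = list(actual = ca, predicted = cp),
              proportions = list(actual = prop(ca), predicted = prop(cp)))
  if (indicator == "td") {
    dheat <- abs(cp[["HeatDeviation"]] - ca[["HeatDeviation"]])
    dcold <- abs(cp[["ColdDeviation"]] - ca[["ColdDeviation"]])
    out$overheat_freq_deviation_pct <-
      if (ca[["HeatDeviation"]] == 0) NA_real_
      else round(100 * dheat / ca[["HeatDeviation"]], 2)
    out$consistency_pct <- round(100 * (n - dheat - dcold) / n, 2)
  } else {
    out$consistency_pct <- round(100 * (n - sum(abs(cp - ca)) / 2) / n, 2)
  }
  class(out) <- "warning_stats"
  out
}

#' @export
print.warning_stats <- function(x, ...) {
  cat(sprintf("%s warning statistics (n = %d)\n", toupper(x$indicator), x$n))
  for (s in names(x$counts$actual))
    cat(sprintf("  %-14s actual %6.2f%%  predicted %6.2f%%\n", s,
                x$proportions$actual[s], x$proportions$predicted[s]))
  if (!is.null(x$overheat_freq_deviation_pct))
    cat(sprintf("  overheating frequency deviation: %s%%\n",
                format(x$overheat_freq_deviation_pct)))
  cat(sprintf("  state distribution consistency: %.2f%%\n", x$consistency_pct))
  invisible(x)
}

#' Combined TD + THI warning report
#'
#' @param actual_series an [aligned_series] with true \code{TD} and
#'   \code{THI} at the warned instants.
#' @param log a \code{warning_log} from [rolling_warn()].
#' @param threshold TD threshold, degC.
#' @return list with \code{td} and \code{thi} [warning_stats()] objects.
#' @export
warning_report <- function(actual_series, log, threshold = 2.5) {
  df <- as.data.frame(actual_series)
  m <- merge(df[c("time", "TD", "THI")], as.data.frame(log), by = "time")
  if (!nrow(m)) stop("no overlapping instants between series and warning log")
  list(td = warning_stats(td_warning_state(m$TD, threshold), m$td_state, "td"),
       thi = warning_stats(thi_risk_level(m$THI), m$thi_level, "thi"))
}
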