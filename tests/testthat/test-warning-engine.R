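# State identification and the dual-indicator early-warning strategy.

test_that("environmental state rule is inclusive at both band edges", {
  sch <- default_age_schedule()
  # temperature band at age 20 is 28-29 degC
  expect_equal(classify_env_state(c(27.9, 28, 28.5, 29, 29.5), "temperature",
                                  20, sch),
               c("Low", "Normal", "Normal", "Normal", "High"))
  # CO2 has only an upper limit
  expect_equal(classify_env_state(c(1500, 1600), "co2", 20, sch),
               c("Normal", "OverLimit"))
  # humidity band at age 20 is 60-65%
  expect_equal(classify_env_state(c(59.9, 60, 65, 65.1), "humidity", 20, sch),
               c("Low", "Normal", "Normal", "High"))
  # wind band at age 29+ is 1.5-2.5 m/s
  expect_equal(classify_env_state(c(1.4, 1.5, 2.5, 2.6), "wind", 30, sch),
               c("Low", "Normal", "Normal", "High"))
  expect_error(classify_env_state(1, "pressure", 20, sch))
})

test_that("THI risk levels split at 70 / 76 / 81 with inclusive lower bounds", {
  expect_equal(thi_risk_level(c(69.9, 70, 75.9, 76, 80.9, 81, 90)),
               c("Comfort", "Warning", "Warning", "Danger", "Danger",
                 "Emergency", "Emergency"))
  expect_error(thi_risk_level(NA_real_), "non-finite")
})

test_that("TD warning uses strict +-2.5 degC thresholds", {
  expect_equal(td_warning_state(c(2.6, -2.6, 2.5, -2.5, 0)),
               c("HeatDeviation", "ColdDeviation", "Normal", "Normal",
                 "Normal"))
})

test_that("threshold classifiers are exhaustive, exclusive and monotone", {
  sch <- default_age_schedule()
  grid <- seq(-10, 50, by = 0.25)
  s <- classify_env_state(grid, "temperature", 10, sch)
  expect_true(all(s %in% c("Low", "Normal", "High")))
  # monotone step function: Low ... Normal ... High in order
  expect_true(all(diff(match(s, c("Low", "Normal", "High"))) >= 0))
  lv <- thi_risk_level(seq(50, 95, by = 0.5))
  expect_true(all(diff(match(lv, c("Comfort", "Warning", "Danger",
                                   "Emergency"))) >= 0))
  td <- td_warning_state(seq(-5, 5, by = 0.1))
  expect_true(all(diff(match(td, c("ColdDeviation", "Normal",
                                   "HeatDeviation"))) >= 0))
})

test_that("warning statistics reproduce the published worked example exactly", {
  act <- rep(c("HeatDeviation", "Normal"), c(38, 558))   # n = 596
  prd <- rep(c("HeatDeviation", "Normal"), c(40, 556))
  st <- warning_stats(act, prd, "td")
  expect_equal(st$n, 596L)
  expect_equal(st$proportions$actual[["Normal"]], 93.62)
  expect_equal(st$proportions$predicted[["Normal"]], 93.29)
  expect_equal(st$proportions$actual[["HeatDeviation"]], 6.38)
  expect_equal(st$proportions$predicted[["HeatDeviation"]], 6.71)
  expect_equal(st$overheat_freq_deviation_pct, 5.26, ignore_attr = TRUE)
  expect_equal(st$consistency_pct, 99.66)
})

test_that("warning statistics behave at the degenerate corners", {
  same <- rep(c("Normal", "HeatDeviation"), c(90, 10))
  st <- warning_stats(same, same, "td")
  expect_equal(st$overheat_freq_deviation_pct, 0, ignore_attr = TRUE)
  expect_equal(st$consistency_pct, 100)
  # all actual/predicted at the THI warning level -> 100% consistency
  w <- rep("Warning", 50)
  expect_equal(warning_stats(w, w, "thi")$consistency_pct, 100)
  # no actual heat state -> deviation not applicable
  st2 <- warning_stats(rep("Normal", 10),
                       rep(c("Normal", "HeatDeviation"), c(9, 1)), "td")
  expect_true(is.na(st2$overheat_freq_deviation_pct))
  # proportions per source sum to 100 within rounding
  set.seed(1)
  r1 <- sample(c("ColdDeviation", "Normal", "HeatDeviation"), 333, TRUE)
  r2 <- sample(c("ColdDeviation", "Normal", "HeatDeviation"), 333, TRUE)
  st3 <- warning_stats(r1, r2, "td")
  expect_lt(abs(sum(st3$proportions$actual) - 100), 0.02)
  expect_lt(abs(sum(st3$proportions$predicted) - 100), 0.02)
  expect_error(warning_stats(c("Normal"), c("Hot")), "unknown state")
})

test_that("rolling warnings label every step after warm-up and detect a heat ramp", {
  set.seed(20)
  n <- 220
  ser <- tiny_series(n, seed = 20)
  # inject a sustained heat excursion inside the test span
  ramp <- 190:205
  ser$Tin[ramp] <- ser$Ttarget[ramp] + 4
  ser$TD <- ser$Tin - ser$Ttarget
  ser$THI <- compute_thi(ser$Tin, ser$RHin)
  fit_td <- wecagru(ser, "td", variant = "gru", hidden_dim = 8,
                    max_epochs = 25, seed = 3)
  fit_thi <- wecagru(ser, "thi", variant = "gru", hidden_dim = 8,
                     max_epochs = 25, seed = 3)
  log <- rolling_warn(fit_td, fit_thi, ser)
  # one record per step after the L + H warm-up
  expect_equal(nrow(log), n - fit_td$L - fit_td$H + 1)
  expect_true(all(log$td_state %in% c("ColdDeviation", "Normal", "HeatDeviation")))
  expect_true(all(log$thi_level %in% c("Comfort", "Warning", "Danger", "Emergency")))
  # labels are consistent with the predictions they annotate
  expect_equal(log$td_state, td_warning_state(log$td_pred))
  expect_equal(log$thi_level, thi_risk_level(log$thi_pred))
  rep <- warning_report(ser, log)
  expect_s3_class(rep$td, "warning_stats")
  expect_s3_class(rep$thi, "warning_stats")
})
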