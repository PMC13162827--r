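# Alignment, aggregation, interpolation, indicators, splitting,
# normalization, correlation screening and window construction.

rec <- function(ts, id = "robot-01", kind = "robot", temp = 25, rh = 60,
                wind = 0.3, co2 = 900) {
  data.frame(timestamp = as.POSIXct("2025-06-01", tz = "UTC") + ts,
             source_id = id, source_kind = kind, channel = NA_integer_,
             cage = NA_integer_, temp_c = temp, rh_pct = rh, wind_ms = wind,
             co2_ppm = co2)
}

test_that("alignment snaps records to the nearest 3-s grid point", {
  a <- align_sources(rec(1))            # 1 s -> grid 0
  expect_equal(as.numeric(a$time) %% 86400, 0)
  b <- align_sources(rec(2))            # 2 s -> grid 3
  expect_equal(as.numeric(b$time) %% 86400, 3)
  # no record within 1.5 s of grid point 3 -> that cell missing (no row)
  c2 <- align_sources(rbind(rec(0), rec(7)))
  expect_equal(as.numeric(c2$time) %% 86400, c(0, 6))
})

test_that("alignment ties are deterministic: earlier record wins", {
  # two records equidistant (1 s) from grid point 3
  two <- rbind(rec(2, temp = 20), rec(4, temp = 30))
  a <- align_sources(two)
  expect_equal(a$temp_c[as.numeric(a$time) %% 86400 == 3], 20)
  # a single record exactly halfway (1.5 s) goes to the earlier grid point
  h <- align_sources(rec(1.5, temp = 21))
  expect_equal(as.numeric(h$time) %% 86400, 0)
})

test_that("duplicates collapse; conflicting same-timestamp records are last-write-wins", {
  d <- rbind(rec(0), rec(0))  # exact duplicate
  expect_equal(nrow(align_sources(d)), 1L)
  conflict <- rbind(rec(0, temp = 20), rec(0, temp = 22))
  expect_equal(align_sources(conflict)$temp_c, 22)
  expect_equal(nrow(align_sources(data.frame())), 0L)
})

test_that("5-min aggregation averages valid in-range values per half-open window", {
  r <- rbind(rec(10, temp = 24), rec(100, temp = 26))
  s <- aggregate_5min(align_sources(r))
  expect_equal(s$Tin[1], 25)
  # out-of-range value excluded
  r2 <- rbind(rec(10, temp = 24), rec(100, temp = 999))
  expect_equal(aggregate_5min(align_sources(r2))$Tin[1], 24)
  # below-range CO2 excluded too (sensor floor 300 ppm)
  r3 <- rbind(rec(10, co2 = 100), rec(100, co2 = 800))
  expect_equal(aggregate_5min(align_sources(r3))$CO2[1], 800)
  # window with zero valid values -> missing
  r4 <- rbind(rec(10, temp = 999), rec(400, temp = 25))
  agg <- aggregate_5min(align_sources(r4))
  expect_true(is.na(agg$Tin[1]))
  expect_equal(agg$Tin[2], 25)
  # half-open windows: a record at exactly 300 s belongs to the second window
  r5 <- rbind(rec(0, temp = 20), rec(300, temp = 30))
  expect_equal(aggregate_5min(align_sources(r5))$Tin, c(20, 30))
})

test_that("indoor policy separates robot/fixed from outdoor sources", {
  r <- rbind(rec(10, id = "robot-01", kind = "robot", temp = 24),
             rec(10, id = "fixed-01", kind = "fixed", temp = 26),
             rec(10, id = "outdoor-01", kind = "outdoor", temp = 30))
  s <- aggregate_5min(align_sources(r))
  expect_equal(s$Tin[1], 25)   # robot + fixed
  expect_equal(s$Tout[1], 30)
  s2 <- aggregate_5min(align_sources(r), indoor = "robot")
  expect_equal(s2$Tin[1], 24)
})

test_that("aggregating an already 5-min series is the identity", {
  ser <- tiny_series(50)
  agg <- aggregate_5min(ser)
  expect_equal(as.data.frame(agg), as.data.frame(ser), tolerance = 1e-12)
})

test_that("linear interpolation fills interior gaps, nearest value fills edges", {
  t0 <- as.POSIXct("2025-06-01", tz = "UTC")
  s <- aligned_series(t0 + c(0, 300, 600), data.frame(Tin = c(10, NA, 14)))
  expect_equal(interpolate_missing(s)$Tin, c(10, 12, 14))
  s2 <- aligned_series(t0 + c(0, 300, 600), data.frame(Tin = c(NA, 5, 5)))
  expect_equal(interpolate_missing(s2)$Tin, c(5, 5, 5))
  s3 <- aligned_series(t0 + c(0, 300, 600), data.frame(Tin = c(1, 2, 3)))
  expect_identical(interpolate_missing(s3)$Tin, c(1, 2, 3))
  s4 <- aligned_series(t0 + c(0, 300), data.frame(Tin = c(NA_real_, NA_real_)))
  expect_error(interpolate_missing(s4), "no valid values")
})

test_that("TD is the signed difference from the age target", {
  t0 <- as.POSIXct("2025-06-01", tz = "UTC")
  s <- aligned_series(t0 + c(0, 300, 600),
                      data.frame(Tin = c(28.5, 24, 26), Age = 24,
                                 Ttarget = 26))
  td <- compute_td(s)$TD
  expect_equal(td, c(2.5, -2, 0))
})

test_that("THI matches its closed forms and monotonicity", {
  expect_equal(compute_thi(25, 60), 72.82)
  # RH = 100: the humidity term vanishes
  for (T in c(0, 10, 26/1.8, 30))
    expect_equal(compute_thi(T, 100), 1.8 * T + 32, tolerance = 1e-12)
  # T = 26/1.8: THI = 58 at any RH
  for (rh in c(0, 37, 100))
    expect_equal(compute_thi(26 / 1.8, rh), 58, tolerance = 1e-12)
  # strictly increasing in T at any RH
  for (rh in c(0, 50, 100))
    expect_true(all(diff(compute_thi(seq(-5, 40, by = 0.5), rh)) > 0))
  # increasing in RH iff T > 26/1.8
  expect_gt(compute_thi(20, 80), compute_thi(20, 40))
  expect_lt(compute_thi(10, 80), compute_thi(10, 40))
  expect_error(compute_thi(25, 120), "outside")
})

test_that("chronological split uses floor(0.8 n) without shuffling", {
  ser <- tiny_series(10)
  sp <- chronological_split(ser)
  expect_equal(nrow(sp$train), 8L)
  expect_equal(nrow(sp$test), 2L)
  expect_true(max(sp$train$time) < min(sp$test$time))
  expect_equal(chronological_split(tiny_series(60), 0.8)$n_train, 48L)
  # the published record count splits 6766 / 1692
  expect_equal(floor(0.8 * 8458), 6766)
  expect_equal(8458 - floor(0.8 * 8458), 1692)
  expect_error(chronological_split(ser, 1), "ratio")
  expect_error(chronological_split(ser, 0), "ratio")
})

test_that("min-max normalizer is leak-free, unclipped and invertible", {
  ser <- tiny_series(100)
  ser$Tin[95] <- max(ser$Tin) + 3   # test-span extreme must never leak in
  sp <- chronological_split(ser)
  nz <- fit_normalizer(sp$train, c("Tin", "TD", "THI"))
  # boundary mapping
  expect_equal(normalize(nz, nz$Tin[["min"]], "Tin"), c(min = 0), ignore_attr = TRUE)
  expect_equal(normalize(nz, nz$Tin[["max"]], "Tin"), c(max = 1), ignore_attr = TRUE)
  # training rows all land in [0, 1]
  ztr <- normalize(nz, sp$train)
  expect_true(all(ztr$Tin >= 0 & ztr$Tin <= 1))
  # values beyond the training range are not clipped
  expect_gt(normalize(nz, nz$Tin[["max"]] + 1, "Tin"), 1)
  expect_lt(normalize(nz, nz$Tin[["min"]] - 1, "Tin"), 0)
  # affine round-trip
  x <- seq(-5, 45, by = 0.7)
  expect_equal(denormalize(nz, normalize(nz, x, "Tin"), "Tin"), x,
               tolerance = 1e-9)
  # leak-freedom: stats computed on train only, never train+test
  nz_all <- fit_normalizer(ser, c("Tin"))
  expect_equal(nz$Tin[["min"]], min(sp$train$Tin))
  expect_equal(nz$Tin[["max"]], max(sp$train$Tin))
  expect_false(isTRUE(all.equal(nz_all$Tin, nz$Tin)))
  # constant column errors by name
  cs <- tiny_series(20)
  cs$Vin <- 1
  expect_error(fit_normalizer(cs, "Vin"), "Vin")
  # JSON round-trip
  f <- tempfile(fileext = ".json")
  write_normalizer(nz, f)
  expect_equal(read_normalizer(f)$TD, nz$TD)
})

test_that("pearson correlation and strength classes follow the band definitions", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(round(pearson_r(x, c(1, 2, 4)), 4) , 0.9820)
  expect_error(pearson_r(x, c(2, 2, 2)), "constant")
  expect_equal(classify_correlation(c(0.55, -0.95, 0.30, 0.29, 0.7, -0.5)),
               c("moderate", "very_high", "low", "negligible", "high",
                 "moderate"))
})

test_that("feature selection returns the screened sets; screen mode applies the 0.50 cutoff", {
  expect_equal(select_features("td"), c("Age", "TD", "Tout", "CO2", "Ttarget"))
  expect_equal(select_features("thi"), c("Age", "THI", "Tin", "Ttarget"))
  # screen mode: a weakly correlated synthetic variable is excluded
  ser <- tiny_series(200, seed = 3)
  set.seed(4)
  ser$Junk <- rnorm(nrow(ser))                       # |r| ~ 0
  ser$Strong <- ser$TD * 2 + rnorm(nrow(ser), 0, 0.1)  # |r| ~ 1
  got <- select_features("td", train = ser, mode = "screen")
  expect_false("Junk" %in% got)
  expect_true("Strong" %in% got)
  expect_equal(got[1], "TD")
})

test_that("window construction matches brute-force enumeration", {
  ser_n <- 50; L <- 36; H <- 6
  x <- matrix(rnorm(ser_n * 2), ncol = 2); y <- rnorm(ser_n)
  w <- make_windows(x, y, L, H)
  expect_equal(dim(w$X)[1], 9L)             # 50 - 36 - 6 + 1
  w1 <- make_windows(matrix(rnorm(42), ncol = 1), rnorm(42), L, H)
  expect_equal(dim(w1$X)[1], 1L)            # minimum length
  expect_warning(make_windows(matrix(rnorm(41), ncol = 1), rnorm(41), L, H),
                 "no samples")
  # formula holds for many (n, L, H, stride) against enumeration
  set.seed(5)
  for (i in 1:25) {
    n <- sample(10:80, 1); Lw <- sample(2:12, 1); Hw <- sample(1:6, 1)
    st <- sample(1:4, 1)
    starts <- enum_windows(n, Lw, Hw, st)
    if (length(starts) == 0) next
    ww <- make_windows(matrix(seq_len(n), ncol = 1), seq_len(n), Lw, Hw, st)
    expect_equal(dim(ww$X)[1], length(starts))
    # contents: sample i covers rows starts[i] .. starts[i]+L-1, target at +L+H-1
    for (j in seq_along(starts)) {
      expect_equal(as.numeric(ww$X[j, , 1]), starts[j] + 0:(Lw - 1))
      expect_equal(ww$y[j], starts[j] + Lw + Hw - 1)
    }
  }
})

test_that("windows are causal: editing rows after the anchor leaves earlier samples intact", {
  n <- 60
  x <- matrix(rnorm(n), ncol = 1); y <- rnorm(n)
  w <- make_windows(x, y, 10, 3)
  x2 <- x; x2[40:60, ] <- 999; y2 <- y; y2[40:60] <- 999
  w2 <- make_windows(x2, y2, 10, 3)
  safe <- which(w$target_row < 40)  # anchor and target both before the edit
  expect_equal(w2$X[safe, , ], w$X[safe, , ])
  expect_equal(w2$y[safe], w$y[safe])
})

test_that("missing summary reports counts and 2-d.p. percentages", {
  t0 <- as.POSIXct("2025-06-01", tz = "UTC")
  s <- aligned_series(t0 + 300 * (0:9),
                      data.frame(CO2 = c(NA, NA, rnorm(8)), Tin = rnorm(10)))
  ms <- missing_summary(s)
  expect_equal(ms$missing[ms$variable == "CO2"], 2L)
  expect_equal(ms$missing_pct[ms$variable == "CO2"], 20)
})
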