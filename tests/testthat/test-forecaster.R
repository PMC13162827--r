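# Forecaster building blocks: ECA, GRU, training, variants, causality.

test_that("adaptive ECA kernel size follows the floor/odd-bump rule", {
  expect_equal(eca_kernel_size(8), 3L)
  expect_equal(eca_kernel_size(2), 1L)
  expect_equal(eca_kernel_size(64), 3L)
  expect_equal(eca_kernel_size(9), 3L)
  expect_equal(eca_kernel_size(1), 1L)
  expect_error(eca_kernel_size(0), ">= 1")
})

test_that("ECA weights lie strictly in (0,1) and rescale channels", {
  set.seed(1)
  X <- matrix(rnorm(36 * 6), 36, 6)
  al <- rnorm(3)
  at <- eca_attend(X, al)
  expect_true(all(at$weights > 0 & at$weights < 1))
  expect_equal(at$output, sweep(X, 2, at$weights, `*`))
  # saturating kernel pushes weights toward 1 -> output toward input
  Xp <- matrix(abs(rnorm(36 * 4)) + 1, 36, 4)  # positive descriptors
  at2 <- eca_attend(Xp, c(50, 50, 50))
  expect_lt(max(abs(at2$output - Xp)), 1e-6)
})

test_that("ECA weights are invariant to the window length and symmetric layouts", {
  set.seed(2)
  base <- matrix(rnorm(12 * 5), 12, 5)
  al <- rnorm(3)
  w1 <- eca_attend(base, al)$weights
  # repeating the window in time leaves the temporal mean, hence the weights
  w2 <- eca_attend(rbind(base, base, base), al)$weights
  expect_equal(w1, w2, tolerance = 1e-12)
  # palindromic channel layout + symmetric kernel -> mirror-equal weights
  d <- c(1.0, -0.5, 2.0, -0.5, 1.0)
  Xp <- matrix(rep(d, each = 10), 10, 5)
  ws <- eca_attend(Xp, c(0.3, 1.1, 0.3))$weights
  expect_equal(ws[1], ws[5], tolerance = 1e-12)
  expect_equal(ws[2], ws[4], tolerance = 1e-12)
})

test_that("GRU forward matches the plain-R gate-equation oracle", {
  set.seed(3)
  X <- matrix(rnorm(12 * 3), 12, 3)
  p <- rand_gru_params(C = 3, H = 4)
  expect_equal(gru_forward(X, p), r_gru_oracle(X, p), tolerance = 1e-10)

  # scalar hand case (C = 1, hidden = 1): one step by hand
  ps <- list(Wz = matrix(0.5), Uz = matrix(0.1), bz = matrix(0),
             Wr = matrix(-0.3), Ur = matrix(0.2), br = matrix(0),
             Wh = matrix(0.8), Uh = matrix(-0.4), bh = matrix(0))
  x1 <- 0.7
  z1 <- 1 / (1 + exp(-0.5 * x1))
  hc1 <- tanh(0.8 * x1)           # h0 = 0 so reset gate drops out
  h1 <- z1 * hc1
  expect_equal(gru_forward(matrix(x1, 1, 1), ps), h1, tolerance = 1e-10)

  # all-zero weights keep the hidden state at zero from h0 = 0
  pz <- lapply(ps, function(m) m * 0)
  expect_equal(gru_forward(matrix(rnorm(5), 5, 1), pz), 0, tolerance = 1e-12)
  expect_error(gru_forward(matrix(c(1, NA), 2, 1), ps), "non-finite")
})

test_that("finite differences confirm the analytic gradients of every backbone", {
  set.seed(4)
  for (spec in list(c("gru", FALSE), c("gru", TRUE), c("lstm", FALSE),
                    c("tcn", FALSE), c("tcn", TRUE))) {
    type <- spec[1]; eca <- as.logical(spec[2])
    L <- 6L; C <- 3L; N <- 4L
    cfg <- list(type = type, eca = eca, bias = TRUE, hidden = 3L, k = 3L,
                ksize = 3L, dilations = c(1L, 2L))
    X <- array(rnorm(L * C * N), dim = c(L, C, N)); y <- rnorm(N)
    p <- broodcast:::cpp_init_params(cfg, C, 11L)
    # jitter away from exactly-zero biases so no ReLU pre-activation sits on
    # the kink, where central differences are not the derivative
    p <- lapply(p, function(m) m + matrix(rnorm(length(m), 0, 0.05),
                                          nrow(m), ncol(m)))
    lg <- broodcast:::cpp_loss_grad(X, y, p, cfg)
    for (nm in names(p)) {
      i <- sample(length(p[[nm]]), 1)  # one random element per matrix
      eps <- 1e-6
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (broodcast:::cpp_loss_grad(X, y, pp, cfg)$loss -
              broodcast:::cpp_loss_grad(X, y, pm, cfg)$loss) / (2 * eps)
      expect_equal(lg$grads[[nm]][i], num, tolerance = 1e-5,
                   label = paste(type, eca, nm))
    }
  }
})

test_that("variants assemble the documented channel sets", {
  ser <- tiny_series(120)
  fit <- wecagru(ser, "td", variant = "wavelet_eca_gru", hidden_dim = 4,
                 max_epochs = 2, wavelet = wavelet_config(window = 16))
  expect_length(fit$channels, 9L)   # 5 screened + 4 wavelet
  expect_true(all(c("TD_a3", "TD_d1", "TD_d2", "TD_d3") %in% fit$channels))
  expect_true(fit$net_cfg$eca)

  fit_g <- wecagru(ser, "td", variant = "gru", hidden_dim = 4, max_epochs = 2)
  expect_equal(fit_g$channels, c("Age", "TD", "Tout", "CO2", "Ttarget"))
  expect_false(fit_g$net_cfg$eca)

  fit_thi <- wecagru(ser, "thi", variant = "wavelet_gru", hidden_dim = 4,
                     max_epochs = 2, wavelet = wavelet_config(window = 16))
  expect_length(fit_thi$channels, 8L)  # 4 screened + 4 wavelet
  expect_false(fit_thi$net_cfg$eca)

  # dropping the raw target channel is available as a switch
  fit_nr <- wecagru(ser, "td", variant = "wavelet_gru", hidden_dim = 4,
                    max_epochs = 2, include_raw_target = FALSE,
                    wavelet = wavelet_config(window = 16))
  expect_false("TD" %in% fit_nr$channels)
  expect_length(fit_nr$channels, 8L)

  # TCN receptive field covers the input window
  fit_t <- wecagru(ser, "td", variant = "tcn", hidden_dim = 4, max_epochs = 2)
  rf <- 1 + (fit_t$net_cfg$ksize - 1) * sum(fit_t$net_cfg$dilations)
  expect_gte(rf, fit_t$L)
})

test_that("training is seed-deterministic and predictions are pure functions", {
  ser <- tiny_series(140, seed = 6)
  f1 <- wecagru(ser, "td", variant = "eca_gru", hidden_dim = 6,
                max_epochs = 5, seed = 9)
  f2 <- wecagru(ser, "td", variant = "eca_gru", hidden_dim = 6,
                max_epochs = 5, seed = 9)
  expect_identical(f1$params, f2$params)
  expect_identical(predict(f1), predict(f2))
  f3 <- wecagru(ser, "td", variant = "eca_gru", hidden_dim = 6,
                max_epochs = 5, seed = 10)
  expect_false(identical(f1$params, f3$params))
  # same window twice -> identical output
  p1 <- predict(f1, ser); p2 <- predict(f1, ser)
  expect_identical(p1, p2)
})

test_that("a zeroed head predicts the inverse-normalized bias for any input", {
  ser <- tiny_series(120, seed = 7)
  fit <- wecagru(ser, "td", variant = "gru", hidden_dim = 4, max_epochs = 2)
  fit$params$Wy[] <- 0
  fit$params$by[] <- 0.25
  p <- predict(fit, ser)
  expected <- denormalize(fit$target_normalizer, 0.25, "target")
  expect_true(all(abs(p$predicted - expected) < 1e-12))
})

test_that("a constant target is learned to near-zero validation error", {
  n <- 130
  ser <- tiny_series(n, seed = 8)
  # an exactly constant target would make min-max scaling undefined, so use
  # a numerically constant one and demand the exactly representable fit
  ser$TD <- 1 + 1e-3 * sin(seq_len(n))
  fit <- wecagru(ser, "td", variant = "gru", hidden_dim = 4, max_epochs = 60,
                 features = c("Age", "TD", "Ttarget"), seed = 2)
  p <- predict(fit)
  expect_lt(mean((p$actual - p$predicted)^2), 1e-4)
})

test_that("the fitted pipeline is causal end-to-end", {
  ser <- tiny_series(160, seed = 9)
  fit <- wecagru(ser, "td", variant = "wavelet_eca_gru", hidden_dim = 4,
                 max_epochs = 3, wavelet = wavelet_config(window = 16))
  p0 <- predict(fit, ser)
  # perturb the series strictly after an anchor cutoff
  cut <- 120
  ser2 <- ser
  for (v in c("Tin", "TD", "THI", "Tout", "CO2"))
    ser2[[v]][(cut + 1):nrow(ser2)] <- ser2[[v]][(cut + 1):nrow(ser2)] + 50
  p1 <- predict(fit, ser2)
  # predictions whose whole input window (anchor <= cut) precedes the edit
  # are unchanged; anchors at row r use rows r-L+1..r
  anchors <- match(p0$time, ser$time) - fit$H
  safe <- which(anchors <= cut)
  expect_equal(p1$predicted[safe], p0$predicted[safe], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(p1$predicted, p0$predicted)))
})

test_that("early stopping restores the best validation weights", {
  ser <- tiny_series(160, seed = 10)
  fit <- wecagru(ser, "td", variant = "gru", hidden_dim = 6, max_epochs = 40,
                 patience = 3, seed = 5)
  h <- fit$history
  expect_lte(h$best_epoch, h$epochs_run)
  expect_equal(which.min(h$val), h$best_epoch)
})

test_that("model checkpoints round-trip bit-exactly", {
  ser <- tiny_series(120, seed = 11)
  fit <- wecagru(ser, "thi", variant = "gru", hidden_dim = 4, max_epochs = 2)
  f <- tempfile(fileext = ".rds")
  write_model(fit, f)
  back <- read_model(f)
  expect_identical(back$params, fit$params)
  expect_identical(predict(back, ser), predict(fit, ser))
})

test_that("degenerate inputs raise actionable errors", {
  ser <- tiny_series(120)
  expect_error(wecagru(ser, "td", variant = "gru", split_ratio = 0.2,
                       hidden_dim = 4, max_epochs = 2),
               "too short")
  gap <- ser; gap$Tout[5] <- NA
  expect_error(wecagru(gap, "td", variant = "gru", hidden_dim = 4,
                       max_epochs = 2), "missing")
  short <- tiny_series(30)
  expect_error(predict(wecagru(ser, "td", variant = "gru", hidden_dim = 4,
                               max_epochs = 2), short), "too short")
})
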