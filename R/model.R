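# The Wavelet-ECA-GRU forecaster and its ablation/baseline variants.
#
# wecagru() is the single fitting entry point: it takes an aligned,
# gap-filled 5-min series carrying the target indicator (TD or THI),
# assembles the normalized supervised windows (raw screened channels plus,
# for wavelet variants, the causal wavelet feature channels of the target),
# and trains the requested backbone with Adam and chronological-validation
# early stopping. Baselines (lstm, tcn, gru) and ablations (eca_gru,
# wavelet_gru) share the same data path so comparisons are like-for-like.

.variants <- c("wavelet_eca_gru", "wavelet_gru", "eca_gru", "gru", "lstm", "tcn")

#' Adaptive ECA kernel size
#'
#' The shared 1-D convolution of the efficient channel attention block uses
#' an odd kernel size chosen from the channel count:
#' t = floor(|log2(C)/gamma + b/gamma|), bumped to the next odd integer when
#' even, with a minimum of 1.
#'
#' @param C number of feature channels (>= 1).
#' @param gamma,b kernel-size hyperparameters (defaults 2 and 1).
#' @return odd integer kernel size.
#' @examples
#' eca_kernel_size(8)   # 3
#' eca_kernel_size(2)   # 1
#' @export
eca_kernel_size <- function(C, gamma = 2, b = 1) {
  if (any(C < 1)) stop("channel count must be >= 1")
  t <- floor(abs(log2(C) / gamma + b / gamma))
  k <- ifelse(t %% 2 == 1, t, t + 1)
  as.integer(pmax(1, k))
}

#' Efficient channel attention over one input window
#'
#' Each channel is summarized by its temporal mean; a shared zero-padded
#' length-k convolution over the channel axis plus a sigmoid yields one
#' weight per channel, strictly inside (0, 1), which rescales that channel.
#'
#' @param window numeric L x C matrix (time steps x channels).
#' @param alpha shared convolution kernel (odd length).
#' @return list with \code{weights} (length C) and \code{output} (the
#'   reweighted L x C window).
#' @export
eca_attend <- function(window, alpha) {
  window <- as.matrix(window)
  w <- as.numeric(cpp_eca_weights(window, as.numeric(alpha)))
  list(weights = w, output = sweep(window, 2L, w, `*`))
}

#' GRU forward pass over one window
#'
#' Iterates the update/reset-gate recursion from h_0 = 0 and returns the
#' hidden state after the last time step (the sequence representation).
#'
#' @param window numeric L x C matrix.
#' @param params named list of GRU parameters: \code{Wz, Uz, bz, Wr, Ur,
#'   br, Wh, Uh, bh} (hidden x C / hidden x hidden / hidden x 1).
#' @return numeric vector of length \code{hidden}.
#' @export
gru_forward <- function(window, params) {
  window <- as.matrix(window)
  if (!all(is.finite(window))) stop("non-finite input window")
  X <- array(window, dim = c(nrow(window), ncol(window), 1L))
  H <- nrow(params$Wz)
  if (is.null(params$Wy)) params$Wy <- matrix(0, 1, H)  # head unused here
  if (is.null(params$by)) params$by <- matrix(0, 1, 1)
  cfg <- list(type = "gru", eca = FALSE, bias = TRUE, hidden = H, k = 1L)
  as.numeric(cpp_hidden(X, params, cfg))
}

# raw (physical-unit) channel matrix + target for one series
build_channel_frame <- function(series, tvar, channels, use_wavelet, wconfig) {
  df <- as.data.frame(series)
  miss <- setdiff(c(channels, tvar), names(df))
  if (length(miss))
    stop("series lacks columns: ", paste(miss, collapse = ", "),
         " (run add_flock_context/compute_td/add_thi first)")
  x <- df[, channels, drop = FALSE]
  if (anyNA(x) || anyNA(df[[tvar]]))
    stop("series still has missing cells; run interpolate_missing() first")
  if (use_wavelet) {
    ft <- feature_track(df[[tvar]], wconfig)
    colnames(ft) <- paste0(tvar, "_", colnames(ft))
    x <- cbind(x, as.data.frame(ft))
  }
  list(x = x, y = df[[tvar]], time = df$time)
}

#' Fit a short-term broiler-house environment forecaster
#'
#' Trains a 30-min-ahead (H steps of 5 min) rolling forecaster for the
#' temperature deviation (TD) or temperature-humidity index (THI) of an
#' aligned house-level series. The flagship variant
#' \code{"wavelet_eca_gru"} feeds the screened input variables plus the
#' causal sliding-window wavelet features of the target through an
#' efficient-channel-attention block into a single-layer GRU with a linear
#' head; \code{"wavelet_gru"}, \code{"eca_gru"}, \code{"gru"},
#' \code{"lstm"} and \code{"tcn"} are the matched ablations/baselines.
#'
#' Training minimizes MSE on min-max-normalized targets (normalizers fitted
#' on the training span only) with Adam, batch shuffling and early stopping
#' on the chronological tail of the training windows; metrics and
#' predictions are reported in physical units.
#'
#' @param series an [aligned_series] with no missing cells carrying the
#'   screened input variables and the target indicator (see
#'   [select_features()], [compute_td()], [add_thi()]).
#' @param target \code{"td"} or \code{"thi"}.
#' @param variant model variant, one of \code{"wavelet_eca_gru"},
#'   \code{"wavelet_gru"}, \code{"eca_gru"}, \code{"gru"}, \code{"lstm"},
#'   \code{"tcn"}.
#' @param features input variables; default the screened set for the target.
#' @param wavelet a [wavelet_config()] (wavelet variants only).
#' @param hidden_dim hidden width of the backbone (default 128).
#' @param L,H input window length and forecast horizon in 5-min steps
#'   (defaults 36 and 6).
#' @param lr,batch_size,max_epochs Adam learning rate, batch size and epoch
#'   cap (defaults 0.001, 32, 200).
#' @param patience early-stopping patience in epochs (default 20;
#'   best-validation weights are restored).
#' @param val_fraction fraction of training windows held out chronologically
#'   for early stopping (default 0.1).
#' @param split_ratio chronological train share of the series rows (default
#'   0.8).
#' @param include_raw_target keep the raw target series among the input
#'   channels alongside its wavelet features (default TRUE; the TD model
#'   then has 5 raw + 4 wavelet = 9 channels).
#' @param use_bias include bias terms in all gates (default TRUE; FALSE
#'   reproduces the bias-free gate equations).
#' @param strict_split exclude test windows whose input history reaches back
#'   into the training span (default FALSE: deployment-realistic warm start;
#'   targets always lie in the test span either way).
#' @param eca_gamma,eca_b ECA kernel-size hyperparameters.
#' @param seed integer seed for parameter initialization and batch
#'   shuffling; fixed seed gives identical fits.
#' @param stride window stride (default 1).
#' @return an object of class \code{wecagru} with methods \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{fitted},
#'   \code{residuals} and \code{plot}.
#' @examples
#' \donttest{
#' sim <- simulate_house(scenario_config(duration_days = 3, seed = 7))
#' ser <- prepare_series(sim$records, start_age = 15)
#' fit <- wecagru(ser, "td", variant = "gru", hidden_dim = 8, max_epochs = 5)
#' print(fit)
#' head(predict(fit))
#' }
#' @export
wecagru <- function(series, target = c("td", "thi"),
                    variant = .variants, features = NULL,
                    wavelet = wavelet_config(), hidden_dim = 128L,
                    L = 36L, H = 6L, lr = 0.001, batch_size = 32L,
                    max_epochs = 200L, patience = 20L, val_fraction = 0.1,
                    split_ratio = 0.8, include_raw_target = TRUE,
                    use_bias = TRUE, strict_split = FALSE,
                    eca_gamma = 2, eca_b = 1, seed = 1L, stride = 1L) {
  stopifnot(inherits(series, "aligned_series"))
  target <- match.arg(target)
  variant <- match.arg(variant)
  tvar <- if (target == "td") "TD" else "THI"
  if (is.null(features)) features <- select_features(target)
  channels <- if (include_raw_target) features else setdiff(features, tvar)
  use_wavelet <- grepl("^wavelet", variant)
  use_eca <- grepl("eca", variant)
  backbone <- switch(variant, lstm = "lstm", tcn = "tcn", "gru")

  frame <- build_channel_frame(series, tvar, channels, use_wavelet, wavelet)
  n <- nrow(frame$x)
  n_train <- floor(split_ratio * n)
  if (n_train < L + H + 1L) stop("training span too short for L + H windows")

  normalizer <- fit_normalizer(frame$x[seq_len(n_train), , drop = FALSE],
                               constant = "zero")
  tnorm <- fit_normalizer(data.frame(target = frame$y[seq_len(n_train)]))
  xnorm <- as.matrix(normalize(normalizer, frame$x))
  ynorm <- normalize(tnorm, frame$y, "target")

  win <- make_windows(xnorm, ynorm, L = L, H = H, stride = stride)
  is_test <- win$target_row > n_train
  if (strict_split) is_test <- is_test & (win$anchor - L + 1L > n_train)
  tr_idx <- which(win$target_row <= n_train)
  te_idx <- which(is_test)
  n_val <- floor(val_fraction * length(tr_idx))
  val_idx <- if (n_val >= 1L) utils::tail(tr_idx, n_val) else integer(0)
  fit_idx <- setdiff(tr_idx, val_idx)
  if (length(fit_idx) < 1L) stop("no training samples")

  C <- ncol(xnorm)
  net_cfg <- list(type = backbone, eca = use_eca, bias = use_bias,
                  hidden = as.integer(hidden_dim),
                  k = eca_kernel_size(C, eca_gamma, eca_b),
                  ksize = 3L, dilations = c(1L, 2L, 4L, 8L, 16L))
  as_cube <- function(idx) aperm(win$X[idx, , , drop = FALSE], c(2L, 3L, 1L))
  fit <- cpp_train(as_cube(fit_idx), win$y[fit_idx],
                   as_cube(val_idx), win$y[val_idx],
                   net_cfg, lr, as.integer(batch_size),
                   as.integer(max_epochs), as.integer(patience),
                   as.integer(seed))

  predict_idx <- function(idx) {
    if (!length(idx)) return(numeric(0))
    denormalize(tnorm, as.numeric(cpp_forward(as_cube(idx), fit$params, net_cfg)),
                "target")
  }
  obj <- structure(list(
    variant = variant, target = target, tvar = tvar,
    channels = colnames(xnorm), features = channels,
    use_wavelet = use_wavelet, wavelet = if (use_wavelet) wavelet else NULL,
    params = fit$params, net_cfg = net_cfg,
    normalizer = normalizer, target_normalizer = tnorm,
    L = L, H = H, stride = stride, step = series_step(series),
    n = n, n_train = n_train, split_ratio = split_ratio,
    history = list(train = fit$train_loss, val = fit$val_loss,
                   best_epoch = fit$best_epoch, epochs_run = fit$epochs_run),
    hyper = list(hidden_dim = hidden_dim, lr = lr, batch_size = batch_size,
                 max_epochs = max_epochs, patience = patience,
                 val_fraction = val_fraction, use_bias = use_bias,
                 eca_gamma = eca_gamma, eca_b = eca_b, seed = seed,
                 strict_split = strict_split,
                 include_raw_target = include_raw_target),
    windows = list(train = tr_idx, val = val_idx, test = te_idx,
                   anchor = win$anchor, target_row = win$target_row),
    time = frame$time, actual = frame$y,
    call = match.call()), class = "wecagru")
  obj$train_pred <- predict_idx(tr_idx)
  obj$test_pred <- predict_idx(te_idx)
  obj
}

#' Rolling predictions of a fitted forecaster
#'
#' Without \code{newdata}, returns the held-out test-span predictions made
#' at fit time. With \code{newdata} (an aligned, gap-free series carrying
#' the model's input variables), rebuilds the causal windows with the
#' stored normalizers and wavelet configuration and predicts the target
#' H steps ahead of every anchor, in physical units.
#'
#' @param object a fitted \code{wecagru} model.
#' @param newdata optional [aligned_series].
#' @param ... unused.
#' @return data.frame with columns \code{time} (the predicted instant,
#'   anchor + H steps), \code{predicted} and, when the truth is available,
#'   \code{actual}.
#' @export
predict.wecagru <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    idx <- object$windows$test
    tr <- object$windows$target_row[idx]
    return(data.frame(time = object$time[tr],
                      actual = object$actual[tr],
                      predicted = object$test_pred))
  }
  stopifnot(inherits(newdata, "aligned_series"))
  frame <- build_channel_frame(newdata, object$tvar, object$features,
                               object$use_wavelet, object$wavelet)
  xnorm <- as.matrix(normalize(object$normalizer, frame$x))
  if (!identical(colnames(xnorm), object$channels))
    stop("newdata channels do not match the fitted model")
  ynorm <- normalize(object$target_normalizer, frame$y, "target")
  if (nrow(xnorm) < object$L + object$H)
    stop("newdata too short for L + H windows")
  win <- make_windows(xnorm, ynorm, L = object$L, H = object$H,
                      stride = object$stride)
  X <- aperm(win$X, c(2L, 3L, 1L))
  pred <- denormalize(object$target_normalizer,
                      as.numeric(cpp_forward(X, object$params, object$net_cfg)),
                      "target")
  data.frame(time = frame$time[win$target_row],
             actual = frame$y[win$target_row], predicted = pred)
}

#' @export
fitted.wecagru <- function(object, ...) {
  idx <- object$windows$train
  data.frame(time = object$time[object$windows$target_row[idx]],
             actual = object$actual[object$windows$target_row[idx]],
             predicted = object$train_pred)
}

#' @export
residuals.wecagru <- function(object, ...) {
  f <- fitted(object)
  f$actual - f$predicted
}

#' @export
coef.wecagru <- function(object, ...) object$params

#' @export
print.wecagru <- function(x, ...) {
  cat(sprintf("%s forecaster for %s (%d-step horizon = %d min)\n",
              x$variant, toupper(x$target), x$H, x$H * x$step / 60))
  cat(sprintf("  channels (%d): %s\n", length(x$channels),
              paste(x$channels, collapse = ", ")))
  cat(sprintf("  hidden %d, trained %d epochs (best %d)\n",
              x$hyper$hidden_dim, x$history$epochs_run, x$history$best_epoch))
  if (length(x$test_pred)) {
    m <- forecast_metrics(predict(x)$actual, x$test_pred)
    cat(sprintf("  test RMSE %.4f, R2 %.4f on %d windows\n", m$rmse, m$r2, m$n))
  }
  invisible(x)
}

#' @export
summary.wecagru <- function(object, ...) {
  f <- fitted(object)
  p <- predict(object)
  out <- list(model = object,
              train = forecast_metrics(f$actual, f$predicted),
              test = forecast_metrics(p$actual, p$predicted))
  class(out) <- "summary.wecagru"
  out
}

#' @export
print.summary.wecagru <- function(x, ...) {
  print(x$model)
  cat("  train:"); print(x$train)
  cat("  test: "); print(x$test)
  invisible(x)
}

#' @param x a fitted \code{wecagru} model.
#' @param which \code{"test"} (observed vs predicted on the test span) or
#'   \code{"history"} (training/validation loss per epoch).
#' @rdname predict.wecagru
#' @export
plot.wecagru <- function(x, which = c("test", "history"), ...) {
  which <- match.arg(which)
  if (which == "test") {
    p <- predict(x)
    graphics::plot(p$time, p$actual, type = "l", col = "steelblue",
                   xlab = "time", ylab = toupper(x$target),
                   main = sprintf("%s: observed vs predicted (test span)", x$variant),
                   ...)
    graphics::lines(p$time, p$predicted, col = "darkorange")
    graphics::legend("topleft", legend = c("observed", "predicted"),
                     col = c("steelblue", "darkorange"), lty = 1, bty = "n")
  } else {
    tr <- x$history$train
    graphics::plot(seq_along(tr), tr, type = "l", col = "steelblue",
                   xlab = "epoch", ylab = "MSE (normalized)",
                   main = "training history", ...)
    if (length(x$history$val))
      graphics::lines(seq_along(x$history$val), x$history$val, col = "darkorange")
  }
  invisible(x)
}

#' Save / load a fitted forecaster
#'
#' The checkpoint bundles the configuration, learned parameters, normalizers
#' and channel order in one file; loading restores a model whose predictions
#' are bit-identical to the original.
#'
#' @param model a \code{wecagru} model.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "wecagru"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "wecagru"))
  m
}
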