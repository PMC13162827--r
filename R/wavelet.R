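# Causal sliding-window discrete wavelet features.
#
# At every time step t the W most recent observations form a window signal;
# a pyramidal DWT decomposes it into a level-L approximation band and L detail
# bands, and the final (most recent) coefficient of each band is the feature
# vector at t. Because the window only ever contains observations at times
# <= t, the features are causal by construction.

.wavelet_filters <- list(
  db2 = list(
    dec_lo = c(-0.12940952255126037, 0.22414386804201339, 0.83651630373780794, 0.48296291314453416),
    dec_hi = c(-0.48296291314453416, 0.83651630373780794, -0.22414386804201339, -0.12940952255126037),
    rec_lo = c(0.48296291314453416, 0.83651630373780794, 0.22414386804201339, -0.12940952255126037),
    rec_hi = c(-0.12940952255126037, -0.22414386804201339, 0.83651630373780794, -0.48296291314453416)),
  db4 = list(
    dec_lo = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764, -0.18703481171909309,
               -0.027983769416859854, 0.63088076792985892, 0.71484657055291567, 0.23037781330889651),
    dec_hi = c(-0.23037781330889651, 0.71484657055291567, -0.63088076792985892, -0.027983769416859854,
               0.18703481171909309, 0.030841381835560764, -0.032883011666885197, -0.010597401785069032),
    rec_lo = c(0.23037781330889651, 0.71484657055291567, 0.63088076792985892, -0.027983769416859854,
               -0.18703481171909309, 0.030841381835560764, 0.032883011666885197, -0.010597401785069032),
    rec_hi = c(-0.010597401785069032, -0.032883011666885197, 0.030841381835560764, 0.18703481171909309,
               -0.027983769416859854, -0.63088076792985892, 0.71484657055291567, -0.23037781330889651)),
  sym4 = list(
    dec_lo = c(-0.075765714789273325, -0.02963552764599851, 0.49761866763201545, 0.80373875180591614,
               0.29785779560527736, -0.099219543576847216, -0.012603967262037833, 0.032223100604042702),
    dec_hi = c(-0.032223100604042702, -0.012603967262037833, 0.099219543576847216, 0.29785779560527736,
               -0.80373875180591614, 0.49761866763201545, 0.02963552764599851, -0.075765714789273325),
    rec_lo = c(0.032223100604042702, -0.012603967262037833, -0.099219543576847216, 0.29785779560527736,
               0.80373875180591614, 0.49761866763201545, -0.02963552764599851, -0.075765714789273325),
    rec_hi = c(-0.075765714789273325, 0.02963552764599851, 0.49761866763201545, -0.80373875180591614,
               0.29785779560527736, 0.099219543576847216, -0.012603967262037833, -0.032223100604042702)))

#' Decomposition/reconstruction filters of a wavelet basis
#'
#' @param basis one of \code{"db2"}, \code{"db4"}, \code{"sym4"}.
#' @return list with elements \code{dec_lo}, \code{dec_hi}, \code{rec_lo},
#'   \code{rec_hi}.
#' @export
wavelet_filters <- function(basis = c("db4", "db2", "sym4")) {
  basis <- match.arg(basis)
  .wavelet_filters[[basis]]
}

#' Configuration of the causal windowed wavelet decomposition
#'
#' @param basis wavelet basis, one of \code{"db2"}, \code{"db4"} (default),
#'   \code{"sym4"}.
#' @param levels decomposition depth (default 3).
#' @param window sliding-window length W in time steps (default 56). The
#'   window is longer than the model's 36-step input window on purpose: the
#'   wavelet memory at each input step uses its own 56-step history.
#' @param extension boundary extension inside the window; only half-sample
#'   \code{"symmetric"} extension is supported (the causal guarantee comes
#'   from the windowing itself, and symmetric extension minimizes artifacts
#'   at the crucial right edge).
#' @return object of class \code{wavelet_config}.
#' @export
wavelet_config <- function(basis = "db4", levels = 3L, window = 56L,
                           extension = "symmetric") {
  basis <- match.arg(basis, c("db2", "db4", "sym4"))
  levels <- as.integer(levels)
  window <- as.integer(window)
  if (!identical(extension, "symmetric"))
    stop("only symmetric (half-sample) extension is supported")
  if (levels < 1L) stop("levels must be >= 1")
  f <- length(.wavelet_filters[[basis]]$dec_lo)
  # the signal must remain at least as long as the filter at every level
  n <- window
  for (l in seq_len(levels)) {
    if (n < f)
      stop("window ", window, " too short for ", levels, "-level ", basis,
           " decomposition (length ", n, " < filter length ", f,
           " at level ", l, ")")
    n <- (n + f - 1L) %/% 2L
  }
  structure(list(basis = basis, levels = levels, window = window,
                 extension = extension),
            class = "wavelet_config")
}

# half-sample symmetric extension by m samples on each side
# (... x2 x1 | x1 x2 ... xn | xn xn-1 ...), with repeated reflection if m > n
sym_extend <- function(x, m) {
  n <- length(x)
  base <- seq_len(n)
  left <- integer(0); cur <- base
  while (length(left) < m) { cur <- rev(cur); left <- c(cur, left) }
  left <- left[seq.int(length(left) - m + 1L, length(left))]
  right <- integer(0); cur <- base
  while (length(right) < m) { cur <- rev(cur); right <- c(right, cur) }
  right <- right[seq_len(m)]
  x[c(left, base, right)]
}

# one analysis step: symmetric extension, convolution, dyadic downsampling
dwt_step <- function(x, flt) {
  f <- length(flt); n <- length(x)
  ext <- sym_extend(x, f - 1L)
  full <- stats::convolve(ext, rev(flt), type = "open")
  outlen <- (n + f - 1L) %/% 2L
  full[f - 1L + 2L * seq_len(outlen)]
}

# one synthesis step: zero-upsampling, convolution, edge trim
idwt_step <- function(ca, cd, rec_lo, rec_hi, n_out) {
  f <- length(rec_lo); m <- length(ca)
  up <- function(cc) { u <- numeric(2L * m); u[seq(1L, 2L * m, by = 2L)] <- cc; u }
  y <- stats::convolve(up(ca), rev(rec_lo), type = "open") +
       stats::convolve(up(cd), rev(rec_hi), type = "open")
  y[(f - 2L) + seq_len(n_out)]
}

#' Multi-level pyramidal DWT of a signal
#'
#' Decomposes \code{x} to \code{config$levels} levels with half-sample
#' symmetric boundary extension. \code{wavedec} returns the approximation
#' band and all detail bands; \code{waverec} inverts it (perfect
#' reconstruction up to floating-point error).
#'
#' @param x numeric signal.
#' @param config a [wavelet_config()].
#' @return \code{wavedec}: list with \code{a} (level-L approximation
#'   coefficients), \code{d} (list of detail coefficient vectors, level 1
#'   first) and \code{lengths} (input length per level, needed for
#'   reconstruction). \code{waverec}: the reconstructed signal.
#' @export
wavedec <- function(x, config = wavelet_config()) {
  stopifnot(inherits(config, "wavelet_config"))
  if (length(x) == 0L) stop("empty signal")
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  flt <- .wavelet_filters[[config$basis]]
  d <- vector("list", config$levels)
  lengths <- integer(config$levels)
  a <- x
  for (l in seq_len(config$levels)) {
    lengths[l] <- length(a)
    d[[l]] <- dwt_step(a, flt$dec_hi)
    a <- dwt_step(a, flt$dec_lo)
  }
  list(a = a, d = d, lengths = lengths)
}

#' @param coeffs result of [wavedec()].
#' @rdname wavedec
#' @export
waverec <- function(coeffs, config = wavelet_config()) {
  stopifnot(inherits(config, "wavelet_config"))
  flt <- .wavelet_filters[[config$basis]]
  a <- coeffs$a
  for (l in rev(seq_len(config$levels)))
    a <- idwt_step(a, coeffs$d[[l]], flt$rec_lo, flt$rec_hi, coeffs$lengths[l])
  a
}

#' Causal window ending at time step t
#'
#' Returns the last \code{W} observations up to and including index \code{t}
#' (1-based). When fewer than \code{W} observations exist, the window is
#' left-padded by replicating the earliest observed value.
#'
#' @param x numeric series.
#' @param t 1-based index of the current time step.
#' @param W window length.
#' @return numeric vector of length \code{W}.
#' @export
causal_window <- function(x, t, W) {
  if (length(x) == 0L) stop("empty series")
  stopifnot(t >= 1L, t <= length(x), W >= 1L)
  if (t >= W) return(x[seq.int(t - W + 1L, t)])
  c(rep(x[1L], W - t), x[seq_len(t)])
}

#' Wavelet feature vector at one time step
#'
#' Runs the pyramidal DWT on a length-W window signal and extracts the final
#' (most recent) coefficient of the approximation band and of each detail
#' band, so the features stay aligned with the current time step.
#'
#' @param signal numeric window of length \code{config$window}.
#' @param config a [wavelet_config()].
#' @return named numeric vector \code{c(a<L>, d1, ..., d<L>)} of length
#'   \code{levels + 1}.
#' @export
dwt_last_coeffs <- function(signal, config = wavelet_config()) {
  stopifnot(inherits(config, "wavelet_config"))
  if (length(signal) != config$window)
    stop("signal length ", length(signal), " != configured window ", config$window)
  dec <- wavedec(signal, config)
  out <- c(dec$a[length(dec$a)],
           vapply(dec$d, function(v) v[length(v)], numeric(1)))
  names(out) <- c(paste0("a", config$levels), paste0("d", seq_len(config$levels)))
  out
}

#' Per-time-step causal wavelet feature track
#'
#' Applies [causal_window()] + [dwt_last_coeffs()] at every time step of a
#' series. Row t of the result depends only on observations at times <= t.
#'
#' @param x numeric series (physical units; features are min-max scaled later
#'   with training-set statistics like any other input channel).
#' @param config a [wavelet_config()].
#' @return numeric matrix, \code{length(x)} rows and \code{levels + 1} named
#'   columns.
#' @export
feature_track <- function(x, config = wavelet_config()) {
  if (length(x) == 0L) stop("empty series")
  out <- matrix(0, nrow = length(x), ncol = config$levels + 1L)
  for (t in seq_along(x))
    out[t, ] <- dwt_last_coeffs(causal_window(x, t, config$window), config)
  colnames(out) <- c(paste0("a", config$levels), paste0("d", seq_len(config$levels)))
  out
}
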