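# Shared fixtures and independent oracles, all built in code.

# small gap-free aligned series with realistic column set, built directly
# (no simulator) for fast model/window tests
tiny_series <- function(n = 120, seed = 1, start_age = 16L) {
  set.seed(seed)
  tt <- seq(0, by = 300, length.out = n)
  age <- start_age + floor(tt / 86400)
  sch <- default_age_schedule()
  ttarget <- target_temperature(sch, age)
  tin <- ttarget + 1.5 * sin(2 * pi * tt / 86400) + rnorm(n, 0, 0.2)
  rhin <- 62 - 1.5 * (tin - ttarget) + rnorm(n, 0, 0.5)
  ser <- aligned_series(
    as.POSIXct("2025-06-10", tz = "UTC") + tt,
    data.frame(Tin = tin, RHin = rhin, Vin = 0.3 + rnorm(n, 0, 0.02),
               CO2 = 900 + 100 * cos(2 * pi * tt / 86400) + rnorm(n, 0, 10),
               Tout = 24 + 5 * sin(2 * pi * tt / 86400) + rnorm(n, 0, 0.3),
               RHout = 60 + rnorm(n, 0, 1), Vout = 1 + rnorm(n, 0, 0.05),
               Age = age, Ttarget = ttarget))
  ser <- compute_td(ser)
  add_thi(ser)
}

# independent filter-bank oracle: explicit half-sample symmetric extension,
# direct convolution sums and dyadic decimation written from the definition
naive_dwt_step <- function(x, flt) {
  f <- length(flt); n <- length(x)
  pad <- f - 1L
  stopifnot(pad <= n)  # fixture signals are long enough; no repeated mirroring
  left <- rev(x[seq_len(pad)])          # ... x2 x1 |
  right <- x[n:(n - pad + 1L)]          # | xn xn-1 ...
  ext <- c(left, x, right)
  outlen <- (n + f - 1L) %/% 2L
  out <- numeric(outlen)
  for (i in seq_len(outlen)) {
    # output sample i corresponds to full-convolution index f - 1 + 2 i (1-based)
    kk <- f - 1L + 2L * i
    acc <- 0
    for (j in seq_len(f)) {
      m <- kk - j + 1L
      if (m >= 1L && m <= length(ext)) acc <- acc + ext[m] * flt[j]
    }
    out[i] <- acc
  }
  out
}

naive_wavedec <- function(x, basis, levels) {
  flt <- wavelet_filters(basis)
  d <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    d[[l]] <- naive_dwt_step(a, flt$dec_hi)
    a <- naive_dwt_step(a, flt$dec_lo)
  }
  list(a = a, d = d)
}

# plain-R GRU oracle straight from the gate equations
r_gru_oracle <- function(X, p, h0 = NULL) {
  sig <- function(v) 1 / (1 + exp(-v))
  H <- nrow(p$Wz)
  h <- if (is.null(h0)) rep(0, H) else h0
  for (t in seq_len(nrow(X))) {
    x <- X[t, ]
    z <- sig(p$Wz %*% x + p$Uz %*% h + p$bz)
    r <- sig(p$Wr %*% x + p$Ur %*% h + p$br)
    hc <- tanh(p$Wh %*% x + p$Uh %*% (r * h) + p$bh)
    h <- (1 - z) * h + z * hc
  }
  as.numeric(h)
}

rand_gru_params <- function(C, H, seed = 1) {
  set.seed(seed)
  m <- function(r, c) matrix(rnorm(r * c, 0, 0.4), r, c)
  list(Wz = m(H, C), Uz = m(H, H), bz = m(H, 1),
       Wr = m(H, C), Ur = m(H, H), br = m(H, 1),
       Wh = m(H, C), Uh = m(H, H), bh = m(H, 1),
       Wy = m(1, H), by = m(1, 1))
}

# brute-force supervised-window enumeration from the definition
enum_windows <- function(n, L, H, stride) {
  starts <- integer(0)
  s <- 1L
  while (s + L + H - 1L <= n) { starts <- c(starts, s); s <- s + stride }
  starts
}

# fast low-resolution scenario for end-to-end tests
quick_config <- function(days = 2, seed = 1, ...) {
  scenario_config(duration_days = days, start_age = 16L,
                  robot_sample_interval = 60, seed = seed, ...)
}
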