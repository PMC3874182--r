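# Fixture builders: seeded piecewise-linear traces with grid-aligned knots.

# Piecewise-linear trace from knot times (snapped to the dt grid) and
# per-piece slopes, plus optional white noise.
piecewise_trace <- function(knots, slopes, total = 30, dt = 0.2,
                            y0 = 100, sigma = 0, seed = 1, force = 50) {
  stopifnot(length(slopes) == length(knots) + 1)
  knots <- round(knots / dt) * dt
  kt <- c(0, knots, total)
  kv <- c(y0, y0 + cumsum(slopes * diff(kt)))
  t <- seq(0, total, by = dt)
  y <- stats::approx(kt, kv, t)$y
  if (sigma > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(t), 0, sigma)
  }
  smt_trace(t, y, rep(force, length(t)))
}

# Random piecewise-linear trace: n_knots grid-aligned knots, pieces >= 4 s,
# adjacent slopes well separated. Returns trace plus true knots.
random_piecewise <- function(n_knots, total = 30, dt = 0.2, sigma = 0,
                             seed = 1) {
  set.seed(seed)
  repeat {
    kt <- round(sort(stats::runif(n_knots, 4, total - 4)) / dt) * dt
    if (n_knots < 2 || min(diff(kt)) >= 4) break
  }
  repeat {
    sl <- stats::runif(n_knots + 1, -3, 3)
    if (n_knots == 0 || min(abs(diff(sl))) > 0.8) break
  }
  noise_seed <- seed + 7919L
  tr <- piecewise_trace(kt, sl, total = total, dt = dt, sigma = sigma,
                        seed = noise_seed)
  list(trace = tr, knots = kt, slopes = sl)
}

# Direct O(n^2) reference for the biased-autocorrelation sum used by the
# interval score (independent of the package's FFT implementation).
direct_abs_acf_sum <- function(e) {
  n <- length(e)
  c0 <- sum(e * e) / n
  if (c0 <= 0) return(0)
  s <- 0
  for (k in 1:(n - 1)) s <- s + abs(sum(e[1:(n - k)] * e[(1 + k):n]) / n)
  s / c0
}
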