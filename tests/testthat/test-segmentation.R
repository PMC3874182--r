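test_that("fit_line matches the closed-form least-squares solution", {
  t <- seq(0, 20, by = 0.2)
  # exact line
  tr <- smt_trace(t, 3 + 0.5 * t, rep(40, length(t)))
  fit <- fit_line(tr, 1, length(t))
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 3, tolerance = 1e-12)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-12)
  # symmetric V over its full span: zero net slope
  v <- abs(t - 10)
  trv <- smt_trace(t, v, rep(40, length(t)))
  expect_equal(fit_line(trv, 1, length(t))$slope, 0, tolerance = 1e-12)
  # random data against lm() as an independent oracle
  set.seed(31)
  y <- 5 + 1.3 * t + rnorm(length(t), 0, 4)
  trr <- smt_trace(t, y, rep(40, length(t)))
  fr <- fit_line(trr, 11, 81)
  ref <- lm(y[11:81] ~ t[11:81])
  expect_equal(fr$slope, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(fr$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(fr$slope_se, summary(ref)$coefficients[2, 2],
               tolerance = 1e-10)
  expect_error(fit_line(trr, 5, 5), "at least 2")
})

test_that("segment_score penalises structured residuals and scales linearly", {
  expect_equal(segment_score(rep(0, 50)), 0)
  expect_error(segment_score(c(1, 2)), "at least 3")
  set.seed(7)
  for (rep_i in 1:5) {
    e <- rnorm(120)
    e <- e - mean(e)
    # parabola with the same RMS as the white residuals
    x <- seq(-1, 1, length.out = 120)
    par_res <- (x^2 - mean(x^2))
    par_res <- par_res * sqrt(sum(e^2) / sum(par_res^2))
    for (norm in c("mean", "sum")) {
      expect_gt(segment_score(par_res, acf_norm = norm),
                segment_score(e, acf_norm = norm))
      # linear in residual scale
      expect_equal(segment_score(2 * e, acf_norm = norm),
                   2 * segment_score(e, acf_norm = norm), tolerance = 1e-9)
    }
    e <- rnorm(80)
  }
})

test_that("the FFT autocorrelation sum matches the direct definition", {
  set.seed(12)
  for (n in c(5, 17, 64, 301)) {
    e <- rnorm(n)
    e <- e - mean(e)
    ours <- segment_score(e, acf_norm = "sum") / (sum(abs(e)) / n)
    expect_equal(ours, direct_abs_acf_sum(e), tolerance = 1e-9)
  }
})

test_that("the literal sum-of-residuals score is degenerate for OLS residuals", {
  tr <- random_piecewise(0, sigma = 6, seed = 3)$trace
  fit <- fit_line(tr, 1, length(tr$time))
  expect_lt(segment_score(fit$residuals, method = "literal"), 1e-10)
  expect_gt(segment_score(fit$residuals, method = "robust"), 0)
})

test_that("score is invariant to vertical offset and time translation", {
  x <- random_piecewise(1, sigma = 5, seed = 6)
  tr <- x$trace
  score0 <- best_segment_from(tr, 1)$score
  tr_shift <- smt_trace(tr$time + 100, tr$extension + 5000, tr$force)
  expect_equal(best_segment_from(tr_shift, 1)$score, score0,
               tolerance = 1e-6)
})

test_that("best_segment_from finds knots and agrees with a naive scan", {
  p0 <- segmentation_params(settle = 0)
  # noiseless single line: full window, zero score (longest tie wins)
  tr <- piecewise_trace(numeric(0), 0.7, total = 20)
  seg <- best_segment_from(tr, 1, p0)
  expect_equal(seg$i_end, length(tr$time))
  expect_equal(seg$score, 0, tolerance = 1e-12)
  # two-slope trace, knot at 18 s, search from 4 s: end within one sample
  tr2 <- piecewise_trace(18, c(0, 0.5), total = 30)
  start <- which(tr2$time == 4)
  seg2 <- best_segment_from(tr2, start, p0)
  expect_lte(abs(seg2$t_end - 18), 0.2 + 1e-9)
  # naive per-end scan (lm + segment_score) agrees with the prefix-sum scan
  xn <- random_piecewise(1, sigma = 6, seed = 10)
  trn <- xn$trace
  nmin <- 11L
  naive <- function(start) {
    best <- NULL; bs <- Inf
    for (j in (start + nmin - 1L):length(trn$time)) {
      f <- fit_line(trn, start, j)
      sc <- segment_score(f$residuals)
      if (sc <= bs + max(1e-12, 1e-6 * bs)) { bs <- min(sc, bs); best <- j }
    }
    best
  }
  got <- best_segment_from(trn, 5, p0)
  expect_equal(got$i_end, naive(5))
  # pure white noise: slope consistent with zero
  trw <- piecewise_trace(numeric(0), 0, total = 30, sigma = 10, seed = 20)
  segw <- best_segment_from(trw, 1, p0)
  expect_lt(abs(segw$slope), 2 * segw$slope_se)
})

test_that("greedy segmentation recovers noiseless pieces and respects overlap", {
  p0 <- segmentation_params(settle = 0)
  tr <- piecewise_trace(c(10, 21), c(0, 2, -1), total = 32)
  res <- segment_trace(tr, p0)
  expect_equal(nrow(res$segments), 3)
  expect_equal(res$segments$t_end[1:2], c(10, 21), tolerance = 0.2 + 1e-9)
  expect_equal(res$segments$slope, c(0, 2, -1), tolerance = 0.05)
  # consecutive segments share at most `overlap` seconds
  ov <- res$segments$t_end[-3] - res$segments$t_start[-1]
  expect_true(all(ov <= 0.5 + 1e-9))
  # the window is covered: first/last segment bounds hit the window edges
  expect_equal(res$segments$t_start[1], res$windows$t0[1])
  expect_equal(res$segments$t_end[3], res$windows$t1[1])
})

test_that("segmentation covers the window with bounded gaps and logs skips", {
  x <- random_piecewise(2, sigma = 8, seed = 14, total = 40)
  p <- segmentation_params(settle = 0)
  res <- segment_trace(x$trace, p)
  segs <- res$segments
  expect_equal(segs$t_start[1], res$windows$t0[1])
  expect_equal(segs$t_end[nrow(segs)], res$windows$t1[1])
  if (nrow(segs) > 1) {
    gaps <- segs$t_start[-1] - segs$t_end[-nrow(segs)]
    expect_true(all(gaps <= p$skip_max + 1e-9))
  }
})

test_that("control traces segment to slopes indistinguishable from zero", {
  tr <- simulate_control_trace(standard_binding_protocol(56),
                               noise_model(sigma = 10), seed = 17)
  res <- segment_trace(tr)
  expect_gt(nrow(res$segments), 0)
  expect_true(all(abs(res$segments$slope) <= 2.5 * res$segments$slope_se))
})

test_that("analysis windows start `settle` seconds after each force change", {
  tr <- simulate_control_trace(standard_binding_protocol(56),
                               noise_model(sigma = 5), seed = 2)
  res <- segment_trace(tr)
  ph <- c(0, 120, 240)
  expect_equal(res$windows$t0, ph + 20, tolerance = 0.2 + 1e-9)
  # a window shorter than min_len yields an empty result with a warning
  short <- smt_trace(seq(0, 21, 0.2), rnorm(106, 100, 1), rep(40, 106))
  expect_warning(res2 <- segment_trace(short), "empty")
  expect_equal(nrow(res2$segments), 0)
})
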