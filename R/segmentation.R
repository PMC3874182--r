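#' Segmentation parameters
#'
#' Tuning constants of the greedy constant-growth interval finder: candidate
#' intervals last at least \code{min_len} seconds; short high-noise regions
#' (< \code{skip_max} s) between intervals may be skipped; successive
#' intervals may overlap by \code{overlap} s because transition positions are
#' uncertain; analysis windows begin \code{settle} s after each change in
#' force.
#'
#' @param min_len Minimum interval duration, s.
#' @param skip_max Maximum duration of a skippable high-noise region, s.
#' @param overlap Allowed overlap between successive intervals, s.
#' @param settle Dead time after each force change, s.
#' @param skip_zscore Robust z-score above which samples count as high noise.
#' @param score Interval score variant: \code{"robust"} uses the mean
#'   absolute residual; \code{"literal"} uses the absolute mean residual,
#'   which is degenerate (identically ~0) for least-squares fits with an
#'   intercept and is kept only for comparison.
#' @param per Normalisation of the residual magnitude term: per
#'   \code{"sample"} (divide by n) or per \code{"second"} (divide by
#'   duration).
#' @param acf_norm Normalisation of the residual-autocorrelation term:
#'   \code{"mean"} (mean of |rho_k| over positive lags, the default) or
#'   \code{"sum"}. With \code{"sum"}, white-noise scores grow like sqrt(n),
#'   which biases the minimiser towards the shortest admissible interval;
#'   the per-lag mean keeps white-noise scores decreasing with length while
#'   structured residuals stay O(1), so homogeneous stretches are fit by one
#'   long interval.
#' @return An object of class \code{segmentation_params}.
#' @export
segmentation_params <- function(min_len = 2, skip_max = 1, overlap = 0.5,
                                settle = 20, skip_zscore = 3,
                                score = c("robust", "literal"),
                                per = c("sample", "second"),
                                acf_norm = c("mean", "sum")) {
  score <- match.arg(score)
  per <- match.arg(per)
  acf_norm <- match.arg(acf_norm)
  stopifnot(min_len > 0, skip_max >= 0, overlap >= 0, overlap < min_len,
            settle >= 0, skip_zscore > 0)
  structure(list(min_len = min_len, skip_max = skip_max, overlap = overlap,
                 settle = settle, skip_zscore = skip_zscore,
                 score = score, per = per, acf_norm = acf_norm),
            class = "segmentation_params")
}

#' Ordinary least-squares line fit over a sample range
#'
#' @param trace An [smt_trace()].
#' @param i,j First and last sample index (inclusive), \code{j - i + 1 >= 2}.
#' @return A list with \code{slope} (nm/s), \code{intercept} (nm),
#'   \code{residuals} (nm), and \code{slope_se} (nm/s; NA for 2-point fits).
#' @export
fit_line <- function(trace, i, j) {
  if (j - i + 1 < 2) stop("need at least 2 samples")
  t <- trace$time[i:j]; y <- trace$extension[i:j]
  if (max(t) - min(t) <= 0) stop("degenerate time range")
  n <- length(t)
  tm <- mean(t); ym <- mean(y)
  sxx <- sum((t - tm)^2)
  slope <- sum((t - tm) * (y - ym)) / sxx
  intercept <- ym - slope * tm
  e <- y - intercept - slope * t
  se <- if (n > 2) sqrt(sum(e^2) / (n - 2) / sxx) else NA_real_
  list(slope = slope, intercept = intercept, residuals = e, slope_se = se)
}

# Sum over positive lags of |biased sample autocorrelation| of e, via FFT.
# rho_k = c_k / c_0 with c_k = (1/n) sum_i e_i e_{i+k}.
abs_acf_sum <- function(e) {
  n <- length(e)
  m <- stats::nextn(2L * n, 2)
  f <- stats::fft(c(e, rep(0, m - n)))
  ac <- Re(stats::fft(Mod(f)^2, inverse = TRUE)) / m
  c0 <- ac[1]
  if (c0 <= 0) return(0)
  sum(abs(ac[2:n])) / c0
}

#' Interval score: residual magnitude times residual autocorrelation
#'
#' The score of a fitted interval is the magnitude of its residuals per unit
#' length multiplied by the summed absolute autocorrelation of the residual
#' sequence, so large and *structured* residuals (curvature, missed
#' breakpoints) are penalised while white residuals score low. Zero if and
#' only if all residuals are zero. Linear in the residual scale:
#' \code{segment_score(2 * e) == 2 * segment_score(e)}.
#'
#' @param residuals Residual vector in nm, length >= 3.
#' @param method \code{"robust"} (mean absolute residual) or
#'   \code{"literal"} (absolute mean residual; degenerate for OLS fits with
#'   intercept).
#' @param per Normalise by \code{"sample"} count or interval duration in
#'   \code{"second"}s.
#' @param acf_norm \code{"mean"} (per-lag mean of |rho_k|, default) or
#'   \code{"sum"}; see [segmentation_params()].
#' @param dt Sampling interval (needed for \code{per = "second"}).
#' @return Non-negative score (nm).
#' @export
segment_score <- function(residuals, method = c("robust", "literal"),
                          per = c("sample", "second"),
                          acf_norm = c("mean", "sum"), dt = NULL) {
  method <- match.arg(method)
  per <- match.arg(per)
  acf_norm <- match.arg(acf_norm)
  n <- length(residuals)
  if (n < 3) stop("need at least 3 residuals")
  denom <- if (per == "sample") n else {
    if (is.null(dt)) stop("'dt' required for per-second normalisation")
    n * dt
  }
  mag <- if (method == "robust") sum(abs(residuals)) / denom
         else abs(sum(residuals)) / denom
  if (mag == 0) return(0)
  acf_term <- abs_acf_sum(residuals)
  if (acf_norm == "mean") acf_term <- acf_term / (n - 1)
  mag * acf_term
}

# Minimum samples per segment given params and dt: duration >= min_len and
# at least 3 samples for the autocorrelation.
min_samples <- function(params, dt) {
  max(3L, as.integer(ceiling(params$min_len / dt - 1e-9)) + 1L)
}

# Score an interval of a trace (internal; used by greedy and DP).
interval_fit_score <- function(trace, i, j, params) {
  fit <- fit_line(trace, i, j)
  score <- segment_score(fit$residuals, method = params$score,
                         per = params$per, acf_norm = params$acf_norm,
                         dt = trace$dt)
  list(fit = fit, score = score)
}

#' Best constant-growth interval starting at a sample
#'
#' Performs least-squares fits on all subintervals beginning at \code{start}
#' and lasting at least \code{min_len} seconds, up to \code{end}, and returns
#' the interval with the minimum score; ties (within a small numerical
#' tolerance) are broken in favour of the longest interval.
#'
#' @param trace An [smt_trace()].
#' @param start First sample index of the candidate intervals.
#' @param params A [segmentation_params()].
#' @param end Last admissible sample index (default: end of trace).
#' @return A one-row data.frame (a segment): \code{t_start}, \code{t_end},
#'   \code{i_start}, \code{i_end}, \code{slope}, \code{intercept},
#'   \code{score}, \code{n_samples}, \code{slope_se}.
#' @export
best_segment_from <- function(trace, start, params = segmentation_params(),
                              end = length(trace$time)) {
  dt <- trace$dt
  nmin <- min_samples(params, dt)
  j_min <- start + nmin - 1L
  if (j_min > end) stop("insufficient data after 'start'")
  t <- trace$time; y <- trace$extension
  # prefix sums from 'start' for O(1) OLS coefficients at every end
  ts <- t[start:end]; ys <- y[start:end]
  cx <- cumsum(ts); cy <- cumsum(ys)
  cxx <- cumsum(ts * ts); cxy <- cumsum(ts * ys)
  best <- NULL; best_score <- Inf
  for (j in j_min:end) {
    m <- j - start + 1L
    sx <- cx[m]; sy <- cy[m]; sxx <- cxx[m]; sxy <- cxy[m]
    den <- m * sxx - sx * sx
    slope <- (m * sxy - sx * sy) / den
    intercept <- (sy - slope * sx) / m
    e <- ys[1:m] - intercept - slope * ts[1:m]
    sc <- segment_score(e, method = params$score, per = params$per,
                        acf_norm = params$acf_norm, dt = dt)
    tie <- best_score + max(1e-12, 1e-6 * best_score)
    if (sc <= tie) {  # strictly better, or tie -> longer wins
      best_score <- min(sc, best_score)
      sxx_c <- sxx - sx * sx / m
      se <- if (m > 2) sqrt(sum(e^2) / (m - 2) / sxx_c) else NA_real_
      best <- data.frame(t_start = t[start], t_end = t[j],
                         i_start = start, i_end = j,
                         slope = slope, intercept = intercept,
                         score = sc, n_samples = m, slope_se = se)
    }
  }
  best
}

empty_segments <- function() {
  data.frame(t_start = numeric(0), t_end = numeric(0),
             i_start = integer(0), i_end = integer(0),
             slope = numeric(0), intercept = numeric(0),
             score = numeric(0), n_samples = integer(0),
             slope_se = numeric(0))
}

# Greedy segmentation of one index window [s0, E].
greedy_window <- function(trace, s0, E, params) {
  dt <- trace$dt
  nmin <- min_samples(params, dt)
  # shared samples between successive intervals; overlap = 0 gives a
  # disjoint partition of the window
  ov <- as.integer(floor(params$overlap / dt + 1e-9))
  skip_n <- as.integer(round(params$skip_max / dt))
  segs <- empty_segments()
  skipped <- data.frame(t_start = numeric(0), t_end = numeric(0))
  start <- s0
  while (E - start + 1L >= nmin) {
    seg <- best_segment_from(trace, start, params, end = E)
    if (E - seg$i_end < nmin) {
      # tail too short for another interval: exhaust the curve
      if (seg$i_end < E) {
        fit <- interval_fit_score(trace, seg$i_start, E, params)
        m <- E - seg$i_start + 1L
        seg <- data.frame(t_start = trace$time[seg$i_start],
                          t_end = trace$time[E],
                          i_start = seg$i_start, i_end = E,
                          slope = fit$fit$slope, intercept = fit$fit$intercept,
                          score = fit$score, n_samples = m,
                          slope_se = fit$fit$slope_se)
      }
      segs <- rbind(segs, seg)
      break
    }
    segs <- rbind(segs, seg)
    # skip a short run of high-noise samples following the interval, judged
    # against the interval's own fit (robust sigma from its residuals)
    fit <- fit_line(trace, seg$i_start, seg$i_end)
    sigma_hat <- stats::mad(fit$residuals)
    nxt <- seg$i_end + 1L - ov
    if (skip_n > 0 && sigma_hat > 0) {
      look <- seq.int(seg$i_end + 1L, min(seg$i_end + skip_n, E))
      pred <- seg$intercept + seg$slope * trace$time[look]
      z <- abs(trace$extension[look] - pred) / sigma_hat
      bad <- z > params$skip_zscore
      run <- 0L
      for (b in bad) { if (b) run <- run + 1L else break }
      if (run > 0L && run < skip_n) {
        skipped <- rbind(skipped, data.frame(
          t_start = trace$time[seg$i_end + 1L],
          t_end = trace$time[seg$i_end + run]))
        nxt <- seg$i_end + run + 1L
      }
    }
    start <- max(nxt, start + 1L)
  }
  list(segments = segs, skipped = skipped)
}

#' Segment a trace into constant-growth intervals
#'
#' Greedy segmentation: within each analysis window, the best-scoring
#' interval from the current start is accepted, then the search restarts
#' \code{overlap} seconds before its end, proceeding iteratively until the
#' window is exhausted. Short high-noise runs (< \code{skip_max} s) at
#' interval transitions are skipped and logged. By default each
#' constant-force phase long enough to hold \code{settle + min_len} seconds
#' contributes one window starting \code{settle} s after the force change.
#'
#' @param trace An [smt_trace()].
#' @param params A [segmentation_params()].
#' @param window Optional numeric \code{c(t0, t1)} to analyse a single
#'   explicit time window instead of auto-detected force phases.
#' @return An object of class \code{smt_segmentation}: list with
#'   \code{segments} (data.frame), \code{skipped} (data.frame), and
#'   \code{windows} (data.frame of analysed windows with their phase force).
#' @export
segment_trace <- function(trace, params = segmentation_params(),
                          window = NULL) {
  dt <- trace$dt
  nmin <- min_samples(params, dt)
  wins <- list()
  if (!is.null(window)) {
    s0 <- which(trace$time >= window[1] - 1e-9)[1]
    E <- max(which(trace$time <= window[2] + 1e-9))
    f <- stats::median(trace$force[s0:E])
    wins[[1]] <- list(s0 = s0, E = E, force = f)
  } else {
    ph <- trace_phases(trace)
    for (p in seq_len(nrow(ph))) {
      s0 <- ph$start[p] + as.integer(round(params$settle / dt))
      E <- ph$end[p]
      if (E - s0 + 1L >= nmin)
        wins[[length(wins) + 1]] <- list(s0 = s0, E = E, force = ph$force[p])
    }
  }
  segs <- empty_segments(); skipped <- data.frame(t_start = numeric(0),
                                                  t_end = numeric(0))
  wtab <- data.frame(t0 = numeric(0), t1 = numeric(0), force = numeric(0))
  if (length(wins) == 0) {
    warning("no analysis window of at least min_len; empty result")
  }
  for (w in wins) {
    res <- greedy_window(trace, w$s0, w$E, params)
    if (nrow(res$segments)) {
      res$segments$window_force <- w$force
      segs <- rbind(segs, res$segments)
    }
    skipped <- rbind(skipped, res$skipped)
    wtab <- rbind(wtab, data.frame(t0 = trace$time[w$s0],
                                   t1 = trace$time[w$E], force = w$force))
  }
  structure(list(segments = segs, skipped = skipped, windows = wtab,
                 params = params),
            class = "smt_segmentation")
}

#' @export
print.smt_segmentation <- function(x, ...) {
  cat(sprintf("segmentation: %d segment(s) over %d window(s), %d skipped region(s)\n",
              nrow(x$segments), nrow(x$windows), nrow(x$skipped)))
  if (nrow(x$segments)) {
    df <- x$segments[, c("t_start", "t_end", "slope", "score", "slope_se")]
    print(format(df, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' Total score of a segmentation
#' @param x An \code{smt_segmentation} or the result of [dp_segment()].
#' @export
total_score <- function(x) sum(x$segments$score)
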