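#' Exact dynamic-programming segmentation (test oracle)
#'
#' Globally minimises the total interval score over all partitions of the
#' analysis window into at most \code{max_segments} non-overlapping intervals
#' of duration >= \code{min_len}, by dynamic programming over O(n^2) interval
#' scores. Among optima, the partition with the fewest segments wins, so on
#' noiseless piecewise-linear input the true breakpoints are recovered
#' exactly. Intended as a ground-truth oracle for validating the greedy
#' segmentation on short traces, not as a user-facing mode.
#'
#' @param trace An [smt_trace()].
#' @param params A [segmentation_params()]; \code{overlap}, \code{skip_max}
#'   and \code{settle} are ignored (partitions are exact and windows
#'   explicit).
#' @param max_segments Maximum number of segments considered.
#' @param window Numeric \code{c(t0, t1)} analysis window; default is the
#'   whole trace.
#' @return A list with \code{segments} (data.frame as in [segment_trace()]),
#'   \code{total} (minimum total score) and \code{n_segments}.
#' @export
dp_segment <- function(trace, params = segmentation_params(),
                       max_segments = 5, window = NULL) {
  if (is.null(window)) window <- range(trace$time)
  s0 <- which(trace$time >= window[1] - 1e-9)[1]
  E <- max(which(trace$time <= window[2] + 1e-9))
  n <- E - s0 + 1L
  if (n > 2000) stop("dp_segment is an O(n^2) test oracle; n must be <= 2000")
  dt <- trace$dt
  nmin <- min_samples(params, dt)
  if (n < nmin) stop("window shorter than min_len")
  t <- trace$time[s0:E]; y <- trace$extension[s0:E]

  # cost[i, j]: score of interval i..j (local indices), Inf if too short
  cost <- matrix(Inf, n, n)
  for (i in seq_len(n - nmin + 1L)) {
    ts <- t[i:n]; ys <- y[i:n]
    cx <- cumsum(ts); cy <- cumsum(ys)
    cxx <- cumsum(ts * ts); cxy <- cumsum(ts * ys)
    for (j in (i + nmin - 1L):n) {
      m <- j - i + 1L
      sx <- cx[m]; sy <- cy[m]; sxx <- cxx[m]; sxy <- cxy[m]
      den <- m * sxx - sx * sx
      slope <- (m * sxy - sx * sy) / den
      intercept <- (sy - slope * sx) / m
      e <- ys[1:(m)] - intercept - slope * ts[1:(m)]
      cost[i, j] <- segment_score(e, method = params$score,
                                  per = params$per,
                                  acf_norm = params$acf_norm, dt = dt)
    }
  }

  K <- max_segments
  D <- matrix(Inf, K, n)       # D[k, j]: best total for prefix 1..j with k segments
  P <- matrix(NA_integer_, K, n)  # split: start index of the k-th segment
  D[1, ] <- cost[1, ]
  P[1, ] <- 1L
  if (K >= 2) {
    for (k in 2:K) {
      for (j in seq.int(k * nmin, n)) {
        istarts <- seq.int((k - 1L) * nmin + 1L, j - nmin + 1L)
        tot <- D[k - 1L, istarts - 1L] + cost[istarts, j]
        b <- which.min(tot)
        D[k, j] <- tot[b]
        P[k, j] <- istarts[b]
      }
    }
  }
  totals <- D[, n]
  best_total <- min(totals)
  k_star <- which(totals <= best_total + max(1e-12, 1e-6 * best_total))[1]

  # reconstruct
  bounds <- integer(0)
  j <- n
  for (k in seq.int(k_star, 1L)) {
    i <- P[k, j]
    bounds <- c(i, bounds)
    j <- i - 1L
  }
  segs <- empty_segments()
  ends <- c(bounds[-1] - 1L, n)
  for (s in seq_along(bounds)) {
    i <- bounds[s]; jj <- ends[s]
    fit <- fit_line(trace, s0 + i - 1L, s0 + jj - 1L)
    sc <- segment_score(fit$residuals, method = params$score,
                        per = params$per, acf_norm = params$acf_norm,
                        dt = dt)
    segs <- rbind(segs, data.frame(
      t_start = t[i], t_end = t[jj],
      i_start = s0 + i - 1L, i_end = s0 + jj - 1L,
      slope = fit$slope, intercept = fit$intercept, score = sc,
      n_samples = jj - i + 1L, slope_se = fit$slope_se))
  }
  list(segments = segs, total = sum(segs$score), n_segments = k_star)
}
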