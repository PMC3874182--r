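#' Naked-DNA baseline extension for the high-force phase
#'
#' The baseline against which binding-induced extension gain is measured:
#' mean measured extension over the last \code{tail} seconds of the 40 pN
#' phase preceding the force step, corrected for the elastic extension
#' difference between the two forces via the mechanics model. With
#' \code{elastic_correction = FALSE} the raw pre-step mean is used.
#'
#' @param trace An [smt_trace()] with a phase protocol (base force, test
#'   force, ...).
#' @param params A [mechanics_params()].
#' @param tail Averaging window at the end of the pre-step phase, s.
#' @param elastic_correction Apply the model correction between the base and
#'   test forces.
#' @return Baseline extension at the test force, nm.
#' @export
binding_baseline <- function(trace, params = mechanics_params(), tail = 20,
                             elastic_correction = TRUE) {
  ph <- trace_phases(trace)
  p <- which.max(ph$force)[1]
  if (p == 1) {
    # no pre-step phase recorded: fall back to the model baseline
    return(force_extension(ph$force[p], trace$construct_bp, params))
  }
  pre <- p - 1L
  t_end <- trace$time[ph$end[pre]]
  idx <- seq.int(ph$start[pre], ph$end[pre])
  idx <- idx[trace$time[idx] >= t_end - tail]
  base <- mean(trace$extension[idx])
  if (elastic_correction) {
    base <- base + force_extension(ph$force[p], trace$construct_bp, params) -
      force_extension(ph$force[pre], trace$construct_bp, params)
  }
  base
}

#' Binding-induced extension gain over a measurement window
#'
#' \eqn{\Delta L} is the mean extension over a window late in the constant
#' high-force phase (default 105--120 s after the force step) minus the
#' naked-DNA baseline from [binding_baseline()].
#'
#' @param trace An [smt_trace()].
#' @param window Window in seconds *relative to the force step* (start of
#'   the highest-force phase).
#' @param params A [mechanics_params()].
#' @param elastic_correction Passed to [binding_baseline()].
#' @param baseline Optional explicit baseline (nm), overriding
#'   [binding_baseline()].
#' @return A list of class \code{extension_summary}: \code{delta_L} (nm),
#'   \code{window} (absolute s), \code{force} (pN), \code{mode}.
#' @export
delta_extension <- function(trace, window = c(105, 120),
                            params = mechanics_params(),
                            elastic_correction = TRUE,
                            baseline = NULL) {
  ph <- trace_phases(trace)
  p <- which.max(ph$force)[1]
  t_step <- trace$time[ph$start[p]]
  t_phase_end <- trace$time[ph$end[p]]
  w <- t_step + window
  if (w[1] < t_step - 1e-9 || w[2] > t_phase_end + trace$dt + 1e-9)
    stop("measurement window lies outside the high-force phase")
  if (is.null(baseline))
    baseline <- binding_baseline(trace, params,
                                 elastic_correction = elastic_correction)
  idx <- which(trace$time >= w[1] - 1e-9 & trace$time <= w[2] + 1e-9)
  idx <- idx[idx >= ph$start[p] & idx <= ph$end[p]]
  structure(list(delta_L = mean(trace$extension[idx]) - baseline,
                 window = w, force = ph$force[p],
                 mode = trace$meta$mode %||% NA_character_),
            class = "extension_summary")
}

#' Pause levels from a segmentation
#'
#' Segments whose slope is indistinguishable from zero become pause levels:
#' plateaus in the extension trace at which filament binding has completed an
#' integer number of full filament lengths. The level is the mean extension
#' over the segment minus the baseline.
#'
#' @param segmentation An \code{smt_segmentation} from [segment_trace()].
#' @param trace The segmented [smt_trace()].
#' @param baseline Baseline extension in nm (see [binding_baseline()]).
#' @param slope_threshold Max |slope| (nm/s) to call a plateau; default per
#'   segment is \code{max(0.02, 2 * slope_se)}.
#' @param min_level Minimum level above baseline (nm) to report; plateaus at
#'   the naked-DNA baseline itself (no binding yet) are not pauses. Default
#'   20 nm, twice the tracking accuracy.
#' @param all_windows Consider segments from every analysis window; by
#'   default only the highest-force window (where binding occurs) is used.
#' @return A data.frame with columns \code{level} (nm above baseline),
#'   \code{duration} (s), \code{slope} (nm/s); zero rows if no plateau.
#' @export
detect_pauses <- function(segmentation, trace, baseline = NULL,
                          slope_threshold = NULL, min_level = 20,
                          all_windows = FALSE) {
  segs <- segmentation$segments
  if (!all_windows && nrow(segs) && !is.null(segs$window_force))
    segs <- segs[segs$window_force >= max(segs$window_force) - 1e-9, ,
                 drop = FALSE]
  if (is.null(baseline)) baseline <- binding_baseline(trace)
  out <- data.frame(level = numeric(0), duration = numeric(0),
                    slope = numeric(0))
  for (s in seq_len(nrow(segs))) {
    thr <- if (is.null(slope_threshold))
      max(0.02, 2 * segs$slope_se[s]) else slope_threshold
    if (is.finite(segs$slope[s]) && abs(segs$slope[s]) <= thr) {
      idx <- seq.int(segs$i_start[s], segs$i_end[s])
      level <- mean(trace$extension[idx]) - baseline
      if (level >= min_level)
        out <- rbind(out, data.frame(
          level = level,
          duration = segs$t_end[s] - segs$t_start[s],
          slope = segs$slope[s]))
    }
  }
  out
}

#' Duration-weighted pause-level histogram with peak finding
#'
#' Pools pause levels across a cohort into a duration-weighted histogram and
#' locates its peaks (local maxima above a prominence floor). Peak centres
#' are refined as the duration-weighted mean of the levels within one bin of
#' the peak bin.
#'
#' @param pauses data.frame with \code{level} and \code{duration} columns
#'   (rbind of [detect_pauses()] results).
#' @param bin_width Histogram bin width, nm (default 10, the tracking
#'   accuracy).
#' @param prominence Fraction of the maximum bin weight below which local
#'   maxima are ignored.
#' @return A list of class \code{pause_histogram}: \code{mids},
#'   \code{weights}, \code{peaks} (refined peak centres, nm),
#'   \code{bin_width}.
#' @export
pause_histogram <- function(pauses, bin_width = 10, prominence = 0.2) {
  if (nrow(pauses) < 1) stop("need at least one pause")
  lv <- pauses$level; wt <- pauses$duration
  lo <- floor(min(lv) / bin_width) * bin_width - bin_width
  hi <- ceiling(max(lv) / bin_width) * bin_width + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  bin <- findInterval(lv, breaks, rightmost.closed = TRUE)
  w <- vapply(seq_len(length(breaks) - 1),
              function(b) sum(wt[bin == b]), numeric(1))
  mids <- breaks[-length(breaks)] + bin_width / 2
  floor_w <- prominence * max(w)
  nb <- length(w)
  peaks <- numeric(0)
  for (b in seq_len(nb)) {
    left <- if (b > 1) w[b - 1] else 0
    right <- if (b < nb) w[b + 1] else 0
    if (w[b] >= floor_w && w[b] > left && w[b] >= right) {
      near <- abs(lv - mids[b]) <= bin_width
      peaks <- c(peaks, stats::weighted.mean(lv[near], wt[near]))
    }
  }
  structure(list(mids = mids, weights = w, peaks = peaks,
                 bin_width = bin_width),
            class = "pause_histogram")
}

#' @export
print.pause_histogram <- function(x, ...) {
  cat(sprintf("pause histogram: %d bins of %g nm, peaks at %s nm\n",
              length(x$mids), x$bin_width,
              paste(sprintf("%.1f", x$peaks), collapse = ", ")))
  invisible(x)
}

#' Extension per nucleotide from pause-histogram peaks
#'
#' Pause peaks sit at integer multiples of the full filament extension, so
#' the extension per nucleotide is the ratio of each peak level to (multiple
#' x filament length). Peaks are assigned to integer multiples of the modal
#' peak spacing; assignments whose implied spacing deviates by more than
#' \code{ratio_tol} are dropped.
#'
#' @param peak_levels Peak centres in nm (from [pause_histogram()]).
#' @param filament_nt Filament length in nucleotides.
#' @param ratio_tol Relative tolerance for multiple assignment.
#' @return A list of class \code{ext_per_nt_estimate}: \code{value} (nm/nt),
#'   \code{sd}, \code{n_pauses} (peaks used), \code{assignment} data.frame.
#' @export
ext_per_nt <- function(peak_levels, filament_nt, ratio_tol = 0.25) {
  peaks <- sort(peak_levels[peak_levels > 0])
  if (length(peaks) == 0) stop("no assignable peaks")
  gaps <- diff(c(0, peaks))
  spacing <- min(gaps[gaps > 0])
  k <- pmax(1L, as.integer(round(peaks / spacing)))
  err <- abs(peaks / k - spacing) / spacing
  keep <- err <= ratio_tol
  if (!any(keep)) stop("no assignable peaks (ambiguous multiples)")
  vals <- peaks[keep] / (k[keep] * filament_nt)
  structure(list(value = mean(vals),
                 sd = if (length(vals) > 1) stats::sd(vals) else 0,
                 n_pauses = length(vals),
                 assignment = data.frame(level = peaks[keep], k = k[keep],
                                         value = vals)),
            class = "ext_per_nt_estimate")
}

#' @export
print.ext_per_nt_estimate <- function(x, ...) {
  cat(sprintf("extension/nt: %.3f +/- %.3f nm/nt from %d peak(s)\n",
              x$value, x$sd, x$n_pauses))
  invisible(x)
}

#' Pool extension-per-nt estimates across filament lengths
#'
#' Weighted mean of per-length estimates (weights: number of peaks used),
#' with the pooled sd combining within- and between-length spread.
#'
#' @param estimates List of \code{ext_per_nt_estimate} objects.
#' @return An \code{ext_per_nt_estimate}.
#' @export
pool_ext_per_nt <- function(estimates) {
  vals <- vapply(estimates, function(e) e$value, numeric(1))
  ws <- vapply(estimates, function(e) e$n_pauses, numeric(1))
  v <- stats::weighted.mean(vals, ws)
  s <- if (length(vals) > 1) sqrt(stats::weighted.mean((vals - v)^2, ws))
       else estimates[[1]]$sd
  structure(list(value = v, sd = s, n_pauses = sum(ws),
                 per_length = vals),
            class = "ext_per_nt_estimate")
}

#' Implied filament coverage of the ssDNA
#'
#' If a reduced extension per nucleotide were entirely due to incomplete
#' ssDNA coverage by the recombinase, the coverage fraction would be the
#' ratio of the measured extension/nt to the fully covered reference
#' (RecA-like filaments: 0.17 nm/nt).
#'
#' @param est An \code{ext_per_nt_estimate} or a numeric value in nm/nt.
#' @param reference_ext Fully covered reference extension, nm/nt.
#' @return A list of class \code{coverage_estimate}: \code{fraction} (in
#'   (0, 1]; values above 1 are clipped), \code{raw_ratio},
#'   \code{reference_ext}.
#' @export
coverage_fraction <- function(est, reference_ext = 0.17) {
  value <- if (inherits(est, "ext_per_nt_estimate")) est$value else est
  if (!is.numeric(value) || value <= 0 || reference_ext <= 0)
    stop("extension/nt and reference must be positive")
  ratio <- value / reference_ext
  structure(list(fraction = min(ratio, 1), raw_ratio = ratio,
                 reference_ext = reference_ext),
            class = "coverage_estimate")
}

#' @export
print.coverage_estimate <- function(x, ...) {
  cat(sprintf("implied coverage: %.1f%% (vs %.2f nm/nt reference)\n",
              100 * x$fraction, x$reference_ext))
  invisible(x)
}

#' Cohort summary table of extension gains
#'
#' Groups \eqn{\Delta L} summaries by pulling mode and force bin and reports
#' mean, standard deviation and count per cell.
#'
#' @param summaries List of \code{extension_summary} objects (or a
#'   data.frame with \code{delta_L}, \code{force}, \code{mode}).
#' @param force_bins Breaks in pN for grouping (passed to [cut()]).
#' @return data.frame with \code{mode}, \code{force_bin}, \code{n},
#'   \code{mean_delta_L}, \code{sd_delta_L} (NA when n = 1).
#' @export
cohort_summary <- function(summaries, force_bins = c(35, 50, 54, 56, 58, 60)) {
  df <- if (is.data.frame(summaries)) summaries else
    do.call(rbind, lapply(summaries, function(s)
      data.frame(delta_L = s$delta_L, force = s$force,
                 mode = as.character(s$mode))))
  if (nrow(df) == 0) stop("no summaries")
  df$force_bin <- cut(df$force, breaks = force_bins, include.lowest = TRUE)
  groups <- split(df, list(df$mode, df$force_bin), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g)
    data.frame(mode = g$mode[1], force_bin = as.character(g$force_bin[1]),
               n = nrow(g), mean_delta_L = mean(g$delta_L),
               sd_delta_L = if (nrow(g) > 1) stats::sd(g$delta_L) else NA_real_)))
  rownames(out) <- NULL
  out[order(out$mode, out$force_bin), ]
}
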