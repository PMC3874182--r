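#' Locate the overstretching transition in a force-ramp trace
#'
#' Fits a logistic force-extension model
#' \eqn{E(F) = L_0 (1 + cF) + A / (1 + \exp(-(F - F_0)/s))} to extension
#' versus nominal force and returns the transition midpoint \eqn{F_0} and the
#' 10--90\% transition width \eqn{2 s \ln 9}. Used to calibrate the
#' per-bead force scale against the 65 pN overstretching standard.
#'
#' @param ramp An [smt_trace()] spanning the transition (extension must rise
#'   well above the B-form plateau within the ramp).
#' @return A list with \code{transition_force} (pN, nominal),
#'   \code{width} (pN), and the fitted \code{model}.
#' @export
detect_overstretch <- function(ramp) {
  f <- ramp$force; e <- ramp$extension
  ord <- order(f)
  f <- f[ord]; e <- e[ord]
  lo <- stats::median(e[f <= stats::quantile(f, 0.1)])
  hi <- stats::median(e[f >= stats::quantile(f, 0.95)])
  if (!is.finite(lo) || !is.finite(hi) || hi < 1.3 * lo)
    stop("no overstretching transition within the ramp")
  # starting values: midpoint where extension crosses halfway
  half <- (lo + hi) / 2
  f0_start <- f[which.min(abs(e - half))]
  df <- data.frame(f = f, e = e)
  fit <- minpack.lm::nlsLM(
    e ~ L0 * (1 + cc * f) + A / (1 + exp(-(f - F0) / sc)),
    data = df,
    start = list(L0 = lo, cc = 3e-4, A = hi - lo, F0 = f0_start, sc = 0.5),
    lower = c(L0 = 0, cc = 0, A = 0, F0 = min(f), sc = 1e-3),
    upper = c(L0 = Inf, cc = 0.01, A = Inf, F0 = max(f), sc = 20),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  if (cf[["F0"]] >= max(f) - 1e-6 || cf[["F0"]] <= min(f) + 1e-6)
    stop("no overstretching transition within the ramp")
  list(transition_force = unname(cf[["F0"]]),
       width = unname(2 * log(9) * cf[["sc"]]),
       model = fit)
}

#' Per-bead force scale from the overstretching standard
#'
#' Beads vary in magnetization, so the true force differs from the nominal
#' force by a per-bead factor. The factor is the ratio of the overstretching
#' standard (65 pN) to the nominal transition force observed for that bead.
#'
#' @param transition_force_nominal Nominal transition midpoint, pN.
#' @param standard Overstretching standard, pN.
#' @return Dimensionless scale: multiply nominal forces by it to calibrate.
#' @export
bead_scale <- function(transition_force_nominal, standard = 65) {
  if (transition_force_nominal <= 0 || standard <= 0)
    stop("forces must be positive")
  standard / transition_force_nominal
}

#' Apply a force calibration to a trace
#'
#' Multiplies the force column by \code{scale}; extension is untouched. The
#' applied scale is recorded in the trace metadata.
#'
#' @param trace An [smt_trace()].
#' @param scale Calibration factor (> 0), from [bead_scale()].
#' @return The calibrated [smt_trace()].
#' @export
apply_calibration <- function(trace, scale) {
  if (scale <= 0) stop("'scale' must be > 0")
  meta <- trace$meta
  meta$calibration_scale <- (meta$calibration_scale %||% 1) * scale
  smt_trace(trace$time, trace$extension, trace$force * scale,
            construct_bp = trace$construct_bp, meta = meta)
}

#' Calibrate a bead from its overstretching ramp
#'
#' Convenience wrapper: [detect_overstretch()] then [bead_scale()].
#'
#' @param ramp An [smt_trace()] force ramp.
#' @param standard Overstretching standard, pN.
#' @return A list of class \code{calibration_result}:
#'   \code{transition_force_nominal}, \code{bead_scale},
#'   \code{residual_width} (pN).
#' @export
calibrate_bead <- function(ramp, standard = 65) {
  det <- detect_overstretch(ramp)
  structure(list(transition_force_nominal = det$transition_force,
                 bead_scale = bead_scale(det$transition_force, standard),
                 residual_width = det$width),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration: nominal transition %.2f pN, width %.2f pN, bead scale %.4f\n",
              x$transition_force_nominal, x$residual_width, x$bead_scale))
  invisible(x)
}
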