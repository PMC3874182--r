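#' dsDNA mechanics parameters
#'
#' Phenomenological force-extension constants for torsionally unconstrained
#' dsDNA. The model is anchored at three features that matter for trace
#' analysis: the B-form contour length below the overstretching transition, a
#' cooperative overstretching transition centred at \code{overstretch_force},
#' and a plateau at \code{overstretch_factor} times the B-form length above it.
#'
#' @param bform_rise Helical rise per base pair in nm (B-form contour).
#' @param overstretch_force Centre of the overstretching transition, pN.
#' @param overstretch_width 10--90\% force width of the transition, pN. The
#'   underlying logistic scale is \code{overstretch_width / (2 * log(9))}.
#' @param overstretch_factor Relative extension of the overstretched state
#'   (fold change over B-form contour).
#' @param low_force_compliance Relative extension gained per pN below the
#'   transition (linearised enthalpic stretching), 1/pN.
#' @return An object of class \code{mechanics_params}.
#' @examples
#' p <- mechanics_params()
#' force_extension(40, 48502, p)
#' @export
mechanics_params <- function(bform_rise = 0.34,
                             overstretch_force = 65,
                             overstretch_width = 2,
                             overstretch_factor = 1.7,
                             low_force_compliance = 3e-4) {
  stopifnot(bform_rise > 0,
            overstretch_force >= 0, overstretch_force <= 200,
            overstretch_width > 0,
            overstretch_factor > 1,
            low_force_compliance >= 0)
  structure(list(bform_rise = bform_rise,
                 overstretch_force = overstretch_force,
                 overstretch_width = overstretch_width,
                 overstretch_factor = overstretch_factor,
                 low_force_compliance = low_force_compliance),
            class = "mechanics_params")
}

#' @export
print.mechanics_params <- function(x, ...) {
  cat("dsDNA mechanics: rise", x$bform_rise, "nm/bp;",
      "overstretch", x$overstretch_force, "pN (width",
      x$overstretch_width, "pN, factor", x$overstretch_factor, "x);",
      "compliance", x$low_force_compliance, "/pN\n")
  invisible(x)
}

# Logistic occupancy of the overstretched state; 0.5 exactly at the
# transition centre, 0.1/0.9 at centre -/+ width/2.
overstretch_sigmoid <- function(force, params) {
  scale <- params$overstretch_width / (2 * log(9))
  stats::plogis((force - params$overstretch_force) / scale)
}

#' Model dsDNA extension at a given force
#'
#' Extension of an \code{n_bp} base-pair dsDNA tether at force \code{force}:
#' B-form contour times \code{1 + c*F + (f - 1) * S(F)} where \code{c} is the
#' low-force compliance, \code{f} the overstretch factor and \code{S} a
#' logistic sigmoid centred at the overstretching force. Monotone
#' non-decreasing in force.
#'
#' @param force Applied force in pN (scalar or vector), must be >= 0.
#' @param n_bp Number of base pairs (> 0).
#' @param params A [mechanics_params()] object.
#' @return Extension in nm, same length as \code{force}.
#' @export
force_extension <- function(force, n_bp, params = mechanics_params()) {
  if (any(!is.finite(force)) || any(force < 0))
    stop("'force' must be finite and non-negative")
  if (length(n_bp) != 1L || !is.finite(n_bp) || n_bp <= 0)
    stop("'n_bp' must be a single positive number")
  contour <- n_bp * params$bform_rise
  contour * (1 + params$low_force_compliance * force +
               (params$overstretch_factor - 1) * overstretch_sigmoid(force, params))
}
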