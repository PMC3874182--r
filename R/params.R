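#' ssDNA filament description
#'
#' @param length_nt Filament length in nucleotides (typical experimental
#'   values: 400, 700, 1000, 1600).
#' @param homologous Whether the filament is homologous to the tethered dsDNA.
#' @param ext_per_nt Extension added to the tether per nucleotide of bound
#'   filament, nm/nt.
#' @param target_strand For homologous filaments, which dsDNA strand the
#'   filament pairs with (\code{"complementary"} or \code{"outgoing"});
#'   \code{"none"} for non-homologous filaments.
#' @return An object of class \code{filament_spec}.
#' @export
filament_spec <- function(length_nt = 700, homologous = FALSE,
                          ext_per_nt = 0.12,
                          target_strand = c("none", "complementary", "outgoing")) {
  target_strand <- match.arg(target_strand)
  stopifnot(length_nt > 0, ext_per_nt > 0)
  if (homologous && target_strand == "none")
    stop("homologous filaments must name a target strand")
  if (!homologous && target_strand != "none")
    stop("non-homologous filaments have target_strand = 'none'")
  structure(list(length_nt = as.integer(length_nt), homologous = homologous,
                 ext_per_nt = ext_per_nt, target_strand = target_strand),
            class = "filament_spec")
}

#' Force protocol: ordered constant-force phases or a linear ramp
#'
#' The standard binding protocol holds 40 pN for 120 s, steps to a chosen
#' test force for 120 s, then returns to 40 pN for 120 s.
#'
#' @param durations Phase durations in s (all > 0).
#' @param forces Phase forces in pN, same length as \code{durations}; the
#'   instrument range is 2--200 pN.
#' @return An object of class \code{force_protocol}.
#' @seealso [force_ramp()], [standard_binding_protocol()]
#' @export
force_protocol <- function(durations, forces) {
  stopifnot(length(durations) == length(forces), length(durations) >= 1,
            all(durations > 0), all(forces >= 2), all(forces <= 200))
  structure(list(type = "phases", durations = durations, forces = forces),
            class = "force_protocol")
}

#' @rdname force_protocol
#' @param from,to Ramp start and end forces, pN.
#' @param rate Ramp rate, pN/s (> 0).
#' @export
force_ramp <- function(from = 2, to = 80, rate = 0.5) {
  stopifnot(from >= 2, to <= 200, to > from, rate > 0)
  structure(list(type = "ramp", from = from, to = to, rate = rate),
            class = "force_protocol")
}

#' @rdname force_protocol
#' @param test_force High-force phase value, pN.
#' @param hold Duration of each phase, s.
#' @param base_force Pre/post phase force, pN.
#' @export
standard_binding_protocol <- function(test_force = 56, hold = 120,
                                      base_force = 40) {
  force_protocol(durations = c(hold, hold, hold),
                 forces = c(base_force, test_force, base_force))
}

#' Total protocol duration in seconds
#' @param protocol A [force_protocol()] object.
#' @export
protocol_duration <- function(protocol) {
  if (protocol$type == "ramp") (protocol$to - protocol$from) / protocol$rate
  else sum(protocol$durations)
}

# Force at each time point of a uniform grid.
protocol_force_at <- function(protocol, time) {
  if (protocol$type == "ramp") {
    pmin(protocol$from + protocol$rate * time, protocol$to)
  } else {
    ends <- cumsum(protocol$durations)
    idx <- findInterval(time, c(0, ends), rightmost.closed = TRUE,
                        left.open = TRUE)
    idx[time <= 0] <- 1L
    idx <- pmin(idx, length(protocol$forces))
    protocol$forces[idx]
  }
}

#' Filament binding kinetics
#'
#' Phenomenological kinetics of dsDNA capture by a nucleoprotein filament
#' under force. Nucleation is a Poisson process whose rate is a step function
#' of force: zero below \code{threshold_force}, \code{nucleation_rate} above.
#' Thresholds depend on the pulling mode: dsDNA pulled by its 3'5' ends binds
#' at forces from ~50 pN, whereas 3'3' and 5'5' pulling shows no extension
#' gain anywhere in the studied range (up to 58 pN), so those modes default
#' to a threshold just above it.
#'
#' @param mode Pulling mode: which chemical ends of the dsDNA bear the force.
#' @param nucleation_rate Nucleation events per second above threshold.
#' @param threshold_force Force threshold in pN; default depends on mode.
#' @param growth_speed Extension growth speed while a filament zippers up,
#'   nm/s.
#' @param release_speed Extension decay speed after the force drops below
#'   threshold (non-homologous unbinding), nm/s.
#' @param pause_at_full_filament Pause growth when the bound length reaches an
#'   integer multiple of the full filament length.
#' @return An object of class \code{binding_kinetics}.
#' @export
binding_kinetics <- function(mode = c("3p5p", "3p3p", "5p5p"),
                             nucleation_rate = 0.04,
                             threshold_force = NULL,
                             growth_speed = 4,
                             release_speed = 10,
                             pause_at_full_filament = TRUE) {
  mode <- match.arg(mode)
  if (is.null(threshold_force))
    threshold_force <- if (mode == "3p5p") 50 else 60
  stopifnot(nucleation_rate >= 0, growth_speed >= 0, release_speed >= 0,
            threshold_force >= 2, threshold_force <= 200)
  structure(list(mode = mode, nucleation_rate = nucleation_rate,
                 threshold_force = threshold_force,
                 growth_speed = growth_speed, release_speed = release_speed,
                 pause_at_full_filament = pause_at_full_filament),
            class = "binding_kinetics")
}

#' Measurement noise model
#'
#' @param sigma Per-sample Gaussian noise on extension, nm (tracking
#'   accuracy, ~10 nm).
#' @param dt Sampling interval, s (5 Hz camera: 0.2 s).
#' @param drift_rate Linear instrumental drift, nm/s.
#' @param bead_force_cv Bead-to-bead coefficient of variation of the actual
#'   force at a given magnet position (~5%).
#' @return An object of class \code{noise_model}.
#' @export
noise_model <- function(sigma = 10, dt = 0.2, drift_rate = 0,
                        bead_force_cv = 0.05) {
  stopifnot(sigma >= 0, dt > 0, bead_force_cv >= 0)
  structure(list(sigma = sigma, dt = dt, drift_rate = drift_rate,
                 bead_force_cv = bead_force_cv),
            class = "noise_model")
}
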