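#' Simulate a filament-binding extension trace
#'
#' Generates a seeded synthetic magnetic-tweezers trace of dsDNA interacting
#' with recombinase-ssDNA filaments under a force protocol, together with
#' ground-truth labels. The naked-DNA baseline follows the mechanics model at
#' the instantaneous force; while the force is at or above the mode-specific
#' threshold, filaments nucleate as a Poisson process and the bound extension
#' \eqn{\Delta L} grows at \code{growth_speed} until it reaches an integer
#' multiple of the full filament length (\code{length_nt * ext_per_nt}), where
#' it pauses until the next nucleation. When the force drops below threshold a
#' non-homologous \eqn{\Delta L} decays back to zero at \code{release_speed};
#' homologous complexes persist. The \eqn{\Delta L} process is built in
#' continuous time, so noiseless traces are exactly piecewise linear between
#' the recorded breakpoints.
#'
#' @param protocol A [force_protocol()].
#' @param filament A [filament_spec()].
#' @param kinetics A [binding_kinetics()].
#' @param noise A [noise_model()].
#' @param n_filaments_max Maximum number of filaments that can bind.
#' @param seed Integer seed; identical seeds give identical traces.
#' @param nucleation_times Optional vector of deterministic nucleation times
#'   (s), overriding the Poisson process (for controlled tests).
#' @param construct_bp dsDNA construct length in bp.
#' @param params A [mechanics_params()].
#' @return A list with elements \code{trace} ([smt_trace()]) and \code{truth},
#'   the ground truth: \code{breakpoints} (s), \code{segment_slopes} (nm/s,
#'   one more than breakpoints), \code{pause_levels} (nm), and
#'   \code{n_filaments_bound}.
#' @export
simulate_binding_trace <- function(protocol = standard_binding_protocol(),
                                   filament = filament_spec(),
                                   kinetics = binding_kinetics(),
                                   noise = noise_model(),
                                   n_filaments_max = 2,
                                   seed = 1,
                                   nucleation_times = NULL,
                                   construct_bp = 48502,
                                   params = mechanics_params()) {
  if (protocol$type != "phases")
    stop("binding simulation needs a phase protocol")
  set.seed(seed)
  total <- protocol_duration(protocol)
  l_fil <- filament$length_nt * filament$ext_per_nt

  # Event-driven Delta-L(t): knots (time, value) of a continuous piecewise
  # linear process.
  kt <- 0; kv <- 0
  t_cur <- 0; dl <- 0; k_bound <- 0; growing <- FALSE; target <- 0
  pauses <- numeric(0)
  forced <- sort(nucleation_times)
  next_forced <- function(after) {
    cand <- forced[forced >= after - 1e-12]
    if (length(cand)) cand[1] else Inf
  }
  phase_ends <- cumsum(protocol$durations)
  phase_starts <- c(0, utils::head(phase_ends, -1))
  add_knot <- function(t, v) {
    if (t > kt[length(kt)] + 1e-12) { kt <<- c(kt, t); kv <<- c(kv, v) }
    else kv[length(kv)] <<- v
  }
  for (p in seq_along(protocol$forces)) {
    f <- protocol$forces[p]; t1 <- phase_ends[p]
    if (f >= kinetics$threshold_force) {
      repeat {
        if (growing) {
          t_reach <- t_cur + (target - dl) / max(kinetics$growth_speed, 1e-12)
          if (kinetics$growth_speed <= 0) t_reach <- Inf
          if (t_reach <= t1) {
            add_knot(t_reach, target)
            dl <- target; k_bound <- k_bound + 1
            pauses <- c(pauses, target)
            t_cur <- t_reach
            if (kinetics$pause_at_full_filament) growing <- FALSE
            else if (k_bound < n_filaments_max) target <- (k_bound + 1) * l_fil
            else growing <- FALSE
          } else {
            dl <- dl + kinetics$growth_speed * (t1 - t_cur)
            add_knot(t1, dl)
            t_cur <- t1
            break
          }
        } else if (k_bound < n_filaments_max) {
          t_nuc <- if (!is.null(nucleation_times)) next_forced(t_cur)
                   else t_cur + stats::rexp(1, max(kinetics$nucleation_rate, 1e-300))
          if (is.null(nucleation_times) && kinetics$nucleation_rate <= 0)
            t_nuc <- Inf
          if (t_nuc < t1) {
            add_knot(t_nuc, dl)
            t_cur <- max(t_nuc, t_cur)
            growing <- TRUE
            target <- (k_bound + 1) * l_fil
          } else { add_knot(t1, dl); t_cur <- t1; break }
        } else { add_knot(t1, dl); t_cur <- t1; break }
      }
    } else {
      growing <- FALSE
      if (dl > 0 && !filament$homologous && kinetics$release_speed > 0) {
        add_knot(t_cur, dl)
        t_zero <- t_cur + dl / kinetics$release_speed
        if (t_zero <= t1) {
          add_knot(t_zero, 0)
          dl <- 0; k_bound <- 0
          add_knot(t1, 0)
        } else {
          dl <- dl - kinetics$release_speed * (t1 - t_cur)
          add_knot(t1, dl)
        }
      } else add_knot(t1, dl)
      t_cur <- t1
    }
  }
  add_knot(total, dl)

  n <- round(total / noise$dt)
  time <- (seq_len(n) - 1) * noise$dt
  dl_t <- stats::approx(kt, kv, xout = time, rule = 2)$y
  force_t <- protocol_force_at(protocol, time)
  baseline <- force_extension(force_t, construct_bp, params)
  ext <- baseline + dl_t + noise$drift_rate * time
  if (noise$sigma > 0) ext <- ext + stats::rnorm(n, 0, noise$sigma)

  slopes <- diff(kv) / diff(kt)
  truth <- list(breakpoints = kt[-c(1, length(kt))],
                segment_slopes = slopes,
                pause_levels = unique(pauses),
                n_filaments_bound = k_bound)
  trace <- smt_trace(time, ext, force_t, construct_bp = construct_bp,
                     meta = list(seed = seed, kind = "binding",
                                 mode = kinetics$mode,
                                 filament_nt = filament$length_nt,
                                 test_force = max(protocol$forces)))
  list(trace = trace, truth = truth)
}

#' Simulate a strand-exchange elongation trace
#'
#' A homologous filament progressively exchanges strands with the tethered
#' dsDNA; the tether extension grows linearly at \code{rate} on top of the
#' naked-DNA baseline for the duration of the protocol (20--35 pN regime).
#' The complex is stable, so lowering the force does not reverse the gain.
#'
#' @param rate Strand-exchange elongation rate, nm/s (>= 0).
#' @inheritParams simulate_binding_trace
#' @return A list with \code{trace} and \code{truth} as in
#'   [simulate_binding_trace()].
#' @export
simulate_exchange_trace <- function(rate,
                                    protocol = force_protocol(120, 25),
                                    noise = noise_model(),
                                    seed = 1,
                                    construct_bp = 48502,
                                    params = mechanics_params()) {
  if (rate < 0) stop("'rate' must be >= 0")
  if (protocol$type != "phases")
    stop("exchange simulation needs a phase protocol")
  set.seed(seed)
  total <- protocol_duration(protocol)
  n <- round(total / noise$dt)
  time <- (seq_len(n) - 1) * noise$dt
  force_t <- protocol_force_at(protocol, time)
  ext <- force_extension(force_t, construct_bp, params) + rate * time +
    noise$drift_rate * time
  if (noise$sigma > 0) ext <- ext + stats::rnorm(n, 0, noise$sigma)
  trace <- smt_trace(time, ext, force_t, construct_bp = construct_bp,
                     meta = list(seed = seed, kind = "exchange", rate = rate))
  truth <- list(breakpoints = numeric(0), segment_slopes = rate,
                pause_levels = numeric(0), n_filaments_bound = 1L)
  list(trace = trace, truth = truth)
}

#' Simulate a no-binding control trace
#'
#' Naked-DNA baseline plus noise; optionally a small settling transient
#' (< 20 s) after each force change, emulating the slight early extension
#' drift some control molecules show.
#'
#' @inheritParams simulate_binding_trace
#' @param settle_amplitude Amplitude of the settling transient, nm.
#' @param settle_tau Transient time constant, s.
#' @return An [smt_trace()].
#' @export
simulate_control_trace <- function(protocol = standard_binding_protocol(),
                                   noise = noise_model(),
                                   seed = 1,
                                   settle_amplitude = 0, settle_tau = 5,
                                   construct_bp = 48502,
                                   params = mechanics_params()) {
  if (protocol$type != "phases")
    stop("control simulation needs a phase protocol")
  set.seed(seed)
  total <- protocol_duration(protocol)
  n <- round(total / noise$dt)
  time <- (seq_len(n) - 1) * noise$dt
  force_t <- protocol_force_at(protocol, time)
  ext <- force_extension(force_t, construct_bp, params) +
    noise$drift_rate * time
  if (settle_amplitude != 0) {
    starts <- c(0, cumsum(utils::head(protocol$durations, -1)))
    for (t0 in starts[-1]) {
      after <- time >= t0
      ext[after] <- ext[after] -
        settle_amplitude * exp(-(time[after] - t0) / settle_tau)
    }
  }
  if (noise$sigma > 0) ext <- ext + stats::rnorm(n, 0, noise$sigma)
  smt_trace(time, ext, force_t, construct_bp = construct_bp,
            meta = list(seed = seed, kind = "control"))
}

#' Simulate a force-ramp overstretching trace
#'
#' The true force ramps linearly; the recorded (nominal) force is the true
#' force divided by \code{bead_scale}, emulating a bead whose magnetization
#' deviates from the calibration standard. Extension follows the mechanics
#' model at the true force, so the nominal transition midpoint appears at
#' \code{overstretch_force / bead_scale}.
#'
#' @param bead_scale Ratio of true to nominal force (> 0).
#' @param ramp A [force_ramp()] protocol for the true force.
#' @inheritParams simulate_binding_trace
#' @return An [smt_trace()] whose force column is the nominal force.
#' @export
simulate_overstretch_ramp <- function(bead_scale = 1,
                                      params = mechanics_params(),
                                      noise = noise_model(),
                                      seed = 1,
                                      ramp = force_ramp(),
                                      construct_bp = 48502) {
  if (bead_scale <= 0) stop("'bead_scale' must be > 0")
  if (ramp$type != "ramp") stop("'ramp' must be a force_ramp()")
  set.seed(seed)
  total <- protocol_duration(ramp)
  n <- round(total / noise$dt)
  time <- (seq_len(n) - 1) * noise$dt
  true_force <- protocol_force_at(ramp, time)
  ext <- force_extension(true_force, construct_bp, params)
  if (noise$sigma > 0) ext <- ext + stats::rnorm(n, 0, noise$sigma)
  smt_trace(time, ext, true_force / bead_scale, construct_bp = construct_bp,
            meta = list(seed = seed, kind = "overstretch_ramp",
                        bead_scale = bead_scale))
}

#' Simulate a reproducible cohort of traces
#'
#' Expands a cohort configuration into seeded traces with ground-truth
#' sidecars. Per-trace seeds are drawn once from the master seed, so the
#' cohort is reproducible trace-by-trace.
#'
#' @param config A list of cohort descriptions. Each element is a list with
#'   \code{type} ("binding", "control" or "exchange"), \code{n} replicates
#'   (in YAML configs use the key \code{n_traces}: bare \code{n} is a YAML
#'   boolean), and type-specific fields: binding -- \code{mode}, \code{test_force},
#'   \code{filament_nt} (vectors are crossed); control -- \code{test_force};
#'   exchange -- \code{rate}, \code{force}, \code{duration},
#'   \code{pulled_strand}.
#' @param seed Master seed.
#' @param out_dir If non-NULL, write each trace as CSV plus a ground-truth
#'   JSON sidecar and return file paths in the entries.
#' @param noise A [noise_model()] shared by the cohort.
#' @param params A [mechanics_params()].
#' @param kinetics_args Extra arguments passed to [binding_kinetics()].
#' @param n_filaments_max Passed to [simulate_binding_trace()].
#' @return A list of entries, each with \code{trace}, \code{truth} (NULL for
#'   controls), \code{type}, \code{mode}, \code{force}, \code{filament_nt},
#'   \code{pulled_strand}, \code{seed} and (if written) \code{path}.
#' @export
simulate_cohort <- function(config, seed = 1, out_dir = NULL,
                            noise = noise_model(),
                            params = mechanics_params(),
                            kinetics_args = list(),
                            n_filaments_max = 2) {
  if (length(config) == 0) stop("empty cohort config")
  # expand to per-trace cells
  cells <- list()
  for (co in config) {
    if (is.null(co$type)) stop("each cohort needs a 'type'")
    n <- co$n %||% co$n_traces %||% 1L
    if (co$type == "binding") {
      grid <- expand.grid(mode = co$mode %||% "3p5p",
                          force = co$test_force %||% 56,
                          filament_nt = co$filament_nt %||% 700,
                          rep = seq_len(n), stringsAsFactors = FALSE)
      for (i in seq_len(nrow(grid)))
        cells[[length(cells) + 1]] <- list(type = "binding",
          mode = grid$mode[i], force = grid$force[i],
          filament_nt = grid$filament_nt[i])
    } else if (co$type == "control") {
      grid <- expand.grid(force = co$test_force %||% 56, rep = seq_len(n))
      for (i in seq_len(nrow(grid)))
        cells[[length(cells) + 1]] <- list(type = "control",
          mode = co$mode %||% "3p5p", force = grid$force[i])
    } else if (co$type == "exchange") {
      for (i in seq_len(n))
        cells[[length(cells) + 1]] <- list(type = "exchange",
          rate = co$rate %||% 0.2, force = co$force %||% 25,
          duration = co$duration %||% 120,
          pulled_strand = co$pulled_strand %||% "outgoing")
    } else stop("unknown cohort type: ", co$type)
  }
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(cells))
  entries <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    if (cell$type == "binding") {
      kin <- do.call(binding_kinetics,
                     c(list(mode = cell$mode), kinetics_args))
      sim <- simulate_binding_trace(
        protocol = standard_binding_protocol(test_force = cell$force),
        filament = filament_spec(length_nt = cell$filament_nt),
        kinetics = kin, noise = noise, seed = seeds[i],
        n_filaments_max = n_filaments_max, params = params)
      entry <- list(trace = sim$trace, truth = sim$truth, type = "binding",
                    mode = cell$mode, force = cell$force,
                    filament_nt = cell$filament_nt, seed = seeds[i])
    } else if (cell$type == "control") {
      tr <- simulate_control_trace(
        protocol = standard_binding_protocol(test_force = cell$force),
        noise = noise, seed = seeds[i], params = params)
      entry <- list(trace = tr, truth = NULL, type = "control",
                    mode = cell$mode, force = cell$force, seed = seeds[i])
    } else {
      sim <- simulate_exchange_trace(
        rate = cell$rate,
        protocol = force_protocol(cell$duration, cell$force),
        noise = noise, seed = seeds[i], params = params)
      entry <- list(trace = sim$trace, truth = sim$truth, type = "exchange",
                    force = cell$force, rate = cell$rate,
                    pulled_strand = cell$pulled_strand, seed = seeds[i])
    }
    entries[[i]] <- entry
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(entries)) {
      base <- sprintf("trace_%03d_%s", i, entries[[i]]$type)
      path <- file.path(out_dir, paste0(base, ".csv"))
      write_trace(entries[[i]]$trace, path)
      entries[[i]]$path <- path
      if (!is.null(entries[[i]]$truth)) {
        jsonlite::write_json(entries[[i]]$truth,
                             file.path(out_dir, paste0(base, ".truth.json")),
                             auto_unbox = TRUE, digits = NA)
      }
    }
  }
  entries
}

`%||%` <- function(a, b) if (is.null(a)) b else a
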