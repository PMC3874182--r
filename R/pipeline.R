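#' Read a run configuration (YAML)
#'
#' A run configuration describes the simulated cohorts and the analysis
#' settings. Recognised top-level keys: \code{seed}, \code{noise},
#' \code{mechanics}, \code{segmentation}, \code{kinetics},
#' \code{n_filaments_max}, \code{cohorts}, \code{calibration},
#' \code{window}. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A named list (class \code{run_config}).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "noise", "mechanics", "segmentation", "kinetics",
             "n_filaments_max", "cohorts", "calibration", "window")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (is.null(cfg$cohorts) || length(cfg$cohorts) == 0)
    stop("config must list at least one cohort")
  structure(cfg, class = "run_config")
}

#' Read a cohort manifest (YAML)
#'
#' A manifest lists trace files with their labels: \code{path},
#' \code{mode}, \code{filament_nt}, \code{pulled_strand}, \code{force}.
#'
#' @param path YAML file path.
#' @return data.frame with one row per trace.
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  if (is.null(m$entries) || length(m$entries) == 0)
    stop("manifest has no entries")
  df <- do.call(rbind, lapply(m$entries, function(e)
    data.frame(path = e$path,
               mode = e$mode %||% NA_character_,
               filament_nt = e$filament_nt %||% NA_real_,
               pulled_strand = e$pulled_strand %||% NA_character_,
               force = e$force %||% NA_real_)))
  if (anyDuplicated(df$path)) stop("manifest paths must be unique")
  df
}

#' Characteristic rates per cohort from a manifest
#'
#' Reads each trace listed in the manifest, segments it, groups traces by
#' \code{pulled_strand}, and estimates the characteristic elongation rate
#' per group.
#'
#' @param manifest data.frame from [read_manifest()].
#' @param params A [segmentation_params()].
#' @param seed Bootstrap seed.
#' @return Named list of \code{rate_estimate} objects, one per group, plus
#'   \code{comparison} when there are exactly two groups.
#' @export
manifest_rates <- function(manifest, params = segmentation_params(),
                           seed = 1) {
  segs <- lapply(manifest$path, function(p) segment_trace(read_trace(p),
                                                          params))
  groups <- split(seq_len(nrow(manifest)), manifest$pulled_strand)
  out <- lapply(groups, function(idx)
    characteristic_rate(slope_histogram(segs[idx]), seed = seed))
  if (length(out) == 2)
    out$comparison <- compare_rates(out[[1]], out[[2]], seed = seed)
  out
}

config_objects <- function(cfg) {
  list(noise = do.call(noise_model, cfg$noise %||% list()),
       params = do.call(mechanics_params, cfg$mechanics %||% list()),
       seg = do.call(segmentation_params, cfg$segmentation %||% list()),
       kinetics_args = cfg$kinetics %||% list(),
       n_max = cfg$n_filaments_max %||% 2)
}

#' Run the full analysis pipeline on a configuration
#'
#' Simulates the configured cohorts from the master seed, segments every
#' trace, and produces the pipeline observables: the \eqn{\Delta L} cohort
#' summary table, the pooled pause histogram with its extension-per-nt and
#' implied coverage, characteristic strand-exchange rates per pulled strand
#' (with a two-cohort comparison), and bead calibration from an
#' overstretching ramp when requested. Deterministic given the master seed;
#' outputs embed the config hash and seed.
#'
#' @param config A \code{run_config} (or path to one).
#' @param out_dir If non-NULL, write \code{results.json} and
#'   \code{summary.csv} there.
#' @return A list of class \code{pipeline_result} with elements
#'   \code{binding}, \code{pauses}, \code{exchange}, \code{calibration},
#'   \code{provenance}, \code{log}.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$cohorts) || length(config$cohorts) == 0)
    stop("config must list at least one cohort")
  ob <- config_objects(config)
  seed <- config$seed %||% 1
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)
  log <- character(0)

  entries <- simulate_cohort(config$cohorts, seed = seed, noise = ob$noise,
                             params = ob$params,
                             kinetics_args = ob$kinetics_args,
                             n_filaments_max = ob$n_max)
  segs <- lapply(entries, function(e) segment_trace(e$trace, ob$seg))
  for (i in seq_along(segs)) {
    sk <- segs[[i]]$skipped
    for (r in seq_len(nrow(sk)))
      log <- c(log, sprintf("trace %d: skipped high-noise region %.1f-%.1f s",
                            i, sk$t_start[r], sk$t_end[r]))
  }

  is_bind <- vapply(entries, function(e) e$type %in% c("binding", "control"),
                    logical(1))
  binding <- NULL; pauses_out <- NULL
  if (any(is_bind)) {
    summaries <- lapply(which(is_bind), function(i) {
      s <- delta_extension(entries[[i]]$trace, params = ob$params)
      s$mode <- if (entries[[i]]$type == "control") "control"
                else entries[[i]]$mode
      s
    })
    binding <- cohort_summary(summaries)
    # pause analysis per filament length over binding traces
    bind_idx <- which(vapply(entries, function(e) e$type == "binding",
                             logical(1)))
    if (length(bind_idx)) {
      lens <- vapply(entries[bind_idx], function(e) e$filament_nt, numeric(1))
      ests <- list()
      for (L in unique(lens)) {
        idx <- bind_idx[lens == L]
        pl <- do.call(rbind, lapply(idx, function(i)
          detect_pauses(segs[[i]], entries[[i]]$trace,
                        baseline = binding_baseline(entries[[i]]$trace,
                                                    ob$params))))
        if (nrow(pl) == 0) {
          log <- c(log, sprintf("no pauses detected at %d nt", L))
          next
        }
        hist <- pause_histogram(pl)
        est <- tryCatch(ext_per_nt(hist$peaks, L), error = function(e) NULL)
        if (!is.null(est)) ests[[as.character(L)]] <- est
      }
      if (length(ests)) {
        pooled <- pool_ext_per_nt(ests)
        pauses_out <- list(per_length = ests, pooled = pooled,
                           coverage = coverage_fraction(pooled))
      }
    }
  }

  exchange <- NULL
  is_ex <- vapply(entries, function(e) e$type == "exchange", logical(1))
  if (any(is_ex)) {
    strands <- vapply(entries[is_ex], function(e) e$pulled_strand,
                      character(1))
    groups <- split(which(is_ex), strands)
    exchange <- lapply(groups, function(idx)
      characteristic_rate(slope_histogram(segs[idx]), seed = seed))
    if (length(exchange) == 2)
      exchange$comparison <- compare_rates(exchange[[1]], exchange[[2]],
                                           seed = seed)
  }

  calibration <- NULL
  if (isTRUE(config$calibration$enabled %||% FALSE) ||
      !is.null(config$calibration)) {
    bs <- config$calibration$bead_scale %||% 1
    ramp <- simulate_overstretch_ramp(
      bead_scale = bs, params = ob$params,
      noise = noise_model(sigma = config$calibration$sigma %||% 0,
                          dt = ob$noise$dt),
      seed = seed)
    calibration <- calibrate_bead(ramp,
                                  standard = ob$params$overstretch_force)
  }

  res <- structure(list(binding = binding, pauses = pauses_out,
                        exchange = exchange, calibration = calibration,
                        provenance = list(seed = seed,
                                          config_hash = cfg_hash,
                                          n_traces = length(entries)),
                        log = log),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(pipeline_result_json(res),
                         file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    if (!is.null(binding))
      utils::write.csv(binding, file.path(out_dir, "summary.csv"),
                       row.names = FALSE)
  }
  res
}

# Flatten a pipeline_result to plain lists for JSON serialisation.
pipeline_result_json <- function(res) {
  out <- list(provenance = res$provenance, log = res$log)
  if (!is.null(res$binding)) out$binding <- res$binding
  if (!is.null(res$pauses)) {
    out$pauses <- list(
      pooled_ext_per_nt = res$pauses$pooled$value,
      pooled_sd = res$pauses$pooled$sd,
      per_length = lapply(res$pauses$per_length, function(e)
        list(value = e$value, sd = e$sd, n_peaks = e$n_pauses)),
      coverage_fraction = res$pauses$coverage$fraction)
  }
  if (!is.null(res$exchange)) {
    out$exchange <- lapply(res$exchange, function(e) {
      if (inherits(e, "rate_estimate"))
        list(rate = e$rate, ci_low = e$ci_low, ci_high = e$ci_high,
             n_traces = e$n_traces, zero_fraction = e$zero_fraction)
      else
        list(difference = e$difference, ci_low = e$ci_low,
             ci_high = e$ci_high, ratio = e$ratio,
             significant = e$significant)
    })
  }
  if (!is.null(res$calibration))
    out$calibration <- unclass(res$calibration)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline result (seed", x$provenance$seed, ")\n")
  if (!is.null(x$binding)) { cat("binding summary:\n"); print(x$binding) }
  if (!is.null(x$pauses)) {
    cat(sprintf("pooled extension/nt: %.3f +/- %.3f nm/nt; ",
                x$pauses$pooled$value, x$pauses$pooled$sd))
    print(x$pauses$coverage)
  }
  if (!is.null(x$exchange)) {
    for (nm in names(x$exchange)) { cat(nm, ": "); print(x$exchange[[nm]]) }
  }
  if (!is.null(x$calibration)) print(x$calibration)
  invisible(x)
}
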