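#' Construct an extension trace
#'
#' A trace is a uniformly sampled time series of bead extension and applied
#' force, plus provenance metadata.
#'
#' @param time Time stamps in s, a strictly increasing uniform grid.
#' @param extension Extension in nm, same length as \code{time}, finite.
#' @param force Applied force in pN, same length as \code{time}.
#' @param construct_bp Length of the tethered dsDNA construct in bp
#'   (lambda DNA: 48502).
#' @param meta Named list of provenance (seed, mode, filament length, ...).
#' @return An object of class \code{smt_trace}.
#' @export
smt_trace <- function(time, extension, force, construct_bp = 48502,
                      meta = list()) {
  n <- length(time)
  if (length(extension) != n || length(force) != n)
    stop("time, extension and force must have equal length")
  if (n < 2) stop("a trace needs at least 2 samples")
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    stop("time must be a uniform grid")
  if (any(!is.finite(extension))) stop("extension must be finite")
  structure(list(time = as.numeric(time),
                 extension = as.numeric(extension),
                 force = as.numeric(force),
                 dt = mean(dt),
                 construct_bp = construct_bp,
                 meta = meta),
            class = "smt_trace")
}

#' @export
print.smt_trace <- function(x, ...) {
  cat(sprintf("extension trace: %d samples, %.1f s at dt = %.3g s\n",
              length(x$time), x$time[length(x$time)] - x$time[1], x$dt))
  cat(sprintf("  extension %.0f-%.0f nm, force %.3g-%.3g pN, construct %d bp\n",
              min(x$extension), max(x$extension),
              min(x$force), max(x$force), as.integer(x$construct_bp)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.smt_trace <- function(x, ...) {
  data.frame(time_s = x$time, extension_nm = x$extension, force_pN = x$force)
}

# Constant-force phases of a trace: data.frame(start, end, force) in sample
# indices. Samples whose force differs by < tol pN belong to one phase.
trace_phases <- function(trace, tol = 1e-6) {
  chg <- which(abs(diff(trace$force)) > tol)
  starts <- c(1L, chg + 1L)
  ends <- c(chg, length(trace$force))
  data.frame(start = starts, end = ends, force = trace$force[starts])
}

#' Read / write a trace CSV
#'
#' The on-disk format is a plain CSV with header
#' \code{time_s,extension_nm,force_pN}, one row per sample, preceded by
#' \code{#}-prefixed \code{key: value} metadata lines.
#'
#' @param path File path.
#' @return \code{read_trace} returns an [smt_trace()]; \code{write_trace}
#'   returns \code{path} invisibly.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- sub("^#\\s*", "", ln)
    pos <- regexpr(":", kv, fixed = TRUE)
    if (pos > 0) {
      key <- trimws(substr(kv, 1, pos - 1))
      val <- trimws(substr(kv, pos + 1, nchar(kv)))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  body <- lines[!is_meta]
  dat <- utils::read.csv(text = body, check.names = FALSE)
  need <- c("time_s", "extension_nm", "force_pN")
  if (!all(need %in% names(dat)))
    stop("trace file must have columns ", paste(need, collapse = ", "))
  dtv <- diff(dat$time_s)
  if (any(dtv <= 0)) {
    bad <- which(dtv <= 0)[1] + 1L
    stop("non-monotone time at data row ", bad)
  }
  construct_bp <- if (!is.null(meta$construct_bp)) meta$construct_bp else 48502
  smt_trace(dat$time_s, dat$extension_nm, dat$force_pN,
            construct_bp = construct_bp, meta = meta)
}

#' @rdname read_trace
#' @param trace An [smt_trace()] object.
#' @export
write_trace <- function(trace, path) {
  meta <- trace$meta
  meta$construct_bp <- trace$construct_bp
  hdr <- vapply(names(meta), function(k)
    sprintf("# %s: %s", k, format(meta[[k]], digits = 15)), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(hdr)) writeLines(hdr, con)
  utils::write.csv(as.data.frame(trace), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
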