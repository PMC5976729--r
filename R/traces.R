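#' Sampled-trace containers
#'
#' Traces are tibbles with a uniform `time_ps` axis plus a value column, so
#' they pipe directly into dplyr/ggplot2 workflows. `field_trace()` carries an
#' electric field in V/m, `phase_trace()` a probe phase shift in mrad with an
#' optional per-point uncertainty.
#'
#' @param time_ps numeric vector of delays, picoseconds, uniformly spaced.
#' @param field numeric vector, electric field in V/m.
#' @param meta named list of free-form metadata (peak field, description, ...).
#' @return A tibble of class `field_trace` (columns `time_ps`, `field`) or
#'   `phase_trace` (columns `time_ps`, `phase_mrad` and optionally
#'   `sigma_mrad`).
#' @examples
#' tr <- field_trace(seq(-1, 1, 0.01), sin(seq(-1, 1, 0.01)))
#' trace_dt(tr)
#' @export
field_trace <- function(time_ps, field, meta = list()) {
  check_uniform_grid(time_ps)
  stopifnot(length(time_ps) == length(field), all(is.finite(field)))
  out <- tibble::tibble(time_ps = as.numeric(time_ps), field = as.numeric(field))
  class(out) <- c("field_trace", class(out))
  attr(out, "meta") <- meta
  out
}

#' @rdname field_trace
#' @param phase_mrad numeric vector, probe phase shift in mrad.
#' @param sigma_mrad optional numeric vector of 1-sigma uncertainties, mrad.
#' @export
phase_trace <- function(time_ps, phase_mrad, sigma_mrad = NULL, meta = list()) {
  check_uniform_grid(time_ps)
  stopifnot(length(time_ps) == length(phase_mrad))
  out <- tibble::tibble(time_ps = as.numeric(time_ps),
                        phase_mrad = as.numeric(phase_mrad))
  if (!is.null(sigma_mrad)) {
    stopifnot(length(sigma_mrad) == length(time_ps), all(sigma_mrad >= 0))
    out$sigma_mrad <- as.numeric(sigma_mrad)
  }
  class(out) <- c("phase_trace", class(out))
  attr(out, "meta") <- meta
  out
}

#' @rdname field_trace
#' @param trace a trace tibble with a `time_ps` column.
#' @export
trace_dt <- function(trace) {
  t <- trace$time_ps
  if (length(t) < 2) stop("trace needs at least two samples")
  t[2] - t[1]
}

# Uniformity within 1e-9 relative; all trace algebra (FFT, recursive filters)
# relies on it.
check_uniform_grid <- function(t) {
  if (length(t) < 2) stop("time grid needs at least two points")
  if (!all(is.finite(t))) stop("time grid must be finite")
  dt <- diff(t)
  if (any(dt <= 0)) stop("time grid must be strictly increasing")
  if (max(abs(dt - dt[1])) > 1e-9 * abs(dt[1]))
    stop("time grid must be uniform (relative tolerance 1e-9)")
  invisible(TRUE)
}

#' Read and write delimited trace files
#'
#' The shared on-disk format is whitespace/tab-delimited text with a mandatory
#' header. Comment lines starting with `#` carry provenance (seed, units,
#' delay-origin convention) and are ignored on read. The first column is
#' always `time_ps`.
#'
#' @param path file path.
#' @param trace a `field_trace` or `phase_trace`.
#' @param header named character vector written as `# key: value` provenance
#'   lines.
#' @return `read_trace()` returns a tibble classed by its value column
#'   (`field` -> `field_trace`, `phase_mrad` -> `phase_trace`).
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(trimws(lines), "#")]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) stop("trace file '", path, "' has no data rows")
  df <- utils::read.table(text = body, header = TRUE)
  if (names(df)[1] != "time_ps")
    stop("trace file '", path, "' must start with a time_ps column")
  df[] <- lapply(df, function(col) suppressWarnings(as.numeric(col)))
  bad <- which(!stats::complete.cases(df))
  if (length(bad))
    stop("malformed trace file '", path, "': bad value near data line ", bad[1])
  if ("field" %in% names(df)) {
    field_trace(df$time_ps, df$field)
  } else if ("phase_mrad" %in% names(df)) {
    phase_trace(df$time_ps, df$phase_mrad,
                if ("sigma_mrad" %in% names(df)) df$sigma_mrad else NULL)
  } else {
    tibble::as_tibble(df)
  }
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("generator: thzkerr", header)
  writeLines(paste0("# ", names2(hdr), hdr), con)
  df <- as.data.frame(trace)
  writeLines(paste(names(df), collapse = "\t"), con)
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

names2 <- function(x) {
  nm <- names(x)
  if (is.null(nm)) return(rep("", length(x)))
  ifelse(nzchar(nm), paste0(nm, ": "), "")
}

#' Gaussian smoothing of a sampled trace
#'
#' Discrete convolution with a normalized Gaussian kernel of standard
#' deviation `sigma_ps`; edges are handled by reflection so the kernel mass is
#' preserved everywhere. `sigma_ps = 0` returns the input unchanged. This is
#' the operation used to emulate probing with longer pulses that do not
#' resolve the fast dynamics (e.g. a 1.4 ps Gaussian).
#'
#' @param trace a trace tibble (`time_ps` plus one value column).
#' @param sigma_ps kernel standard deviation in ps, `>= 0`.
#' @return The trace with its value column smoothed.
#' @export
smooth_trace <- function(trace, sigma_ps) {
  stopifnot(sigma_ps >= 0)
  if (sigma_ps == 0) return(trace)
  dt <- trace_dt(trace)
  n <- nrow(trace)
  half <- min(max(1L, ceiling(5 * sigma_ps / dt)), n - 1L)
  k <- stats::dnorm(seq(-half, half) * dt, sd = sigma_ps)
  k <- k / sum(k)
  vcol <- setdiff(names(trace), c("time_ps", "sigma_mrad"))[1]
  x <- trace[[vcol]]
  # reflect both ends
  xp <- c(rev(x[seq_len(half) + 1]), x, rev(x[n - seq_len(half)]))
  sm <- stats::convolve(xp, rev(k), type = "filter")
  # convolve(type = "filter") trims (length(k)-1)/2 from each side of xp
  trace[[vcol]] <- sm[seq_len(n)]
  trace
}
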