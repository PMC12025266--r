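#' Construct a 1D NMR spectrum
#'
#' A `spectrum1d` is the unit every processing step transforms: a strictly
#' monotone chemical-shift axis (ppm), a matching intensity vector, a scan-type
#' tag distinguishing the POCE reference scan (total 12C+13C signal) from the
#' edited scan (13C-only signal), and an append-only processing log.
#'
#' @param ppm Numeric vector of chemical shifts (ppm), strictly monotone.
#' @param intensity Numeric vector of the same length.
#' @param scan_type `"reference"` or `"edited"`.
#' @param sample_id Character label for the originating sample.
#' @param processing_log List of previously applied steps (normally empty).
#' @return An object of class `spectrum1d`.
#' @export
spectrum1d <- function(ppm, intensity, scan_type = c("reference", "edited"),
                       sample_id = "sample", processing_log = list()) {
  scan_type <- match.arg(scan_type)
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity))
    stop("`ppm` and `intensity` must have the same length", call. = FALSE)
  if (length(ppm) < 2L)
    stop("a spectrum needs at least 2 points", call. = FALSE)
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0)))
    stop("`ppm` must be strictly monotone", call. = FALSE)
  structure(
    list(ppm = ppm, intensity = intensity, scan_type = scan_type,
         sample_id = sample_id, processing_log = processing_log),
    class = "spectrum1d"
  )
}

#' @method print spectrum1d
#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("<spectrum1d> %s scan '%s': %d points, %.3f..%.3f ppm\n",
              x$scan_type, x$sample_id, length(x$ppm),
              min(x$ppm), max(x$ppm)))
  if (length(x$processing_log)) {
    cat("processing log:\n")
    for (step in x$processing_log)
      cat("  -", step$step,
          paste(sprintf("%s=%s", names(step$params),
                        vapply(step$params, format, "")), collapse = " "),
          "\n")
  }
  invisible(x)
}

# append a step record; the log is append-only by construction
log_step <- function(s, step, params = list()) {
  s$processing_log <- c(s$processing_log, list(list(step = step, params = params)))
  s
}

#' Estimate the spectral noise standard deviation
#'
#' Robust estimate from first differences (peaks are sparse, so the median
#' absolute first difference is dominated by noise): sd = MAD(diff)/sqrt(2).
#'
#' @param s A [spectrum1d()].
#' @return Non-negative scalar.
#' @export
estimate_noise_sd <- function(s) {
  stats::mad(diff(s$intensity)) / sqrt(2)
}

#' Read and write spectra as two-column CSV with a JSON sidecar
#'
#' The on-disk dialect is a `ppm,intensity` CSV plus `<path>.json` holding the
#' sample id, scan type, and the processing log, so round trips preserve
#' provenance.
#'
#' @param s A [spectrum1d()].
#' @param path CSV file path; the sidecar is written at `paste0(path, ".json")`.
#' @return `write_spectrum` returns `path` invisibly; `read_spectrum` returns a
#'   [spectrum1d()].
#' @export
write_spectrum <- function(s, path) {
  utils::write.csv(data.frame(ppm = s$ppm, intensity = s$intensity),
                   path, row.names = FALSE)
  meta <- list(sample_id = s$sample_id, scan_type = s$scan_type,
               processing_log = s$processing_log)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("ppm", "intensity") %in% names(tab)))
    stop("spectrum CSV must have columns ppm,intensity: ", path, call. = FALSE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  spectrum1d(tab$ppm, tab$intensity,
             scan_type = if (is.null(meta$scan_type)) "reference" else meta$scan_type,
             sample_id = if (is.null(meta$sample_id)) basename(path) else meta$sample_id,
             processing_log = if (is.null(meta$processing_log)) list() else meta$processing_log)
}

# run code with a private RNG stream, restoring the caller's .Random.seed
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
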