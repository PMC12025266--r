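#' Trapezoidal integration of a spectrum over a chemical-shift window
#'
#' Signed trapezoidal integral of intensity over ppm in `[lo, hi]`, with the
#' partial end bins linearly interpolated so the result is continuous in the
#' window bounds. Negative excursions (baseline dips) reduce the area.
#'
#' @param s A [spectrum1d()].
#' @param window One-row data.frame with `lo` and `hi` (ppm).
#' @return Scalar area (intensity x ppm).
#' @export
integrate_window <- function(s, window) {
  ord <- order(s$ppm)
  x <- s$ppm[ord]
  y <- s$intensity[ord]
  lo <- max(window$lo, x[1])
  hi <- min(window$hi, x[length(x)])
  if (window$hi < x[1] || window$lo > x[length(x)])
    stop("integration window lies outside the spectrum ppm range", call. = FALSE)
  inside <- which(x >= window$lo & x <= window$hi)
  if (length(inside) < 3)
    stop("integration window overlaps fewer than 3 grid points", call. = FALSE)
  xx <- x[inside]
  yy <- y[inside]
  if (lo < xx[1]) {
    xx <- c(lo, xx)
    yy <- c(stats::approx(x, y, xout = lo)$y, yy)
  }
  if (hi > xx[length(xx)]) {
    xx <- c(xx, hi)
    yy <- c(yy, stats::approx(x, y, xout = hi)$y)
  }
  sum(diff(xx) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
}

#' 13C enrichment ratio from a reference/edited integral pair
#'
#' Enrichment percent = 100 x edited / reference, i.e. the 13C fraction of the
#' total (12C+13C) pool. Values outside \[0, 100\] are returned as-is but
#' flagged (noise can push integrals past the bounds); a non-positive
#' reference integral yields `NA` with a diagnostic rather than a silent zero.
#'
#' @param edit_integral,ref_integral Window areas from the edited and
#'   reference scans.
#' @return Numeric percent with logical attribute `"out_of_range"`; `NA` (with
#'   a warning) when `ref_integral <= 0`.
#' @export
enrichment_ratio <- function(edit_integral, ref_integral) {
  if (!is.finite(ref_integral) || ref_integral <= 0) {
    warning("non-positive reference integral; enrichment undefined",
            call. = FALSE)
    return(structure(NA_real_, out_of_range = NA))
  }
  pct <- 100 * edit_integral / ref_integral
  structure(pct, out_of_range = (pct < 0 || pct > 100))
}

#' Process and quantify one reference/edited scan pair
#'
#' Applies the standard chain (zero-order phase correction, asymmetric
#' least-squares baseline correction, TMSP axis calibration) to both scans,
#' then integrates every metabolite window on each and forms enrichment
#' ratios.
#'
#' @param reference,edited [spectrum1d()] scans of one sample.
#' @param windows Window table from [load_windows()].
#' @param phase `"auto"`, `"none"`, or a numeric angle passed to
#'   [phase_correct()].
#' @param baseline Logical: apply [baseline_correct()] (with `lam`, `p_asym`)?
#' @param calibrate Logical: apply [calibrate_ppm()]?
#' @param lam,p_asym Baseline parameters.
#' @return A data.frame with one row per window: `metabolite`, `ref_integral`,
#'   `edit_integral`, `enrichment_pct`, `out_of_range`.
#' @export
quantify_pair <- function(reference, edited, windows = default_windows(),
                          phase = "auto", baseline = TRUE, calibrate = TRUE,
                          lam = 1e13, p_asym = 0.001) {
  chain <- function(s) {
    if (!identical(phase, "none")) s <- phase_correct(s, phi0 = phase)
    if (baseline) s <- baseline_correct(s, lam = lam, p_asym = p_asym)
    if (calibrate) s <- calibrate_ppm(s, window_for(windows, "TMSP"))
    s
  }
  ref <- chain(reference)
  edt <- chain(edited)
  res <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, , drop = FALSE]
    ri <- integrate_window(ref, w)
    ei <- integrate_window(edt, w)
    pct <- suppressWarnings(enrichment_ratio(ei, ri))
    data.frame(metabolite = w$name, ref_integral = ri, edit_integral = ei,
               enrichment_pct = as.numeric(pct),
               out_of_range = isTRUE(attr(pct, "out_of_range")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Quantify a whole cohort into an enrichment table
#'
#' Runs [quantify_pair()] on every sample of a rendered cohort (the in-memory
#' list from [render_cohort()]) or a manifest data.frame/CSV with columns
#' `mouse_id, group, region, ref_path, edit_path` pointing at spectrum CSVs.
#' Deterministic given its inputs.
#'
#' @param x Rendered cohort list, manifest data.frame, or manifest CSV path.
#' @param windows Window table.
#' @param ... Passed to [quantify_pair()] (`phase`, `baseline`, ...).
#' @return Long-format enrichment table: one row per (sample, metabolite) with
#'   columns mouse_id, group, region, metabolite, ref_integral, edit_integral,
#'   enrichment_pct, out_of_range, normalized (FALSE).
#' @export
quantify_cohort <- function(x, windows = default_windows(), ...) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("manifest file not found: ", x, call. = FALSE)
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
  }
  if (is.data.frame(x)) {
    need <- c("mouse_id", "group", "region", "ref_path", "edit_path")
    if (!all(need %in% names(x)))
      stop("manifest must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    missing_files <- !file.exists(x$ref_path) | !file.exists(x$edit_path)
    if (any(missing_files))
      stop("missing scan file(s) for sample(s): ",
           paste(x$mouse_id[missing_files], collapse = ", "), call. = FALSE)
    x <- lapply(seq_len(nrow(x)), function(i) {
      list(meta = x[i, c("mouse_id", "group", "region")],
           reference = read_spectrum(x$ref_path[i]),
           edited = read_spectrum(x$edit_path[i]))
    })
  }
  rows <- lapply(x, function(smp) {
    q <- quantify_pair(smp$reference, smp$edited, windows, ...)
    cbind(smp$meta[rep(1, nrow(q)), , drop = FALSE], q, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$normalized <- FALSE
  rownames(out) <- NULL
  out
}

#' Internal-standard normalization and tracer-equilibration QC
#'
#' Per-sample loading correction: each sample's integrals are divided by its
#' TMSP reference integral relative to the cohort mean, removing overall
#' scale differences between samples (enrichment percentages, being ratios,
#' are unchanged). The per-sample TMSP steady-state ratio (edited/reference
#' within the TMSP window, dimensionless) is collected into a QC table whose
#' cohort mean near its nominal value indicates tracer equilibration.
#'
#' @param t Enrichment table from [quantify_cohort()].
#' @return The normalized table, with the QC data.frame (mouse_id, group,
#'   region, loading_factor, steady_ratio) in attribute `"tmsp_qc"`;
#'   retrieve with [tmsp_qc()].
#' @export
normalize_to_tmsp <- function(t) {
  key <- interaction(t$mouse_id, t$region, drop = TRUE)
  is_tmsp <- t$metabolite == "TMSP"
  for (k in levels(key)) {
    if (!any(is_tmsp & key == k))
      stop("sample without a TMSP record: ", k, call. = FALSE)
  }
  tm <- t[is_tmsp, ]
  if (any(tm$ref_integral <= 0))
    stop("non-positive TMSP reference integral for sample(s): ",
         paste(tm$mouse_id[tm$ref_integral <= 0], collapse = ", "),
         call. = FALSE)
  tm_key <- interaction(tm$mouse_id, tm$region, drop = TRUE)
  loading <- tm$ref_integral / mean(tm$ref_integral)
  names(loading) <- as.character(tm_key)
  fac <- loading[as.character(key)]
  t$ref_integral <- t$ref_integral / fac
  t$edit_integral <- t$edit_integral / fac
  t$normalized <- TRUE
  qc <- data.frame(mouse_id = tm$mouse_id, group = tm$group, region = tm$region,
                   loading_factor = unname(loading[as.character(tm_key)]),
                   steady_ratio = tm$edit_integral / tm$ref_integral,
                   stringsAsFactors = FALSE)
  attr(t, "tmsp_qc") <- qc
  t
}

#' @rdname normalize_to_tmsp
#' @export
tmsp_qc <- function(t) {
  qc <- attr(t, "tmsp_qc")
  if (is.null(qc)) stop("no TMSP QC table: run normalize_to_tmsp() first",
                        call. = FALSE)
  qc
}
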