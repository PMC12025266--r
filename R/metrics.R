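#' Electrocorticography frequency bands
#'
#' Default band edges: Delta 0.5-4, Theta 4-8, Alpha 8-13, Beta 13-30,
#' Gamma 30-100 Hz.
#'
#' @return A data.frame with columns name, f_lo, f_hi.
#' @export
band_defs <- function() {
  data.frame(name = c("Delta", "Theta", "Alpha", "Beta", "Gamma"),
             f_lo = c(0.5, 4, 8, 13, 30),
             f_hi = c(4, 8, 13, 30, 100),
             stringsAsFactors = FALSE)
}

#' Novel-object discrimination index
#'
#' DI = (T_novel - T_familiar) / (T_novel + T_familiar), in \[-1, 1\]. Animals
#' with less than `min_total` seconds of total object exploration are excluded
#' (DI is `NA` with attribute `excluded = TRUE`), per the standard 10 s rule.
#'
#' @param t_novel,t_familiar Exploration times in seconds, >= 0.
#' @param min_total Exclusion threshold on total exploration (default 10 s).
#' @return Numeric DI with logical attribute `"excluded"`.
#' @export
discrimination_index <- function(t_novel, t_familiar, min_total = 10) {
  if (t_novel < 0 || t_familiar < 0)
    stop("exploration times must be non-negative", call. = FALSE)
  total <- t_novel + t_familiar
  if (total < min_total)
    return(structure(NA_real_, excluded = TRUE, total = total))
  structure((t_novel - t_familiar) / total, excluded = FALSE, total = total)
}

#' Corner-test turn percentages
#'
#' Left/right turn percentages over valid trials only (invalid trials are
#' dropped from the denominator); the two percentages sum to 100.
#'
#' @param turns Character vector with entries `"left"`, `"right"`, or
#'   `"invalid"`.
#' @return A list: left_pct, right_pct, n_valid.
#' @export
turn_ratio <- function(turns) {
  turns <- match.arg(as.character(turns), c("left", "right", "invalid"),
                     several.ok = TRUE)
  n_left <- sum(turns == "left")
  n_right <- sum(turns == "right")
  n_valid <- n_left + n_right
  if (n_valid == 0) stop("no valid trials", call. = FALSE)
  list(left_pct = 100 * n_left / n_valid,
       right_pct = 100 * n_right / n_valid,
       n_valid = n_valid)
}

#' Censor beam-traversal times at 60 s
#'
#' Trials are capped at `limit` seconds; a fall or timeout event is recorded
#' as the limit. The censoring flag is retained for downstream summaries.
#'
#' @param raw Traversal times in seconds (NA allowed when `event` is set).
#' @param event Per-trial event: `"none"`, `"fall"`, or `"timeout"`.
#' @param limit Censoring limit (default 60 s).
#' @return A data.frame: time, censored.
#' @export
censor_beam_time <- function(raw, event = "none", limit = 60) {
  event <- rep_len(match.arg(as.character(event), c("none", "fall", "timeout"),
                             several.ok = TRUE), length(raw))
  if (any(!is.na(raw) & raw < 0))
    stop("negative traversal time", call. = FALSE)
  time <- ifelse(event != "none", limit, pmin(raw, limit))
  if (any(is.na(time)))
    stop("missing time without a fall/timeout event", call. = FALSE)
  data.frame(time = time,
             censored = event != "none" | (!is.na(raw) & raw >= limit))
}

#' Welch power spectral density
#'
#' Hann-windowed Welch average (default 2 s segments, 50% overlap); one-sided
#' density in signal-units^2/Hz.
#'
#' @param signal Numeric series.
#' @param fs Sampling rate (Hz).
#' @param seg_sec Segment length in seconds (default 2).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return A data.frame: freq (Hz), psd.
#' @export
welch_psd <- function(signal, fs, seg_sec = 2, overlap = 0.5) {
  nper <- round(seg_sec * fs)
  if (length(signal) < nper)
    stop("signal shorter than one Welch segment", call. = FALSE)
  step <- max(1, round(nper * (1 - overlap)))
  starts <- seq(1, length(signal) - nper + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nper - 1) / (nper - 1)))  # Hann
  scale <- fs * sum(w^2)
  nfreq <- floor(nper / 2) + 1
  acc <- numeric(nfreq)
  for (s0 in starts) {
    seg <- signal[s0:(s0 + nper - 1)]
    seg <- (seg - mean(seg)) * w
    P <- abs(stats::fft(seg))^2 / scale
    half <- P[seq_len(nfreq)]
    half[2:(nfreq - 1)] <- 2 * half[2:(nfreq - 1)]  # fold negative freqs
    acc <- acc + half
  }
  data.frame(freq = (seq_len(nfreq) - 1) * fs / nper,
             psd = acc / length(starts))
}

#' Integrated band power
#'
#' Welch PSD integrated over `[f_lo, f_hi]` by the trapezoidal rule with
#' interpolated band edges (an edge shared by two bands contributes half
#' weight to each, so band powers are additive over a partition).
#'
#' @param signal Numeric series (length >= 4 s x fs).
#' @param fs Sampling rate (Hz); must exceed twice the band's upper edge.
#' @param band One-row data.frame with name, f_lo, f_hi (see [band_defs()]).
#' @param seg_sec,overlap Welch parameters.
#' @return Scalar integrated power (signal-units^2).
#' @export
band_power <- function(signal, fs, band, seg_sec = 2, overlap = 0.5) {
  if (fs <= 2 * band$f_hi)
    stop(sprintf("sampling rate %g Hz too low for band %s (needs > %g Hz)",
                 fs, band$name, 2 * band$f_hi), call. = FALSE)
  if (length(signal) < 4 * fs)
    stop("signal shorter than 4 s", call. = FALSE)
  psd <- welch_psd(signal, fs, seg_sec, overlap)
  f <- psd$freq; p <- psd$psd
  lo <- max(band$f_lo, f[1]); hi <- min(band$f_hi, f[length(f)])
  inside <- which(f > lo & f < hi)
  xx <- c(lo, f[inside], hi)
  yy <- c(stats::approx(f, p, lo)$y, p[inside], stats::approx(f, p, hi)$y)
  sum(diff(xx) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
}

#' Mitochondrial membrane-potential index
#'
#' JC-1 aggregate-to-monomer fluorescence ratio; high values indicate a
#' polarized mitochondrial membrane.
#'
#' @param aggregate_fl,monomer_fl Fluorescence intensities; `monomer_fl` must
#'   be positive.
#' @return Scalar ratio, or `NA` with a diagnostic when `monomer_fl <= 0`.
#' @export
mito_potential_index <- function(aggregate_fl, monomer_fl) {
  if (!is.finite(monomer_fl) || monomer_fl <= 0) {
    warning("non-positive monomer fluorescence; index undefined", call. = FALSE)
    return(NA_real_)
  }
  aggregate_fl / monomer_fl
}
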