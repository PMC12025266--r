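# discrete Hilbert transform via the analytic signal (FFT); on an increasing
# ppm axis this maps an absorption Lorentzian onto its dispersion partner
hilbert_transform <- function(y) {
  n <- length(y)
  Y <- stats::fft(y)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Im(stats::fft(Y * h, inverse = TRUE) / n)
}

#' Zero-order phase correction
#'
#' Rotates the spectrum in the complex plane, reconstructing the imaginary
#' channel by Hilbert transform: output = `cos(phi)*y + sin(phi)*H(y)`. With
#' `phi0 = "auto"` the angle is chosen by grid search over \[-pi, pi) at 0.5
#' degree resolution minimizing the sum of squared negative intensities,
#' followed by golden-section refinement to 0.01 degrees — the usual
#' negative-area criterion for absorption-mode spectra. A spectrum simulated
#' with phase error `p` is restored by the automatic choice `phi0 = -p`.
#'
#' @param s A [spectrum1d()].
#' @param phi0 Rotation angle in radians, or `"auto"`.
#' @param phi1 Optional first-order (frequency-linear) phase in radians across
#'   the full sweep width, applied as `phi(x) = phi0 + phi1 * (x - min) /
#'   width`; 0 by default (automatic selection covers `phi0` only).
#' @return The re-phased spectrum; the chosen angle is appended to the
#'   processing log.
#' @export
phase_correct <- function(s, phi0 = "auto", phi1 = 0) {
  stopifnot(inherits(s, "spectrum1d"))
  y <- s$intensity
  h <- hilbert_transform(y)
  auto <- identical(phi0, "auto")
  if (auto) {
    noise <- estimate_noise_sd(s)
    if (all(y == 0) || max(abs(y)) <= 5 * noise)
      stop("phase unidentifiable: no region with |intensity| > 5x noise sd",
           call. = FALSE)
    # score on detrended channels so an additive smooth baseline cannot bias
    # the negative-area criterion; detrending is linear in (y, h), so the
    # quadratic fits are removed once and the rotation applied afterwards
    B <- stats::poly(seq_along(y), degree = 2)
    detrend <- function(v) stats::lm.fit(cbind(1, B), v)$residuals
    yd <- detrend(y)
    hd <- detrend(h)
    obj <- function(phi) {
      v <- cos(phi) * yd + sin(phi) * hd
      sum(pmin(v, 0)^2)
    }
    step <- 0.5 * pi / 180
    grid <- seq(-pi, pi - step, by = step)
    vals <- vapply(grid, obj, numeric(1))
    best <- grid[which.min(vals)]
    # golden-section refinement to 0.01 degrees within +/- one grid step
    gr <- (sqrt(5) - 1) / 2
    a <- best - step; b <- best + step
    tol <- 0.01 * pi / 180
    c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
    fc <- obj(c1); fd <- obj(d1)
    while (b - a > tol) {
      if (fc < fd) {
        b <- d1; d1 <- c1; fd <- fc
        c1 <- b - gr * (b - a); fc <- obj(c1)
      } else {
        a <- c1; c1 <- d1; fc <- fd
        d1 <- a + gr * (b - a); fd <- obj(d1)
      }
    }
    phi0 <- (a + b) / 2
  }
  phi <- phi0
  if (phi1 != 0) {
    frac <- (s$ppm - min(s$ppm)) / diff(range(s$ppm))
    phi <- phi0 + phi1 * frac
  }
  s$intensity <- cos(phi) * y + sin(phi) * h
  log_step(s, "phase_correct",
           list(phi0 = phi0, phi1 = phi1, auto = auto))
}

#' Asymmetric-least-squares baseline correction
#'
#' Estimates a smooth baseline by iteratively reweighted penalized least
#' squares (second-difference penalty `lam`, asymmetry `p_asym`: points above
#' the current baseline get weight `p_asym`, points below `1 - p_asym`), then
#' re-centers the fitted curve by the median residual so that for noisy
#' spectra the baseline tracks the center of the noise rather than its lower
#' envelope. The re-centered baseline is subtracted.
#'
#' The penalty is expressed on the default acquisition grid (16384 points
#' over 20 ppm) and rescaled internally by the fourth power of the actual
#' grid spacing, so a given `lam` corresponds to a fixed smoothing length in
#' ppm whatever the digitization.
#'
#' @param s A [spectrum1d()].
#' @param lam Smoothness penalty (default 1e13 on the reference grid, i.e. a
#'   smoothing length of a couple of ppm: stiff enough that the summed
#'   Lorentzian tails inside crowded peak regions are left in the signal,
#'   soft enough to follow smooth instrumental baselines; smaller values
#'   shave broad peak tails into the baseline).
#' @param p_asym Asymmetry weight in (0, 1) (default 0.001).
#' @param n_iter Reweighting iterations, >= 1 (default 10).
#' @return The baseline-corrected spectrum; the fitted baseline is stored in
#'   attribute `"baseline"`.
#' @export
baseline_correct <- function(s, lam = 1e13, p_asym = 0.001, n_iter = 10) {
  stopifnot(inherits(s, "spectrum1d"), n_iter >= 1)
  y <- s$intensity
  if (any(!is.finite(y)))
    stop("non-finite intensities; cannot fit a baseline", call. = FALSE)
  n <- length(y)
  dx_ref <- 20 / 16383                     # reference grid spacing
  dx <- abs(mean(diff(s$ppm)))
  lam_eff <- lam * (dx_ref / dx)^4         # fixed smoothing length in ppm
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  DtD <- lam_eff * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(n_iter)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    w <- ifelse(y > z, p_asym, 1 - p_asym)
  }
  # second pass: refit on baseline-classified points only (signal points are
  # excluded outright, so peak mass cannot pull the fit), then re-center on
  # the retained residuals; both corrections are exact no-ops on a
  # signal-free spectrum
  r <- y - z
  thr <- 3 * stats::mad(r) + 1e-4 * max(abs(y), 0)
  keep <- r <= thr
  if (sum(keep) > max(20, n / 20)) {
    wk <- as.numeric(keep)
    z <- as.numeric(Matrix::solve(Matrix::Diagonal(n, wk) + DtD, wk * y))
    r <- y - z
  }
  z <- z + stats::median(r[keep])
  s$intensity <- y - z
  s <- log_step(s, "baseline_correct",
                list(lam = lam, p_asym = p_asym, n_iter = n_iter))
  attr(s, "baseline") <- z
  s
}

#' Locate a peak apex within a window
#'
#' Maximum-intensity grid point within the window, refined to sub-grid
#' precision by a 3-point parabolic fit when the apex is interior.
#'
#' @param s A [spectrum1d()].
#' @param window One-row window data.frame (`lo`, `hi`).
#' @return The apex position in ppm.
#' @export
find_apex <- function(s, window) {
  inside <- which(s$ppm >= window$lo & s$ppm <= window$hi)
  if (length(inside) < 3)
    stop("window covers fewer than 3 grid points", call. = FALSE)
  i <- inside[which.max(s$intensity[inside])]
  if (i > 1 && i < length(s$ppm)) {
    y1 <- s$intensity[i - 1]; y2 <- s$intensity[i]; y3 <- s$intensity[i + 1]
    den <- y1 - 2 * y2 + y3
    if (is.finite(den) && den < 0) {
      delta <- 0.5 * (y1 - y3) / den
      if (abs(delta) <= 1) {
        return(s$ppm[i] + delta * (s$ppm[i + 1] - s$ppm[i]))
      }
    }
  }
  s$ppm[i]
}

#' Calibrate the chemical-shift axis to the TMSP resonance
#'
#' Uniformly shifts the ppm axis so the TMSP apex sits at the window's center
#' position. Intensities are untouched (axis-only transform). A warning is
#' emitted when the required shift exceeds `tol` (drift beyond the expected
#' tolerance around known chemical shifts).
#'
#' @param s A [spectrum1d()].
#' @param tmsp_window One-row window data.frame for TMSP (default packaged).
#' @param tol Drift warning threshold in ppm (default 0.05).
#' @return The calibrated spectrum; the applied shift is logged.
#' @export
calibrate_ppm <- function(s, tmsp_window = window_for(default_windows(), "TMSP"),
                          tol = 0.05) {
  stopifnot(inherits(s, "spectrum1d"))
  inside <- which(s$ppm >= tmsp_window$lo & s$ppm <= tmsp_window$hi)
  if (length(inside) < 3)
    stop("TMSP window outside the spectrum axis", call. = FALSE)
  noise <- estimate_noise_sd(s)
  if (max(s$intensity[inside]) <= 5 * noise)
    stop("no detectable TMSP apex in the calibration window", call. = FALSE)
  apex <- find_apex(s, tmsp_window)
  shift <- tmsp_window$center - apex
  if (abs(shift) > tol)
    warning(sprintf("calibration shift %.4f ppm exceeds %.2f ppm tolerance",
                    shift, tol), call. = FALSE)
  s$ppm <- s$ppm + shift
  log_step(s, "calibrate_ppm", list(shift = shift))
}
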