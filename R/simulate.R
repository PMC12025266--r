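#' Lorentzian lineshapes and the analytic window integral
#'
#' Absorption and dispersion Lorentzians with unit integrated area for the
#' absorption mode, and the closed-form integral of the absorption line over a
#' chemical-shift window:
#' \deqn{\int_a^b \frac{\gamma/\pi}{(x-x_0)^2+\gamma^2}\,dx
#'   = \frac{1}{\pi}\left[\arctan\frac{b-x_0}{\gamma} -
#'     \arctan\frac{a-x_0}{\gamma}\right].}
#' The dispersion component uses the Hilbert-transform pair convention on an
#' increasing ppm axis, so zero-order phase mixing is exactly invertible by
#' [phase_correct()].
#'
#' @param x Chemical shifts (ppm).
#' @param x0 Peak center (ppm).
#' @param gamma Half width at half maximum (ppm), > 0.
#' @param lo,hi Window bounds (ppm).
#' @param area Total peak area (defaults to 1).
#' @return Intensities, or for `lorentz_window_area` the scalar analytic area.
#' @export
lorentz_absorption <- function(x, x0, gamma) {
  gamma / (pi * ((x - x0)^2 + gamma^2))
}

#' @rdname lorentz_absorption
#' @export
lorentz_dispersion <- function(x, x0, gamma) {
  (x - x0) / (pi * ((x - x0)^2 + gamma^2))
}

#' @rdname lorentz_absorption
#' @export
lorentz_window_area <- function(x0, gamma, lo, hi, area = 1) {
  area / pi * (atan((hi - x0) / gamma) - atan((lo - x0) / gamma))
}

#' Acquisition parameters for the frequency-domain simulator
#'
#' Defaults follow a 20 ppm sweep; 16384 points is the desk-scale grid (the
#' instrument-scale 65536 is supported). The axis spans `ppm_min` to
#' `ppm_min + spectral_width`, increasing.
#'
#' @param spectral_width Sweep width in ppm, > 0.
#' @param n_points Grid size, >= 1024 (use 65536 to match a 64k acquisition).
#' @param linewidth_gamma Lorentzian half width at half max per peak (ppm).
#' @param noise_sd Additive Gaussian noise sd (intensity units).
#' @param phase0 Zero-order phase error (radians) mixing absorption and
#'   dispersion as `cos(phase0)*A + sin(phase0)*D`.
#' @param baseline_coeffs Polynomial baseline coefficients in increasing powers
#'   of ppm (`c(a0, a1, ...)`); added to both scans.
#' @param ppm_min Lower end of the ppm axis.
#' @return A list of class `acquisition_params`.
#' @export
acquisition_params <- function(spectral_width = 20, n_points = 16384,
                               linewidth_gamma = 0.005, noise_sd = 0,
                               phase0 = 0, baseline_coeffs = 0,
                               ppm_min = -2) {
  stopifnot(spectral_width > 0, n_points >= 1024, linewidth_gamma > 0,
            noise_sd >= 0)
  structure(list(spectral_width = spectral_width, n_points = as.integer(n_points),
                 linewidth_gamma = linewidth_gamma, noise_sd = noise_sd,
                 phase0 = phase0, baseline_coeffs = baseline_coeffs,
                 ppm_min = ppm_min),
            class = "acquisition_params")
}

ppm_axis <- function(acq) {
  seq(acq$ppm_min, acq$ppm_min + acq$spectral_width,
      length.out = acq$n_points)
}

#' Describe one simulated sample
#'
#' Ground-truth amounts and position-specific 13C enrichment fractions for one
#' tissue extract, plus the TMSP internal standard. `tmsp_steady_factor` is the
#' edited/reference area ratio of the TMSP resonance at isotopic steady state
#' (the quantity the tracer-equilibration QC summarizes).
#'
#' @param mouse_id,group,region Cohort labels; `group` is `"control"` or
#'   `"ischemia"`, `region` one of the six dissected brain regions.
#' @param amounts Named non-negative numeric: metabolite abundances (a.u.).
#' @param enrichments Named numeric in `[0, 1]`: 13C fraction per metabolite;
#'   names must match `amounts`.
#' @param tmsp_amount TMSP abundance, > 0.
#' @param tmsp_steady_factor Dimensionless steady-state ratio.
#' @return A list of class `sample_spec`.
#' @export
sample_spec <- function(mouse_id = "M1", group = c("control", "ischemia"),
                        region = "FC", amounts, enrichments,
                        tmsp_amount = 1, tmsp_steady_factor = 1.10) {
  group <- match.arg(group)
  if (is.null(names(amounts)) || is.null(names(enrichments)))
    stop("`amounts` and `enrichments` must be named by metabolite", call. = FALSE)
  missing_e <- setdiff(names(amounts), names(enrichments))
  if (length(missing_e))
    stop("no enrichment given for metabolite(s): ",
         paste(missing_e, collapse = ", "), call. = FALSE)
  enrichments <- enrichments[names(amounts)]
  stopifnot(all(amounts >= 0), all(enrichments >= 0), all(enrichments <= 1),
            tmsp_amount > 0)
  structure(list(mouse_id = mouse_id, group = group, region = region,
                 amounts = amounts, enrichments = enrichments,
                 tmsp_amount = tmsp_amount,
                 tmsp_steady_factor = tmsp_steady_factor),
            class = "sample_spec")
}

#' Brain regions used throughout the package
#' @export
brain_regions <- function() c("FC", "OC", "TC", "STR", "HP", "THA")

#' Default per-metabolite simulation values
#'
#' Baseline 13C enrichment fractions under [3-13C]glucose labeling (chosen so
#' that metabolically related resonances sharing a spectral neighborhood carry
#' similar fractions), and multiplicative ischemia effects on enrichment:
#' 1.0 for the spared pool (Lactate, Ala, Asp3, NAA), ~0.5 for GABA and
#' glutamate, 0.55-0.65 elsewhere, placing most reductions in the 30-50% band.
#'
#' @return Named numeric vectors over the 17 non-TMSP metabolites.
#' @export
default_enrichments <- function() {
  c(Lactate = 0.40, Ala = 0.35, Asp3 = 0.25, NAA = 0.20,
    GABA3 = 0.16, NAAG = 0.21, Glu3 = 0.22, Glx3 = 0.23,
    GABA4 = 0.24, Glu4 = 0.28, Suc = 0.26, Gln4 = 0.26,
    Glx2 = 0.22, `m-Ins` = 0.08, `m-Ins2` = 0.10, `m-Ins3` = 0.10,
    tau = 0.12)
}

#' @rdname default_enrichments
#' @export
default_depletion_factors <- function() {
  f <- c(Lactate = 1.0, Ala = 1.0, Asp3 = 1.0, NAA = 1.0,
         GABA3 = 0.5, GABA4 = 0.5, Glu3 = 0.5, Glu4 = 0.5,
         Glx2 = 0.55, Glx3 = 0.55, Gln4 = 0.6, Suc = 0.6, NAAG = 0.6,
         `m-Ins` = 0.65, `m-Ins2` = 0.65, `m-Ins3` = 0.65, tau = 0.65)
  f[names(default_enrichments())]
}

#' @rdname default_enrichments
#' @export
default_amounts <- function() {
  a <- rep(1, length(default_enrichments()))
  names(a) <- names(default_enrichments())
  a
}

#' Simulate one reference/edited POCE spectrum pair
#'
#' Builds the post-subtraction frequency-domain pair directly from closed-form
#' Lorentzians: each metabolite contributes a peak at its window center with
#' area proportional to its amount in the reference scan (12C+13C) and to
#' amount x enrichment in the edited scan (13C only). TMSP appears in both
#' scans, with edited area `tmsp_steady_factor` times the reference area. A
#' zero-order phase error mixes absorption and dispersion lineshapes, a
#' polynomial baseline is added, and independent Gaussian noise of sd
#' `noise_sd` is drawn per scan.
#'
#' @param sample A [sample_spec()].
#' @param windows Window table from [load_windows()]; every metabolite in the
#'   sample (and TMSP) must have a window whose center lies on the ppm axis.
#' @param acq An [acquisition_params()].
#' @param seed Integer seed for the noise draws (NULL leaves the RNG alone).
#' @param satellites If TRUE, the 13C-bound proton signal is split into a
#'   doublet of two half-area peaks at +/- J/2 around the center (one-bond
#'   1H-13C coupling); off by default since the integration windows are wide
#'   relative to J.
#' @param j_hz,spectrometer_mhz Coupling constant and spectrometer frequency
#'   used to express the satellite splitting in ppm.
#' @return A list with elements `reference` and `edited`, both [spectrum1d()].
#' @export
simulate_spectrum_pair <- function(sample, windows = default_windows(),
                                   acq = acquisition_params(), seed = NULL,
                                   satellites = FALSE, j_hz = 127,
                                   spectrometer_mhz = 500) {
  stopifnot(inherits(sample, "sample_spec"), nrow(windows) >= 1)
  x <- ppm_axis(acq)
  g <- acq$linewidth_gamma
  shape <- function(x0, area) {
    area * (cos(acq$phase0) * lorentz_absorption(x, x0, g) +
            sin(acq$phase0) * lorentz_dispersion(x, x0, g))
  }
  centers <- vapply(names(sample$amounts), function(m) {
    w <- window_for(windows, m)
    w$center
  }, numeric(1))
  tmsp_center <- window_for(windows, "TMSP")$center
  all_centers <- c(centers, tmsp_center)
  if (any(all_centers < min(x) | all_centers > max(x)))
    stop("window center outside the simulated ppm range", call. = FALSE)

  jd <- j_hz / 2 / spectrometer_mhz  # satellite half-splitting in ppm
  ref <- numeric(acq$n_points)
  edt <- numeric(acq$n_points)
  for (i in seq_along(centers)) {
    a <- sample$amounts[i]
    e <- sample$enrichments[i]
    x0 <- centers[i]
    if (satellites) {
      c13 <- function(area) shape(x0 - jd, area / 2) + shape(x0 + jd, area / 2)
      ref <- ref + shape(x0, a * (1 - e)) + c13(a * e)
      edt <- edt + c13(a * e)
    } else {
      ref <- ref + shape(x0, a)
      edt <- edt + shape(x0, a * e)
    }
  }
  ref <- ref + shape(tmsp_center, sample$tmsp_amount)
  edt <- edt + shape(tmsp_center, sample$tmsp_amount * sample$tmsp_steady_factor)

  base <- numeric(acq$n_points)
  for (k in seq_along(acq$baseline_coeffs))
    base <- base + acq$baseline_coeffs[k] * x^(k - 1)
  ref <- ref + base
  edt <- edt + base

  with_seed(seed, {
    if (acq$noise_sd > 0) {
      ref <- ref + stats::rnorm(acq$n_points, sd = acq$noise_sd)
      edt <- edt + stats::rnorm(acq$n_points, sd = acq$noise_sd)
    }
  })
  list(
    reference = spectrum1d(x, ref, "reference", sample$mouse_id),
    edited = spectrum1d(x, edt, "edited", sample$mouse_id)
  )
}

#' Cohort-level simulation design
#'
#' Describes a two-group (control vs ischemia), six-region study: group mean
#' enrichments (ischemia means = baseline x depletion factor), a Gaussian
#' copula giving latent rank correlations between metabolites within a sample,
#' optional per-metabolite region coupling within a mouse, multiplicative
#' lognormal noise with coefficient of variation `noise_cv`, and the TMSP
#' steady-state distribution.
#'
#' @param n_per_group Mice per group, >= 2 (study default 8).
#' @param regions Character vector of region labels (default the six dissected
#'   regions).
#' @param baseline_amounts,baseline_enrichments Named numeric over metabolites.
#' @param depletion_factors Named numeric in (0, 1]: multiplicative ischemia
#'   effect on mean enrichment (1 = spared).
#' @param spared_set Metabolites forced to factor 1 (documentation/QC field;
#'   the packaged defaults already encode it).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise on enrichments and amounts.
#' @param copula_corr Symmetric positive semi-definite matrix with unit
#'   diagonal over the metabolites (latent rank correlations). Default: 0.9
#'   within the spared pool, identity elsewhere.
#' @param region_corr Optional named list: metabolite -> symmetric PSD matrix
#'   over `regions` giving latent coupling of that metabolite across regions
#'   within a mouse (default: no coupling).
#' @param tmsp_mean,tmsp_sd Normal distribution of the per-sample TMSP
#'   steady-state factor.
#' @param tmsp_amount Mean TMSP abundance.
#' @param repair_copula If TRUE, a non-PSD `copula_corr` is repaired to the
#'   nearest correlation matrix instead of raising an error.
#' @param seed Integer seed; cohort generation is a pure function of
#'   (design, seed).
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = 8, regions = brain_regions(),
                          baseline_amounts = default_amounts(),
                          baseline_enrichments = default_enrichments(),
                          depletion_factors = default_depletion_factors(),
                          spared_set = c("Lactate", "Ala", "Asp3", "NAA"),
                          noise_cv = 0.1,
                          copula_corr = NULL,
                          region_corr = NULL,
                          tmsp_mean = 1.10, tmsp_sd = 0.03, tmsp_amount = 1,
                          repair_copula = FALSE, seed = 1) {
  mets <- names(baseline_enrichments)
  stopifnot(n_per_group >= 2, length(mets) >= 1,
            setequal(names(baseline_amounts), mets),
            setequal(names(depletion_factors), mets))
  baseline_amounts <- baseline_amounts[mets]
  depletion_factors <- depletion_factors[mets]
  if (any(depletion_factors <= 0 | depletion_factors > 1))
    stop("depletion_factors must lie in (0, 1]", call. = FALSE)
  if (is.null(copula_corr)) {
    copula_corr <- diag(length(mets))
    dimnames(copula_corr) <- list(mets, mets)
    sp <- intersect(spared_set, mets)
    copula_corr[sp, sp] <- 0.9
    diag(copula_corr) <- 1
  }
  if (is.null(dimnames(copula_corr)))
    dimnames(copula_corr) <- list(mets, mets)
  copula_corr <- copula_corr[mets, mets]
  if (max(abs(copula_corr - t(copula_corr))) > 1e-10)
    stop("copula_corr must be symmetric", call. = FALSE)
  if (max(abs(diag(copula_corr) - 1)) > 1e-10)
    stop("copula_corr must have unit diagonal", call. = FALSE)
  ev <- eigen(copula_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    if (repair_copula) {
      copula_corr <- as.matrix(Matrix::nearPD(copula_corr, corr = TRUE)$mat)
      dimnames(copula_corr) <- list(mets, mets)
    } else {
      stop("copula_corr is not positive semi-definite; ",
           "set repair_copula = TRUE to project to the nearest correlation matrix",
           call. = FALSE)
    }
  }
  structure(list(n_per_group = as.integer(n_per_group), regions = regions,
                 baseline_amounts = baseline_amounts,
                 baseline_enrichments = baseline_enrichments,
                 depletion_factors = depletion_factors,
                 spared_set = spared_set, noise_cv = noise_cv,
                 copula_corr = copula_corr, region_corr = region_corr,
                 tmsp_mean = tmsp_mean, tmsp_sd = tmsp_sd,
                 tmsp_amount = tmsp_amount, seed = as.integer(seed)),
            class = "cohort_design")
}

# lognormal multiplicative noise with unit mean, driven by a standard-normal
# latent z (Gaussian copula): factor = exp(sigma*z - sigma^2/2),
# sigma^2 = log(1 + cv^2)
lognorm_factor <- function(z, cv) {
  if (cv <= 0) return(rep(1, length(z)))
  s <- sqrt(log(1 + cv^2))
  exp(s * z - s^2 / 2)
}

#' Simulate a full cohort with known ground truth
#'
#' Draws `2 * n_per_group * length(regions)` samples. Per-sample metabolite
#' enrichments are generated through a Gaussian copula (latent correlation
#' `copula_corr`, plus optional per-metabolite region coupling within a mouse)
#' with marginal multiplicative lognormal noise of coefficient of variation
#' `noise_cv` around the group mean; ischemia means are baseline x depletion
#' factor. Enrichments are capped at 1. Fully reproducible from `design$seed`.
#'
#' @param design A [cohort_design()].
#' @return A list with `samples` (list of [sample_spec()]) and `ground_truth`,
#'   a data.frame of (mouse_id, group, region, metabolite, amount, enrichment,
#'   enrichment_pct, tmsp_steady_factor).
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  mets <- names(design$baseline_enrichments)
  M <- length(mets)
  R <- length(design$regions)
  groups <- c("control", "ischemia")

  # joint latent covariance over (region, metabolite) cells within one mouse:
  # copula_corr between metabolites in the same region, region_corr[[m]]
  # between regions for the same metabolite, 0 when both differ
  Sigma <- diag(R * M)
  idx <- function(r, m) (r - 1L) * M + m
  for (r in seq_len(R)) {
    Sigma[idx(r, seq_len(M)), idx(r, seq_len(M))] <- design$copula_corr
  }
  if (!is.null(design$region_corr)) {
    for (m_name in names(design$region_corr)) {
      m <- match(m_name, mets)
      if (is.na(m)) stop("region_corr names a metabolite without a window: ",
                         m_name, call. = FALSE)
      Rc <- design$region_corr[[m_name]]
      if (is.null(dimnames(Rc))) dimnames(Rc) <- list(design$regions, design$regions)
      Rc <- Rc[design$regions, design$regions]
      for (r1 in seq_len(R)) for (r2 in seq_len(R)) {
        if (r1 != r2) Sigma[idx(r1, m), idx(r2, m)] <- Rc[r1, r2]
      }
    }
  }
  ev <- eigen(Sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    Sigma <- as.matrix(Matrix::nearPD(Sigma, corr = TRUE)$mat)
    ev <- eigen(Sigma, symmetric = TRUE)
  }
  Lr <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), R * M)

  samples <- list()
  gt <- vector("list", 2L * design$n_per_group)
  with_seed(design$seed, {
    k <- 0L
    for (g in groups) {
      dep <- if (g == "ischemia") design$depletion_factors else
        stats::setNames(rep(1, M), mets)
      means <- design$baseline_enrichments * dep
      for (i in seq_len(design$n_per_group)) {
        k <- k + 1L
        mouse <- sprintf("%s_M%02d", ifelse(g == "control", "C", "I"), i)
        z <- as.numeric(Lr %*% stats::rnorm(R * M))          # latent copula draw
        z_amt <- stats::rnorm(R * M)                         # independent amount noise
        tmsp_f <- stats::rnorm(R, design$tmsp_mean, design$tmsp_sd)
        tmsp_a <- design$tmsp_amount *
          lognorm_factor(stats::rnorm(R), design$noise_cv)
        rows <- vector("list", R)
        for (r in seq_len(R)) {
          zz <- z[idx(r, seq_len(M))]
          enr <- pmin(means * lognorm_factor(zz, design$noise_cv), 1)
          amt <- design$baseline_amounts *
            lognorm_factor(z_amt[idx(r, seq_len(M))], design$noise_cv)
          names(enr) <- mets
          names(amt) <- mets
          sm <- sample_spec(mouse_id = mouse, group = g,
                            region = design$regions[r],
                            amounts = amt, enrichments = enr,
                            tmsp_amount = tmsp_a[r],
                            tmsp_steady_factor = tmsp_f[r])
          samples[[length(samples) + 1L]] <- sm
          rows[[r]] <- data.frame(
            mouse_id = mouse, group = g, region = design$regions[r],
            metabolite = mets, amount = unname(amt), enrichment = unname(enr),
            enrichment_pct = 100 * unname(enr),
            tmsp_steady_factor = tmsp_f[r],
            stringsAsFactors = FALSE)
        }
        gt[[k]] <- do.call(rbind, rows)
      }
    }
  })
  list(samples = samples, ground_truth = do.call(rbind, gt))
}

#' Render a simulated cohort into spectrum pairs
#'
#' @param cohort Output of [simulate_cohort()].
#' @param windows Window table.
#' @param acq An [acquisition_params()]; its `noise_sd` applies per scan.
#' @param seed Base seed; sample `i` uses `seed + i`.
#' @return A list, one element per sample, each with `meta` (mouse_id, group,
#'   region), `reference` and `edited` spectra.
#' @export
render_cohort <- function(cohort, windows = default_windows(),
                          acq = acquisition_params(), seed = 1) {
  lapply(seq_along(cohort$samples), function(i) {
    sm <- cohort$samples[[i]]
    pair <- simulate_spectrum_pair(sm, windows, acq, seed = seed + i)
    list(meta = data.frame(mouse_id = sm$mouse_id, group = sm$group,
                           region = sm$region, stringsAsFactors = FALSE),
         reference = pair$reference, edited = pair$edited)
  })
}

#' Write a rendered cohort to disk
#'
#' Writes one `ppm,intensity` CSV (plus JSON sidecar) per scan and a manifest
#' CSV with columns mouse_id, group, region, ref_path, edit_path.
#'
#' @param rendered Output of [render_cohort()].
#' @param outdir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(rendered, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(rendered, function(smp) {
    stem <- sprintf("%s_%s_%s", smp$meta$mouse_id, smp$meta$group,
                    smp$meta$region)
    ref_path <- file.path(outdir, paste0(stem, "_reference.csv"))
    edit_path <- file.path(outdir, paste0(stem, "_edited.csv"))
    write_spectrum(smp$reference, ref_path)
    write_spectrum(smp$edited, edit_path)
    cbind(smp$meta, data.frame(ref_path = ref_path, edit_path = edit_path,
                               stringsAsFactors = FALSE))
  })
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(outdir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}
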