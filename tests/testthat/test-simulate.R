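acq0 <- acquisition_params()  # noise-free defaults

test_that("zero enrichment and zero TMSP steady factor empty the edited scan", {
  sm <- sample_spec(amounts = c(Lactate = 1, NAA = 2),
                    enrichments = c(Lactate = 0, NAA = 0),
                    tmsp_steady_factor = 0)
  pair <- simulate_spectrum_pair(sm, fix_windows, acq0)
  for (i in seq_len(nrow(fix_windows))) {
    expect_equal(integrate_window(pair$edited, fix_windows[i, ]), 0)
  }
})

test_that("full labeling makes edited and reference scans identical", {
  mets <- names(default_amounts())
  sm <- sample_spec(amounts = default_amounts(),
                    enrichments = stats::setNames(rep(1, length(mets)), mets),
                    tmsp_steady_factor = 1)
  pair <- simulate_spectrum_pair(sm, fix_windows, acq0)
  expect_identical(pair$reference$intensity, pair$edited$intensity)
})

test_that("window-integral ratio reproduces the enrichment against the analytic oracle", {
  # TMSP steady factor set to the same fraction so the distant TMSP tail
  # cancels exactly in the ratio
  pair <- simulate_spectrum_pair(lactate_sample(0.42, tmsp_steady = 0.42),
                                 fix_windows, acq0)
  wl <- fix_windows[fix_windows$name == "Lactate", ]
  r <- integrate_window(pair$edited, wl) / integrate_window(pair$reference, wl)
  expect_equal(r, 0.42, tolerance = 1e-6)
  # and the reference integral itself matches the closed arctan form
  expect_equal(integrate_window(pair$reference, wl),
               analytic_area(wl$center, acq0$linewidth_gamma, wl$lo, wl$hi),
               tolerance = 5e-4)
})

test_that("trapezoidal window integrals track the analytic form across all 18 windows", {
  pair <- simulate_spectrum_pair(default_sample(), fix_windows, acq0)
  g <- acq0$linewidth_gamma
  amounts <- c(default_amounts(), TMSP = 1)
  centers <- stats::setNames(fix_windows$center, fix_windows$name)
  for (i in seq_len(nrow(fix_windows))) {
    w <- fix_windows[i, ]
    # analytic total: every peak's tail contributes to every window
    truth <- sum(vapply(names(amounts), function(m)
      analytic_area(centers[m], g, w$lo, w$hi, amounts[m]), numeric(1)))
    expect_equal(integrate_window(pair$reference, w), truth,
                 tolerance = 5e-3, label = w$name)
  }
})

test_that("noise-free edited integral never exceeds the reference integral", {
  set.seed(11)
  for (rep in 1:5) {
    mets <- names(default_amounts())
    e <- stats::setNames(runif(length(mets)), mets)
    sm <- sample_spec(amounts = default_amounts(), enrichments = e,
                      tmsp_steady_factor = 1)
    pair <- simulate_spectrum_pair(sm, fix_windows, acq0)
    for (i in seq_len(nrow(fix_windows))) {
      w <- fix_windows[i, ]
      expect_lte(integrate_window(pair$edited, w),
                 integrate_window(pair$reference, w) + 1e-12)
    }
  }
})

test_that("the spectrum is linear in the amount maps", {
  e <- c(Lactate = 0.4, NAA = 0.2)
  s1 <- sample_spec(amounts = c(Lactate = 1, NAA = 0), enrichments = e)
  s2 <- sample_spec(amounts = c(Lactate = 0, NAA = 2), enrichments = e)
  s12 <- sample_spec(amounts = c(Lactate = 1, NAA = 2), enrichments = e)
  p1 <- simulate_spectrum_pair(s1, fix_windows, acq0)
  p2 <- simulate_spectrum_pair(s2, fix_windows, acq0)
  p12 <- simulate_spectrum_pair(s12, fix_windows, acq0)
  # TMSP appears in every simulation; subtract one copy of it
  tm <- simulate_spectrum_pair(
    sample_spec(amounts = c(Lactate = 0), enrichments = c(Lactate = 0)),
    fix_windows, acq0)
  expect_equal(p1$reference$intensity + p2$reference$intensity -
                 tm$reference$intensity,
               p12$reference$intensity, tolerance = 1e-12)
})

test_that("simulation errors name the offending metabolite or window", {
  sm <- sample_spec(amounts = c(Unknown = 1), enrichments = c(Unknown = 0.5))
  expect_error(simulate_spectrum_pair(sm, fix_windows, acq0), "Unknown")
  far <- data.frame(name = c("TMSP", "X"), center = c(0.004, 30),
                    lo = c(-0.097, 29), hi = c(0.106, 31))
  smx <- sample_spec(amounts = c(X = 1), enrichments = c(X = 0.5))
  expect_error(simulate_spectrum_pair(smx, far, acq0), "ppm range")
})

test_that("carbon satellite doublets conserve area and vacate the central line", {
  acq <- acquisition_params(n_points = 32768)
  on <- simulate_spectrum_pair(lactate_sample(0.4), fix_windows, acq,
                               satellites = TRUE)
  off <- simulate_spectrum_pair(lactate_sample(0.4), fix_windows, acq)
  wl <- fix_windows[fix_windows$name == "Lactate", ]
  full_axis <- data.frame(lo = min(on$edited$ppm), hi = max(on$edited$ppm))
  # total 13C area is conserved when the doublet replaces the singlet
  expect_equal(integrate_window(on$edited, full_axis),
               integrate_window(off$edited, full_axis), tolerance = 1e-4)
  # the 13C signal moves out to +/- J/2: the central window loses > 95% of it
  expect_lt(integrate_window(on$edited, wl),
            0.05 * integrate_window(off$edited, wl))
})

test_that("cohort generation is a pure function of design and seed", {
  d <- cohort_design(n_per_group = 2, seed = 9)
  expect_identical(simulate_cohort(d), simulate_cohort(d))
  d2 <- cohort_design(n_per_group = 2, seed = 10)
  expect_false(identical(simulate_cohort(d), simulate_cohort(d2)))
})

test_that("noise-free cohorts hit the group means exactly", {
  d <- cohort_design(n_per_group = 2, noise_cv = 0, tmsp_sd = 0, seed = 3)
  gt <- simulate_cohort(d)$ground_truth
  truth_c <- default_enrichments()
  truth_i <- truth_c * default_depletion_factors()
  ctrl <- gt[gt$group == "control", ]
  isch <- gt[gt$group == "ischemia", ]
  expect_equal(ctrl$enrichment, unname(truth_c[ctrl$metabolite]))
  expect_equal(isch$enrichment, unname(truth_i[isch$metabolite]))
  expect_true(all(gt$tmsp_steady_factor == 1.10))
})

test_that("cohort invariants are validated", {
  expect_error(cohort_design(n_per_group = 1), "n_per_group")
  bad <- default_depletion_factors(); bad["Suc"] <- 0
  expect_error(cohort_design(depletion_factors = bad), "0, 1")
  C <- identity_copula()
  C["Lactate", "Ala"] <- C["Ala", "Lactate"] <- 0.99
  C["Lactate", "NAA"] <- C["NAA", "Lactate"] <- 0.99
  C["Ala", "NAA"] <- C["NAA", "Ala"] <- -0.9          # impossible triangle
  expect_error(cohort_design(copula_corr = C), "nearest")
  expect_s3_class(cohort_design(copula_corr = C, repair_copula = TRUE),
                  "cohort_design")
})

test_that("a planted latent rank correlation is recovered across seeds", {
  # Monte-Carlo over seeds; empirical Spearman of the planted pair should sit
  # in [0.80, 0.98] nearly always at 48 observations
  C <- pair_copula(r = 0.92)
  inside <- 0L
  n_seeds <- 200
  for (s in seq_len(n_seeds)) {
    d <- cohort_design(copula_corr = C, seed = 20000 + s)
    gt <- simulate_cohort(d)$ground_truth
    ctrl <- gt[gt$group == "control", ]
    x <- ctrl$enrichment[ctrl$metabolite == "Lactate"]
    y <- ctrl$enrichment[ctrl$metabolite == "Ala"]
    rho <- cor(rank(x), rank(y))  # brute-force rank correlation
    if (rho >= 0.80 && rho <= 0.98) inside <- inside + 1L
  }
  expect_gte(inside / n_seeds, 0.95)
})
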