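# small helper: long table from a matrix of observations x metabolites
long_table <- function(mat, group = "control") {
  obs <- expand.grid(mouse_id = sprintf("M%02d", 1:(nrow(mat) / 6)),
                     region = brain_regions(), stringsAsFactors = FALSE)
  do.call(rbind, lapply(colnames(mat), function(m)
    data.frame(mouse_id = obs$mouse_id, group = group, region = obs$region,
               metabolite = m, enrichment_pct = mat[, m],
               stringsAsFactors = FALSE)))
}

test_that("Spearman edges are invariant under monotone transforms", {
  set.seed(21)
  x <- rnorm(48)
  mat <- cbind(A = x, B = exp(2 * x) + 5, C = rnorm(48))
  edges <- metabolite_network(long_table(mat), "control")
  ab <- edges[edges$item_a == "A" & edges$item_b == "B", ]
  expect_equal(ab$rho, 1.0)
  expect_true(ab$retained)
  # transforming C monotonically changes nothing
  mat2 <- mat; mat2[, "C"] <- log(mat[, "C"] + 100)
  edges2 <- metabolite_network(long_table(mat2), "control")
  expect_equal(edges$rho, edges2$rho, tolerance = 1e-12)
})

test_that("constant series yield missing correlations with a diagnostic", {
  mat <- cbind(A = rnorm(48), B = rep(1, 48))
  expect_warning(edges <- metabolite_network(long_table(mat), "control"),
                 "constant")
  expect_true(is.na(edges$rho))
  expect_false(edges$retained)
})

test_that("BH q-values dominate and are monotone in the raw p-values", {
  set.seed(31)
  mat <- matrix(rnorm(48 * 8), 48, dimnames = list(NULL, LETTERS[1:8]))
  edges <- metabolite_network(long_table(mat), "control")
  expect_true(all(edges$q_fdr >= edges$p_raw))
  expect_true(all(edges$q_fdr >= 0 & edges$q_fdr <= 1))
  ord <- order(edges$p_raw)
  expect_true(all(diff(edges$q_fdr[ord]) >= -1e-12))
})

test_that("independent metabolites produce essentially no retained edges", {
  retained <- integer(200)
  for (s in 1:200) {
    d <- cohort_design(copula_corr = identity_copula(), seed = 40000 + s)
    gt <- simulate_cohort(d)$ground_truth
    retained[s] <- sum(metabolite_network(gt, "control")$retained)
  }
  expect_lte(mean(retained), 0.05)
})

test_that("a strongly coupled pair is retained with high power", {
  hits <- 0L
  for (s in 1:100) {
    d <- cohort_design(copula_corr = pair_copula(r = 0.92), seed = 50000 + s)
    gt <- simulate_cohort(d)$ground_truth
    edges <- metabolite_network(gt, "control")
    e <- edges[edges$item_a == "Ala" & edges$item_b == "Lactate", ]
    if (e$retained && e$rho >= 0.80) hits <- hits + 1L
  }
  expect_gte(hits, 90)
})

test_that("a metabolite identical across regions correlates perfectly everywhere", {
  mice <- sprintf("M%02d", 1:8)
  per_mouse <- stats::setNames(rnorm(8, 20, 3), mice)
  t <- expand.grid(mouse_id = mice, region = brain_regions(),
                   stringsAsFactors = FALSE)
  t$group <- "control"; t$metabolite <- "Lactate"
  t$enrichment_pct <- per_mouse[t$mouse_id]
  rn <- regional_network(t, "Lactate", "control")
  off <- rn$rho[upper.tri(rn$rho)]
  expect_true(all(off == 1))
  expect_true(all(diag(rn$rho) == 1))
  expect_equal(rn$rho, t(rn$rho))
})

test_that("regionally independent noise retains essentially nothing", {
  retained <- integer(100)
  for (s in 1:100) {
    d <- cohort_design(copula_corr = identity_copula(), seed = 60000 + s)
    gt <- simulate_cohort(d)$ground_truth
    retained[s] <- sum(regional_network(gt, "Glu4", "control")$edges$retained)
  }
  expect_lte(mean(retained), 0.05)
})

test_that("a planted cortex-striatum-thalamus coupling dominates the regional network", {
  regions <- brain_regions()
  trio <- c("FC", "STR", "THA")
  Rm <- diag(6); dimnames(Rm) <- list(regions, regions)
  Rm[trio, trio] <- 0.9; diag(Rm) <- 1
  ok <- 0L
  for (s in 1:100) {
    d <- cohort_design(n_per_group = 20, copula_corr = identity_copula(),
                       region_corr = list(Lactate = Rm), seed = 7000 + s)
    gt <- simulate_cohort(d)$ground_truth
    e <- regional_network(gt, "Lactate", "control")$edges
    planted <- apply(e[, c("item_a", "item_b")], 1,
                     function(p) all(p %in% trio))
    subset_ok <- !any(e$retained) || all(planted[e$retained])
    top3_ok <- all(planted[order(-abs(e$rho))[1:3]])
    if (subset_ok && top3_ok) ok <- ok + 1L
  }
  expect_gte(ok, 85)
})

test_that("hub scores follow the closed form and handle empty networks", {
  edges <- data.frame(item_a = c("A", "A", "B"), item_b = c("B", "C", "C"),
                      rho = c(0.9, -0.9, 0.9), q_fdr = 0.001,
                      retained = TRUE)
  hs <- hub_scores(edges)
  expect_equal(hs$degree, c(2, 2, 2))
  expect_equal(hs$strength, c(1.8, 1.8, 1.8))

  none <- edges; none$retained <- FALSE
  expect_warning(hs0 <- hub_scores(none), "empty")
  expect_true(all(hs0$degree == 0) && all(hs0$strength == 0))
})

test_that("a planted thalamic hub is top-ranked by strength", {
  regions <- brain_regions()
  a <- stats::setNames(c(rep(0.75, 5), 1.0), regions)
  Rh <- outer(a, a); diag(Rh) <- 1  # one-factor structure, THA loading 1
  top <- 0L
  for (s in 1:100) {
    d <- cohort_design(n_per_group = 24, copula_corr = identity_copula(),
                       region_corr = list(Lactate = Rh), seed = 8100 + s)
    gt <- simulate_cohort(d)$ground_truth
    rn <- regional_network(gt, "Lactate", "control",
                           rho_min = 0.4, q_max = 0.05)
    hs <- suppressWarnings(hub_scores(rn, nodes = regions))
    if (hs$node[1] == "THA") top <- top + 1L
  }
  expect_gte(top, 95)
})

test_that("edge lists export to GraphML", {
  set.seed(77)
  x <- rnorm(48)
  mat <- cbind(A = x, B = x + rnorm(48, sd = 0.05), C = rnorm(48))
  edges <- metabolite_network(long_table(mat), "control")
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(edges, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), sum(edges$retained))
})
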