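# Spearman rho with a two-sided p-value: exact permutation distribution for
# n <= 9 without ties (via cor.test), t approximation otherwise
spearman_test <- function(x, y, n_min = 4) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < n_min) return(list(rho = NA_real_, p = NA_real_, n = n))
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant series; Spearman correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(x, y, method = "spearman")
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 9 && !ties) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  } else {
    r <- min(max(rho, -1 + 1e-12), 1 - 1e-12)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    if (abs(rho) >= 1) p <- 0
  }
  list(rho = rho, p = p, n = n)
}

#' Inter-metabolite Spearman correlation network
#'
#' For every unordered metabolite pair (TMSP excluded), the Spearman rank
#' correlation over the group's observations — by default one observation per
#' (mouse, region) sample — with pairwise-complete deletion, a two-sided
#' p-value (exact permutation null for n <= 9 without ties, t approximation
#' otherwise), Benjamini-Hochberg adjustment over all pairs jointly, and an
#' edge-retention flag requiring both |rho| > `rho_min` and q < `q_max`
#' (strict inequalities).
#'
#' @param t Enrichment table (from [quantify_cohort()] or ground truth from
#'   [simulate_cohort()]) with columns mouse_id, group, region, metabolite,
#'   enrichment_pct.
#' @param group Group label to subset on (`"control"` or `"ischemia"`).
#' @param rho_min,q_max Retention thresholds (defaults 0.8 and 0.01).
#' @param observation `"sample"` (mouse x region records, n up to 48) or
#'   `"mouse"` (region-averaged per mouse).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param include_tmsp Keep the TMSP internal-standard records as a network
#'   node (default FALSE: only cerebral metabolites are correlated).
#' @return A data.frame of edges: item_a, item_b, rho, n_obs, p_raw, q_fdr,
#'   retained.
#' @export
metabolite_network <- function(t, group = "control", rho_min = 0.8,
                               q_max = 0.01,
                               observation = c("sample", "mouse"),
                               method = c("spearman", "pearson"),
                               include_tmsp = FALSE) {
  observation <- match.arg(observation)
  method <- match.arg(method)
  t <- t[t$group == group & (include_tmsp | t$metabolite != "TMSP"), ]
  if (!nrow(t)) stop("no records for group: ", group, call. = FALSE)
  if (observation == "mouse") {
    agg <- stats::aggregate(enrichment_pct ~ mouse_id + metabolite, t, mean)
    t <- agg
    t$obs <- t$mouse_id
  } else {
    t$obs <- paste(t$mouse_id, t$region, sep = ".")
  }
  wide <- stats::reshape(t[, c("obs", "metabolite", "enrichment_pct")],
                         idvar = "obs", timevar = "metabolite",
                         direction = "wide")
  mets <- sub("^enrichment_pct\\.", "", names(wide)[-1])
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- mets
  pairs <- utils::combn(sort(mets), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    st <- if (method == "spearman") {
      spearman_test(mat[, a], mat[, b])
    } else {
      ok <- is.finite(mat[, a]) & is.finite(mat[, b])
      ct <- stats::cor.test(mat[ok, a], mat[ok, b], method = "pearson")
      list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
    }
    data.frame(item_a = a, item_b = b, rho = st$rho, n_obs = st$n,
               p_raw = st$p, stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, rows)
  edges$q_fdr <- stats::p.adjust(edges$p_raw, method = "BH")
  edges$retained <- !is.na(edges$rho) & abs(edges$rho) > rho_min &
    !is.na(edges$q_fdr) & edges$q_fdr < q_max
  edges
}

#' Inter-regional correlation matrix for one metabolite
#'
#' Spearman rank correlation across mice of one metabolite's enrichment for
#' every region pair, BH-adjusted across the region pairs.
#'
#' @param t Enrichment table.
#' @param metabolite Metabolite name.
#' @param group Group label.
#' @param rho_min,q_max Retention thresholds.
#' @return A list of class `regional_corr` with `metabolite`, symmetric
#'   matrices `rho`, `p`, `q` (unit diagonal for rho), and an `edges`
#'   data.frame like [metabolite_network()].
#' @export
regional_network <- function(t, metabolite, group = "control",
                             rho_min = 0.8, q_max = 0.01) {
  t <- t[t$group == group & t$metabolite == metabolite, ]
  if (!nrow(t)) stop("no records for metabolite ", metabolite, " in group ",
                     group, call. = FALSE)
  regions <- unique(t$region)
  counts <- table(t$region)
  if (length(unique(counts)) > 1)
    warning("unbalanced regions; using pairwise-complete mice", call. = FALSE)
  if (min(counts) < 4)
    stop("fewer than 4 mice per region", call. = FALSE)
  wide <- stats::reshape(t[, c("mouse_id", "region", "enrichment_pct")],
                         idvar = "mouse_id", timevar = "region",
                         direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- sub("^enrichment_pct\\.", "", colnames(mat))
  mat <- mat[, regions, drop = FALSE]
  R <- length(regions)
  rho <- diag(1, R); pmatr <- matrix(NA_real_, R, R)
  dimnames(rho) <- dimnames(pmatr) <- list(regions, regions)
  pairs <- utils::combn(regions, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    st <- spearman_test(mat[, a], mat[, b])
    data.frame(item_a = a, item_b = b, rho = st$rho, n_obs = st$n,
               p_raw = st$p, stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, rows)
  edges$q_fdr <- stats::p.adjust(edges$p_raw, method = "BH")
  edges$retained <- !is.na(edges$rho) & abs(edges$rho) > rho_min &
    !is.na(edges$q_fdr) & edges$q_fdr < q_max
  qmatr <- pmatr
  for (k in seq_len(nrow(edges))) {
    a <- edges$item_a[k]; b <- edges$item_b[k]
    rho[a, b] <- rho[b, a] <- edges$rho[k]
    pmatr[a, b] <- pmatr[b, a] <- edges$p_raw[k]
    qmatr[a, b] <- qmatr[b, a] <- edges$q_fdr[k]
  }
  structure(list(metabolite = metabolite, rho = rho, p = pmatr, q = qmatr,
                 edges = edges),
            class = "regional_corr")
}

#' Node degree and strength over retained edges
#'
#' Degree = number of retained edges at a node; strength = sum of |rho| over
#' its retained edges. Nodes with no retained edges score zero.
#'
#' @param edges Edge data.frame from [metabolite_network()] or a
#'   `regional_corr` object.
#' @param nodes Optional node universe (defaults to every item appearing in
#'   `edges`).
#' @return A data.frame (node, degree, strength) sorted by decreasing
#'   strength, ties broken by node name.
#' @export
hub_scores <- function(edges, nodes = NULL) {
  if (inherits(edges, "regional_corr")) edges <- edges$edges
  if (is.null(nodes)) nodes <- sort(unique(c(edges$item_a, edges$item_b)))
  kept <- edges[edges$retained, , drop = FALSE]
  if (!nrow(kept))
    warning("empty network: all hub scores are zero", call. = FALSE)
  deg <- stats::setNames(numeric(length(nodes)), nodes)
  str <- deg
  for (k in seq_len(nrow(kept))) {
    for (nd in c(kept$item_a[k], kept$item_b[k])) {
      deg[nd] <- deg[nd] + 1
      str[nd] <- str[nd] + abs(kept$rho[k])
    }
  }
  out <- data.frame(node = nodes, degree = unname(deg),
                    strength = unname(str), stringsAsFactors = FALSE)
  out[order(-out$strength, out$node), , drop = FALSE]
}

#' Export an edge list as GraphML
#'
#' @param edges Edge data.frame from [metabolite_network()].
#' @param path Output file.
#' @param retained_only Keep only retained edges (default TRUE).
#' @return `path`, invisibly.
#' @export
write_graphml <- function(edges, path, retained_only = TRUE) {
  e <- if (retained_only) edges[edges$retained, , drop = FALSE] else edges
  nodes <- sort(unique(c(edges$item_a, edges$item_b)))
  g <- igraph::graph_from_data_frame(
    e[, c("item_a", "item_b", "rho", "q_fdr")],
    directed = FALSE,
    vertices = data.frame(name = nodes))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
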