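# Regulation statistics: the per-degree down-regulation curve, concordance,
# degree-distribution skew, per-disease down-regulation, and Monte-Carlo
# confidence envelopes / permutation p-values against the null ensembles.

#' Per-degree down-regulation curve
#'
#' For each gene degree k, the proportion of down-regulated edges among
#' edges incident to genes of degree k (X = degree, Y = proportion).
#' Degrees represented by fewer than `min_genes_per_degree` genes are
#' reported in `excluded` and omitted from the curve, mirroring the study's
#' exclusion of its two degree-5 genes as too few for statistical
#' comparison.
#'
#' @param net a `signed_bipartite` network with at least one edge.
#' @param min_genes_per_degree minimum genes a degree needs to enter the
#'   curve (default 3).
#' @return An object of class `regulation_curve`: data.frame `curve` with
#'   columns `degree`, `prop_down`, `n_edges`, `n_genes`; data.frame
#'   `excluded` (`degree`, `n_genes`); and `min_genes_per_degree`.
#' @export
down_regulation_curve <- function(net, min_genes_per_degree = 3) {
  if (nrow(net$edges) == 0)
    stop("network has no edges: the curve is undefined", call. = FALSE)
  gd <- degree_table(net)$gene_degree
  edge_deg <- gd[net$edges$gene]
  down <- net$edges$sign == "down"

  degs <- sort(unique(as.integer(edge_deg)))
  n_e <- vapply(degs, function(k) sum(edge_deg == k), integer(1))
  n_d <- vapply(degs, function(k) sum(down[edge_deg == k]), integer(1))
  n_g <- vapply(degs, function(k) sum(gd == k), integer(1))

  keep <- n_g >= min_genes_per_degree
  structure(list(
    curve = data.frame(degree = degs[keep],
                       prop_down = n_d[keep] / n_e[keep],
                       n_edges = n_e[keep], n_genes = n_g[keep]),
    excluded = data.frame(degree = degs[!keep], n_genes = n_g[!keep]),
    min_genes_per_degree = min_genes_per_degree
  ), class = "regulation_curve")
}

#' @export
print.regulation_curve <- function(x, ...) {
  cat("Down-regulation curve (proportion of down edges by gene degree)\n")
  print(x$curve, row.names = FALSE)
  if (nrow(x$excluded) > 0)
    cat(sprintf("excluded (fewer than %d genes): %s\n", x$min_genes_per_degree,
                paste(sprintf("degree %d (%d genes)", x$excluded$degree,
                              x$excluded$n_genes), collapse = ", ")))
  invisible(x)
}

#' Within-gene regulation concordance
#'
#' The fraction of genes of degree >= 2 whose incident edges all carry one
#' sign (the gene is up-regulated in all its diseases, or down-regulated in
#' all of them). The study network showed 100% concordance.
#'
#' @param net a `signed_bipartite` network with at least one gene of
#'   degree >= 2 (otherwise the statistic is undefined and an error is
#'   raised).
#' @return A proportion in `[0, 1]`.
#' @export
concordance <- function(net) {
  f <- factor(net$edges$gene)
  k <- tabulate(f)
  if (!any(k >= 2))
    stop("no gene of degree >= 2: concordance is undefined", call. = FALSE)
  ndown <- rowsum((net$edges$sign == "down") + 0, f, reorder = TRUE)
  keep <- k >= 2
  mean(ndown[keep] == 0 | ndown[keep] == k[keep])
}

#' Sample skewness (moment estimator g1)
#'
#' `g1 = m3 / m2^(3/2)` with central moments `m_j = mean((x - mean(x))^j)`.
#'
#' @param x numeric vector.
#' @return Skewness; error if `x` is constant.
#' @export
sample_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0)
    stop("skewness undefined for a constant sequence", call. = FALSE)
  mean((x - m)^3) / m2^1.5
}

# Statistic registry for the degree-distribution test.
degree_statistics <- list(
  skewness = function(deg) sample_skewness(deg),
  max_degree = function(deg) max(deg),
  gini = function(deg) {
    x <- sort(deg)
    n <- length(x)
    if (sum(x) == 0) return(0)
    sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
  }
)

mc_test_result <- function(statistic, p_value, method, B, data_name,
                           extra = NULL) {
  out <- c(list(statistic = statistic, p.value = p_value, method = method,
                data.name = data_name, n_replicates = B), extra)
  class(out) <- "htest"
  out
}

#' Right-skew test of the gene degree distribution
#'
#' Tests whether the gene degree distribution is more right-skewed than in
#' uniformly rewired networks of the same size (same node sets and edge
#' count, edges placed at random). One-sided add-one Monte-Carlo p-value
#' for observed >= null.
#'
#' @param net a `signed_bipartite` network with >= 2 distinct gene degrees.
#' @param n_replicates number of null networks B (default 1000).
#' @param seed root seed.
#' @param statistic `"skewness"` (default, moment estimator g1),
#'   `"max_degree"`, `"gini"`, or a function of the gene degree vector.
#' @return An `htest`-like result with `statistic`, `p.value`,
#'   `null_values`.
#' @export
degree_distribution_test <- function(net, n_replicates = 1000, seed = 1L,
                                     statistic = "skewness") {
  fn <- if (is.function(statistic)) statistic
        else degree_statistics[[match.arg(statistic,
                                          names(degree_statistics))]]
  deg_stat <- function(x) fn(as.numeric(degree_table(x)$gene_degree))
  obs <- deg_stat(net)
  null <- null_ensemble(net, deg_stat, scheme = "uniform_rewire",
                        n_replicates = n_replicates, seed = seed)
  mc_test_result(c(statistic = obs),
                 mc_p_value(obs, null, "greater"),
                 "Gene degree distribution vs. uniformly rewired networks",
                 n_replicates, deparse(substitute(net)),
                 list(null_values = null))
}

#' Test for diseases with mostly down-regulated genes
#'
#' Statistic: the number of diseases whose incident edges are mostly
#' down-regulated (down-fraction strictly above `threshold`). Null:
#' degree-preserving rewiring with the sign multiset permuted, so node
#' degrees and global up/down counts match the data. One-sided add-one
#' Monte-Carlo p-value for observed >= null. Diseases with no edges are
#' excluded (with a message).
#'
#' @param net a `signed_bipartite` network.
#' @param n_replicates number of null networks B (default 1000).
#' @param threshold down-fraction above which a disease counts as "mostly
#'   down" (default 0.5, strict).
#' @param seed root seed.
#' @param swap_multiplier swaps per edge for the rewiring.
#' @return An `htest`-like result.
#' @export
disease_down_test <- function(net, n_replicates = 1000, threshold = 0.5,
                              seed = 1L, swap_multiplier = 100) {
  zero <- setdiff(net$diseases, unique(net$edges$disease))
  if (length(zero) > 0)
    message("excluding disease(s) with no edges: ",
            paste(zero, collapse = ", "))
  stat <- function(x) {
    e <- x$edges
    frac <- tapply(e$sign == "down", e$disease, mean)
    sum(frac > threshold)
  }
  obs <- stat(net)
  null <- null_ensemble(net, stat, scheme = "degree_preserving_rewire",
                        n_replicates = n_replicates, seed = seed,
                        swap_multiplier = swap_multiplier)
  mc_test_result(c(`diseases mostly down` = obs),
                 mc_p_value(obs, null, "greater"),
                 "Count of mostly-down-regulated diseases vs. degree-preserving rewired networks",
                 n_replicates, deparse(substitute(net)),
                 list(null_values = null, threshold = threshold))
}

#' Concordance test against sign-shuffled networks
#'
#' Statistic: [concordance()] of the network. Null: the up/down labels
#' permuted over the fixed topology. One-sided add-one Monte-Carlo p-value
#' for observed >= null.
#'
#' Because the topology is fixed under this scheme, a null replicate is a
#' permutation of the sign vector tabulated over the (fixed) per-gene edge
#' groups; the replicate stream matches the generic [null_ensemble()] route
#' exactly.
#'
#' @param net a `signed_bipartite` network with >= 1 gene of degree >= 2.
#' @param n_replicates number of null networks B (default 1000).
#' @param seed root seed.
#' @return An `htest`-like result.
#' @export
concordance_test <- function(net, n_replicates = 1000, seed = 1L) {
  obs <- concordance(net)
  f <- factor(net$edges$gene)
  k <- tabulate(f)
  keep <- k >= 2
  down <- (net$edges$sign == "down") + 0
  m <- length(down)
  null <- vapply(seq_len(n_replicates), function(r)
    with_seed(child_seed(seed, r), {
      nd <- rowsum(down[sample.int(m)], f, reorder = TRUE)
      mean(nd[keep] == 0 | nd[keep] == k[keep])
    }), numeric(1))
  mc_test_result(c(concordance = obs),
                 mc_p_value(obs, null, "greater"),
                 "Within-gene regulation concordance vs. sign-shuffled networks",
                 n_replicates, deparse(substitute(net)),
                 list(null_values = null))
}

# Null prop_down matrix: one row per degree (all degrees present in the
# observed curve before filtering), one column per replicate. Fast path for
# label_shuffle: topology is fixed, so a replicate is a permutation of the
# sign vector tabulated by the precomputed per-edge gene degree.
null_curve_matrix <- function(net, scheme, n_replicates, seed,
                              swap_multiplier, degrees) {
  if (scheme == "label_shuffle") {
    gd <- degree_table(net)$gene_degree
    edge_deg <- as.integer(gd[net$edges$gene])
    down <- as.numeric(net$edges$sign == "down")
    n_e <- vapply(degrees, function(k) sum(edge_deg == k), numeric(1))
    grp <- match(edge_deg, degrees)
    ok <- !is.na(grp)  # labels shuffle over all edges; tabulate included degrees
    mat <- matrix(NA_real_, length(degrees), n_replicates)
    for (r in seq_len(n_replicates)) {
      perm <- with_seed(child_seed(seed, r), down[sample.int(length(down))])
      mat[, r] <- as.numeric(rowsum(perm[ok], grp[ok], reorder = TRUE)) / n_e
    }
    rownames(mat) <- degrees
    return(mat)
  }
  stat <- function(x) {
    rc <- down_regulation_curve(x, min_genes_per_degree = 0)
    setNames(rc$curve$prop_down, rc$curve$degree)[as.character(degrees)]
  }
  mat <- null_ensemble(net, stat, scheme = scheme,
                       n_replicates = n_replicates, seed = seed,
                       swap_multiplier = swap_multiplier, simplify = FALSE)
  mat <- do.call(cbind, mat)
  rownames(mat) <- degrees
  mat
}

#' Monte-Carlo confidence envelope around the down-regulation curve
#'
#' Computes the observed [down_regulation_curve()] and, from `n_replicates`
#' null networks (default scheme: sign labels shuffled over the fixed
#' topology, the study's construction), per-degree empirical equal-tail
#' quantile bounds at confidence `level`, flags for observed points outside
#' the envelope, and two-sided add-one Monte-Carlo p-values.
#'
#' @param net a `signed_bipartite` network.
#' @param n_replicates number of null networks B (the study used 1000).
#' @param level confidence level (the study used 0.999).
#' @param min_genes_per_degree curve inclusion filter (default 3).
#' @param seed root seed.
#' @param scheme null scheme; `"label_shuffle"` (default) or the rewiring
#'   schemes for sensitivity analysis.
#' @param swap_multiplier swaps per edge (degree-preserving scheme only).
#' @return An object of class `curve_envelope`: data.frame `envelope` with
#'   columns `degree`, `observed`, `lower`, `upper`, `outside`, `p_value`,
#'   `n_edges`, `n_genes`; plus the observed `regulation_curve`, `level`,
#'   `n_replicates`, `scheme` and the null matrix `null_prop_down`.
#' @details Quantiles are inverse-ECDF (type 1) order statistics at
#'   `(1-level)/2` and `1-(1-level)/2`. When `n_replicates <
#'   2/(1-level)` those tail quantiles degenerate to the null minimum and
#'   maximum and a warning of class `dgnet_envelope_B` is issued.
#' @export
curve_envelope <- function(net, n_replicates = 1000, level = 0.999,
                           min_genes_per_degree = 3, seed = 1L,
                           scheme = c("label_shuffle", "uniform_rewire",
                                      "degree_preserving_rewire"),
                           swap_multiplier = 100) {
  scheme <- match.arg(scheme)
  stopifnot(level > 0, level < 1)
  obs_curve <- down_regulation_curve(net, min_genes_per_degree)
  degrees <- obs_curve$curve$degree
  if (length(degrees) == 0)
    stop("no degree passes the minimum-genes filter", call. = FALSE)
  if (n_replicates < 2 / (1 - level))
    warning(warningCondition(sprintf(paste0(
      "n_replicates = %d is below 2/(1-level) = %.0f; the %.1f%% envelope ",
      "tail quantiles degenerate to the null minimum and maximum"),
      n_replicates, 2 / (1 - level), 100 * level),
      class = "dgnet_envelope_B"))

  mat <- null_curve_matrix(net, scheme, n_replicates, seed, swap_multiplier,
                           degrees)
  alpha <- 1 - level
  lower <- apply(mat, 1, quantile, probs = alpha / 2, type = 1, na.rm = TRUE)
  upper <- apply(mat, 1, quantile, probs = 1 - alpha / 2, type = 1,
                 na.rm = TRUE)
  obs <- obs_curve$curve$prop_down
  pvals <- vapply(seq_along(degrees), function(i)
    mc_p_value(obs[i], mat[i, ], "two.sided"), numeric(1))

  structure(list(
    envelope = data.frame(degree = degrees, observed = obs,
                          lower = unname(lower), upper = unname(upper),
                          outside = obs < lower | obs > upper,
                          p_value = pvals,
                          n_edges = obs_curve$curve$n_edges,
                          n_genes = obs_curve$curve$n_genes),
    curve = obs_curve, level = level, n_replicates = n_replicates,
    scheme = scheme, null_prop_down = mat
  ), class = "curve_envelope")
}

#' @export
print.curve_envelope <- function(x, ...) {
  cat(sprintf(
    "Down-regulation curve with %.1f%% Monte-Carlo envelope (%s, B = %d)\n",
    100 * x$level, x$scheme, x$n_replicates))
  print(x$envelope, row.names = FALSE, digits = 4)
  invisible(x)
}

#' High-degree genes discordant with the down-regulation trend
#'
#' Lists genes of degree >= `min_degree` whose incident edges are
#' majority-up (up-fraction strictly above 0.5) — the high-degree genes
#' that run against the trend of high-degree genes being down-regulated.
#'
#' @param net a `signed_bipartite` network.
#' @param min_degree minimum gene degree (default 4).
#' @return A data.frame with columns `gene`, `degree`, `up_fraction`,
#'   sorted by degree descending then gene id; may be empty.
#' @export
discordant_high_degree_genes <- function(net, min_degree = 4) {
  gd <- degree_table(net)$gene_degree
  high <- names(gd)[gd >= min_degree]
  if (length(high) == 0)
    return(data.frame(gene = character(), degree = integer(),
                      up_fraction = numeric()))
  e <- net$edges[net$edges$gene %in% high, ]
  upfrac <- tapply(e$sign == "up", e$gene, mean)
  out <- data.frame(gene = names(upfrac),
                    degree = as.integer(gd[names(upfrac)]),
                    up_fraction = as.numeric(upfrac),
                    stringsAsFactors = FALSE)
  out <- out[out$up_fraction > 0.5, , drop = FALSE]
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
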