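# Synthetic signed bipartite network generator.
#
# Emulates the structure of a multi-disease renal transcriptomic network:
# a handful of diseases, several hundred differentially regulated genes,
# a right-skewed gene degree distribution on a narrow support, (near-)full
# within-gene regulation concordance, and a logistic degree -> down-
# regulation law P(down | k) = plogis(a + b * k).
#
# Generation is gene-anchored: each gene draws its degree k from
# `degree_weights`, then k distinct partner diseases with probability
# proportional to `disease_attachment_weights` (disease degrees are
# emergent, producing large and small disease nodes), then its signs.
# With probability `concordance` the gene is concordant (all edges carry
# one primary sign drawn from P(down | k)); otherwise each edge's sign is
# drawn independently from the same law.

#' Configuration for the synthetic network generator
#'
#' @param n_diseases number of disease nodes.
#' @param n_genes number of gene nodes.
#' @param degree_weights named numeric vector of gene-degree probabilities;
#'   names are the degrees (support must lie in `1..n_diseases`), values sum
#'   to 1.
#' @param disease_attachment_weights positive reals, one per disease:
#'   relative propensity of each disease to receive edges.
#' @param concordance probability that a gene's edges all share one sign.
#' @param intercept_a,slope_b parameters of
#'   `P(down | gene degree k) = plogis(intercept_a + slope_b * k)`;
#'   `slope_b > 0` makes high-degree genes predominantly down-regulated,
#'   `slope_b = 0` is the no-effect null.
#' @param seed integer seed; generation is deterministic given the config.
#' @return A list of class `generator_config`.
#' @seealso [default_generator_config()], [generate_network()]
#' @export
generator_config <- function(n_diseases, n_genes, degree_weights,
                             disease_attachment_weights =
                               rep(1, n_diseases),
                             concordance = 1.0,
                             intercept_a = 0, slope_b = 0,
                             seed = 1L) {
  stopifnot(n_diseases >= 1, n_genes >= 1,
            is.numeric(degree_weights), length(degree_weights) >= 1,
            !is.null(names(degree_weights)))
  ks <- as.integer(names(degree_weights))
  if (anyNA(ks) || any(ks < 1))
    stop("degree_weights names must be positive integer degrees", call. = FALSE)
  if (any(ks > n_diseases))
    stop("degree_weights support exceeds n_diseases: a gene cannot attach to ",
         "more distinct diseases than exist", call. = FALSE)
  if (abs(sum(degree_weights) - 1) > 1e-9)
    stop("degree_weights must sum to 1", call. = FALSE)
  if (any(degree_weights < 0))
    stop("degree_weights must be non-negative", call. = FALSE)
  stopifnot(length(disease_attachment_weights) == n_diseases,
            all(disease_attachment_weights > 0),
            concordance >= 0, concordance <= 1,
            is.finite(intercept_a), is.finite(slope_b),
            is.numeric(seed), length(seed) == 1)
  structure(list(
    n_diseases = as.integer(n_diseases),
    n_genes = as.integer(n_genes),
    degree_weights = degree_weights,
    disease_attachment_weights = as.numeric(disease_attachment_weights),
    concordance = concordance,
    intercept_a = intercept_a,
    slope_b = slope_b,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Default generator configuration (renal-study structure)
#'
#' The conditions the analyses assume: 7 diseases, 747 genes, gene degrees
#' on `1..5` with right-skewed weights `(.55, .25, .11, .06, .03)` (mode at
#' degree 1, decreasing), unequal disease attachment (four diseases much
#' larger than the rest), full concordance, and sign law `a = -2, b = 1.2`,
#' so `P(down | k)` rises from 0.31 at degree 1 through 0.85 at degree 4 to
#' 0.95 at degree 5: low-degree (disease-specific) genes are mostly
#' up-regulated, high-degree (non-specific) genes mostly down-regulated.
#'
#' @param seed integer seed (default 20101111).
#' @param ... overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @export
default_generator_config <- function(seed = 20101111L, ...) {
  args <- list(
    n_diseases = 7L,
    n_genes = 747L,
    degree_weights = c(`1` = 0.55, `2` = 0.25, `3` = 0.11,
                       `4` = 0.06, `5` = 0.03),
    disease_attachment_weights = c(3, 3, 3, 3, 1.5, 1.5, 1),
    concordance = 1.0,
    intercept_a = -2,
    slope_b = 1.2,
    seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(generator_config, args)
}

#' Generate a synthetic signed bipartite network
#'
#' Draws a network from a [generator_config()]; see the package vignette for
#' the generative model. Deterministic given the config (including its
#' seed): identical configs give byte-identical Pajek exports.
#'
#' @param cfg a `generator_config`.
#' @return A `signed_bipartite` network with `cfg$n_diseases` diseases
#'   (`D1..`) and `cfg$n_genes` genes (`g0001..`), every gene of degree >= 1.
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    nd <- cfg$n_diseases
    ng <- cfg$n_genes
    diseases <- paste0("D", seq_len(nd))
    genes <- sprintf("g%0*d", max(4L, nchar(ng)), seq_len(ng))

    ks <- as.integer(names(cfg$degree_weights))
    deg <- sample(ks, ng, replace = TRUE, prob = cfg$degree_weights)
    p_down <- plogis(cfg$intercept_a + cfg$slope_b * deg)

    dis_idx <- vector("list", ng)
    sgn <- vector("list", ng)
    for (i in seq_len(ng)) {
      k <- deg[i]
      d <- sort(sample.int(nd, k, replace = FALSE,
                           prob = cfg$disease_attachment_weights))
      dis_idx[[i]] <- d
      primary <- if (runif(1) < p_down[i]) "down" else "up"
      if (runif(1) < cfg$concordance) {
        sgn[[i]] <- rep(primary, k)
      } else {
        sgn[[i]] <- ifelse(runif(k) < p_down[i], "down", "up")
      }
    }

    edges <- data.frame(
      disease = diseases[unlist(dis_idx)],
      gene = rep(genes, deg),
      sign = unlist(sgn),
      stringsAsFactors = FALSE
    )
    build_network(edges, diseases = diseases, genes = genes)
  })
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("Generator config: %d diseases, %d genes, seed %d\n",
              x$n_diseases, x$n_genes, x$seed))
  cat("  degree weights:",
      paste(sprintf("k=%s: %.3g", names(x$degree_weights), x$degree_weights),
            collapse = ", "), "\n")
  cat(sprintf("  concordance %.3g; P(down|k) = plogis(%.3g + %.3g k)\n",
              x$concordance, x$intercept_a, x$slope_b))
  invisible(x)
}
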