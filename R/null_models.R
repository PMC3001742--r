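# Permutation null models for signed bipartite networks.
#
# Three randomization schemes, matching three levels of conditioning:
#  * uniform_rewire        — keep node sets and |E|; edges placed uniformly
#                            at random among all disease-gene pairs; sign
#                            multiset permuted.
#  * degree_preserving_rewire — additionally keep every node's degree, via
#                            checkerboard (2x2) edge swaps; sign multiset
#                            permuted.
#  * label_shuffle         — keep the topology fixed; permute the up/down
#                            labels over the edges.

#' Uniformly rewired null network
#'
#' Same disease and gene node sets and the same number of edges, but the
#' edge set is sampled uniformly without replacement from all
#' disease-gene pairs; the up/down sign multiset is preserved and randomly
#' permuted over the new edges.
#'
#' @param net a `signed_bipartite` network.
#' @param seed optional seed (default: current RNG stream).
#' @return A randomized `signed_bipartite` network.
#' @export
uniform_rewire <- function(net, seed = NULL) {
  nd <- length(net$diseases)
  ng <- length(net$genes)
  m <- nrow(net$edges)
  if (m > nd * ng)
    stop("more edges than disease-gene pairs", call. = FALSE)
  with_seed(seed, {
    idx <- sample.int(nd * ng, m)
    d <- ((idx - 1L) %% nd) + 1L
    g <- ((idx - 1L) %/% nd) + 1L
    edges <- data.frame(disease = net$diseases[d], gene = net$genes[g],
                        sign = sample(net$edges$sign),
                        stringsAsFactors = FALSE)
    new_signed_bipartite(net$diseases, net$genes, edges)
  })
}

#' Degree-preserving rewired null network
#'
#' Randomizes the topology while keeping every node's degree, by attempting
#' `swap_multiplier * |E|` checkerboard swaps: pick edges (d1,g1), (d2,g2)
#' with d1 != d2 and g1 != g2 and replace them with (d1,g2), (d2,g1) iff
#' neither exists. The up/down sign multiset is preserved and permuted. A
#' network admitting no valid swap (e.g. a star) is returned with its
#' topology intact and signs permuted.
#'
#' @param net a `signed_bipartite` network.
#' @param swap_multiplier attempted swaps per edge (default 100).
#' @param seed optional seed.
#' @return A randomized `signed_bipartite` network.
#' @export
degree_preserving_rewire <- function(net, swap_multiplier = 100, seed = NULL) {
  stopifnot(swap_multiplier >= 1)
  m <- nrow(net$edges)
  with_seed(seed, {
    if (m == 0) return(net)
    d <- match(net$edges$disease, net$diseases)
    g <- match(net$edges$gene, net$genes)
    res <- checkerboard_rewire_cpp(d, g, length(net$diseases),
                                   length(net$genes),
                                   as.numeric(swap_multiplier) * m)
    edges <- data.frame(disease = net$diseases[res$disease],
                        gene = net$genes[res$gene],
                        sign = sample(net$edges$sign),
                        stringsAsFactors = FALSE)
    new_signed_bipartite(net$diseases, net$genes, edges)
  })
}

#' Sign-label shuffled null network
#'
#' Keeps the topology fixed and permutes the up/down labels uniformly over
#' the edges, preserving the up and down counts exactly.
#'
#' @param net a `signed_bipartite` network.
#' @param seed optional seed.
#' @return A `signed_bipartite` network on the same edges.
#' @export
label_shuffle <- function(net, seed = NULL) {
  with_seed(seed, {
    edges <- net$edges
    if (nrow(edges) > 1) edges$sign <- edges$sign[sample.int(nrow(edges))]
    new_signed_bipartite(net$diseases, net$genes, edges)
  })
}

NULL_SCHEMES <- c("uniform_rewire", "degree_preserving_rewire", "label_shuffle")

# Dispatch one replicate of a scheme (seed handled by caller).
randomize_network <- function(net, scheme, swap_multiplier = 100) {
  switch(scheme,
         uniform_rewire = uniform_rewire(net),
         degree_preserving_rewire =
           degree_preserving_rewire(net, swap_multiplier),
         label_shuffle = label_shuffle(net),
         stop("unknown scheme: ", scheme, call. = FALSE))
}

#' Null ensemble of a network statistic
#'
#' Evaluates `statistic` on `n_replicates` independent randomizations of
#' `net` under one of the three null schemes. Replicate `r` runs on a child
#' stream derived from `(seed, r)` (see [child_seed()]), so the ensemble is
#' reproducible and independent of evaluation order.
#'
#' @param net a `signed_bipartite` network.
#' @param statistic function `network -> numeric scalar or vector`.
#' @param scheme one of `"uniform_rewire"`, `"degree_preserving_rewire"`,
#'   `"label_shuffle"`.
#' @param n_replicates number of replicates B (the study used 1000).
#' @param seed root seed.
#' @param swap_multiplier swaps per edge (degree-preserving scheme only).
#' @param simplify if `TRUE` (default), return a vector (scalar statistic)
#'   or a matrix with one column per replicate; else a list.
#' @return Ensemble of statistic values.
#' @export
null_ensemble <- function(net, statistic,
                          scheme = c("label_shuffle", "uniform_rewire",
                                     "degree_preserving_rewire"),
                          n_replicates = 1000, seed = 1L,
                          swap_multiplier = 100, simplify = TRUE) {
  scheme <- match.arg(scheme)
  stopifnot(n_replicates >= 1, is.function(statistic))
  vals <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    vals[[r]] <- with_seed(child_seed(seed, r), {
      repnet <- randomize_network(net, scheme, swap_multiplier)
      tryCatch(statistic(repnet), error = function(e)
        stop(sprintf("statistic failed on replicate %d: %s", r,
                     conditionMessage(e)), call. = FALSE))
    })
  }
  if (!simplify) return(vals)
  if (all(lengths(vals) == 1L)) unlist(vals) else do.call(cbind, vals)
}

#' Add-one Monte-Carlo p-value
#'
#' `p = (1 + #{null at least as extreme as observed}) / (B + 1)`; never
#' returns 0. For `alternative = "two.sided"` the doubled smaller tail,
#' capped at 1.
#'
#' @param observed observed statistic.
#' @param null numeric vector of null replicate values.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @return p-value in (0, 1].
#' @export
mc_p_value <- function(observed, null,
                       alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  null <- null[!is.na(null)]
  B <- length(null)
  p_ge <- (1 + sum(null >= observed)) / (B + 1)
  p_le <- (1 + sum(null <= observed)) / (B + 1)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}
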