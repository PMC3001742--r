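# Shared fixtures and independent oracles, built in code.

clu_path_for <- dgnet:::clu_path_for
with_seed <- dgnet:::with_seed

# 4-edge toy: D1-g1 up, D1-g2 down, D2-g2 down, D2-g3 up.
t1_network <- function() {
  build_network(data.frame(
    disease = c("D1", "D1", "D2", "D2"),
    gene    = c("g1", "g2", "g2", "g3"),
    sign    = c("up", "down", "down", "up"),
    stringsAsFactors = FALSE))
}

make_net <- function(disease, gene, sign, ...) {
  build_network(data.frame(disease = disease, gene = gene, sign = sign,
                           stringsAsFactors = FALSE), ...)
}

# All-down network over k diseases x g genes (complete bipartite).
all_down_net <- function(nd = 2, ng = 3) {
  make_net(rep(paste0("D", seq_len(nd)), ng),
           rep(paste0("g", seq_len(ng)), each = nd),
           rep("down", nd * ng))
}

# Canonical string key of an edge set (topology only).
edge_set_key <- function(net) {
  e <- net$edges
  paste(sort(paste(e$disease, e$gene, sep = "|")), collapse = ";")
}

# Canonical string key including signs.
signed_key <- function(net) {
  e <- net$edges
  paste(sort(paste(e$disease, e$gene, e$sign, sep = "|")), collapse = ";")
}

# Exhaustive enumeration oracle: all placements of n_down "down" labels on
# m edges (logical matrix, one row per placement).
all_label_placements <- function(m, n_down) {
  if (n_down == 0) return(matrix(FALSE, 1, m))
  if (n_down == m) return(matrix(TRUE, 1, m))
  combos <- utils::combn(m, n_down)
  t(apply(combos, 2, function(ix) {
    v <- logical(m); v[ix] <- TRUE; v
  }))
}

# Concordance of a sign placement (logical down vector) on a fixed edge
# list; NA if no gene of degree >= 2. Independent of the package routines.
oracle_concordance <- function(gene, down) {
  tab <- table(gene)
  multi <- names(tab)[tab >= 2]
  if (length(multi) == 0) return(NA_real_)
  mean(vapply(multi, function(g) {
    s <- down[gene == g]
    all(s) || !any(s)
  }, logical(1)))
}

# Per-degree down proportion of a placement (named by degree), no filter.
oracle_prop_down <- function(gene, down) {
  deg <- table(gene)[gene]  # degree of each edge's gene
  tapply(down, as.integer(deg), mean)
}
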