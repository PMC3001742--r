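ref_net <- generate_network(default_generator_config(seed = 77, n_genes = 150))

test_that("uniform rewiring preserves node sets, edge count and sign counts", {
  for (r in 1:20) {
    rn <- uniform_rewire(ref_net, seed = r)
    expect_identical(rn$diseases, ref_net$diseases)
    expect_identical(rn$genes, ref_net$genes)
    expect_equal(n_edges(rn), n_edges(ref_net))
    expect_equal(table(rn$edges$sign), table(ref_net$edges$sign))
    expect_equal(anyDuplicated(paste(rn$edges$disease, rn$edges$gene)), 0)
  }
  # complete bipartite input admits a single edge set
  cb <- all_down_net(2, 3)
  expect_equal(edge_set_key(uniform_rewire(cb, seed = 1)), edge_set_key(cb))
  # more edges than pairs is impossible
  tiny <- structure(list(diseases = "D1", genes = "g1",
                         edges = data.frame(disease = c("D1", "D1"),
                                            gene = c("g1", "g1"),
                                            sign = c("up", "up"))),
                    class = "signed_bipartite")
  expect_error(uniform_rewire(tiny), "more edges")
})

test_that("uniform rewiring samples edge sets uniformly (exhaustive oracle)", {
  # 2 diseases x 3 genes, 4 edges: C(6,4) = 15 possible edge sets
  t1 <- t1_network()
  n <- 10000
  keys <- character(n)
  for (r in 1:n) keys[r] <- edge_set_key(uniform_rewire(t1, seed = r))
  tab <- table(keys)
  expect_equal(length(tab), 15)
  p <- 1 / 15
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(tab / n - p) < 3 * se + 1e-12))
})

test_that("degree-preserving rewiring preserves every node degree", {
  dt0 <- degree_table(ref_net)
  changed <- FALSE
  for (r in 1:20) {
    rn <- degree_preserving_rewire(ref_net, seed = r)
    dt <- degree_table(rn)
    expect_identical(dt$gene_degree, dt0$gene_degree)
    expect_identical(dt$disease_degree, dt0$disease_degree)
    expect_equal(table(rn$edges$sign), table(ref_net$edges$sign))
    expect_equal(anyDuplicated(paste(rn$edges$disease, rn$edges$gene)), 0)
    if (edge_set_key(rn) != edge_set_key(ref_net)) changed <- TRUE
  }
  expect_true(changed)  # the sampler actually moves
})

test_that("a star admits no valid swap and keeps its topology", {
  star <- make_net(rep("D1", 5), paste0("g", 1:5), rep("up", 5))
  rn <- degree_preserving_rewire(star, seed = 4)
  expect_equal(edge_set_key(rn), edge_set_key(star))
})

test_that("checkerboard swaps mix uniformly over the two 2x2 states", {
  net22 <- make_net(c("D1", "D2"), c("g1", "g2"), c("up", "down"))
  n <- 10000
  keys <- character(n)
  for (r in 1:n) keys[r] <- edge_set_key(degree_preserving_rewire(
    net22, swap_multiplier = 100, seed = r))
  tab <- table(keys)
  expect_equal(length(tab), 2)
  se <- sqrt(0.25 / n)
  expect_true(all(abs(tab / n - 0.5) < 3 * se))
})

test_that("label shuffling preserves topology and sign counts", {
  t1 <- t1_network()
  for (r in 1:10) {
    rn <- label_shuffle(t1, seed = r)
    expect_equal(edge_set_key(rn), edge_set_key(t1))
    expect_equal(sum(rn$edges$sign == "up"), 2)
    expect_equal(sum(rn$edges$sign == "down"), 2)
  }
  # single permutation class: all-down input is returned unchanged
  ad <- all_down_net()
  expect_true(same_network(label_shuffle(ad, seed = 1), ad))
})

test_that("label shuffling places labels uniformly (exhaustive oracle)", {
  t1 <- t1_network()
  n <- 12000
  keys <- character(n)
  for (r in 1:n) keys[r] <- signed_key(label_shuffle(t1, seed = r))
  tab <- table(keys)
  expect_equal(length(tab), choose(4, 2))
  p <- 1 / 6
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(tab / n - p) < 3 * se))
})

test_that("null_ensemble is deterministic and respects scheme structure", {
  stat_edges <- function(x) n_edges(x)
  a <- null_ensemble(ref_net, stat_edges, "uniform_rewire",
                     n_replicates = 20, seed = 5)
  b <- null_ensemble(ref_net, stat_edges, "uniform_rewire",
                     n_replicates = 20, seed = 5)
  expect_identical(a, b)
  expect_true(all(a == n_edges(ref_net)))  # constant statistic

  # label shuffling preserves the pooled down fraction exactly
  pooled <- function(x) mean(x$edges$sign == "down")
  vals <- null_ensemble(ref_net, pooled, "label_shuffle",
                        n_replicates = 50, seed = 6)
  expect_true(all(vals == pooled(ref_net)))
})

test_that("swap-chain length does not shift the rewired distribution", {
  # two-sample KS between a scalar statistic at Q and 2Q
  overlap <- function(x) {
    mean(paste(x$edges$disease, x$edges$gene) %in%
           paste(ref_net$edges$disease, ref_net$edges$gene))
  }
  a <- null_ensemble(ref_net, overlap, "degree_preserving_rewire",
                     n_replicates = 100, seed = 7, swap_multiplier = 100)
  b <- null_ensemble(ref_net, overlap, "degree_preserving_rewire",
                     n_replicates = 100, seed = 8, swap_multiplier = 200)
  expect_gt(suppressWarnings(stats::ks.test(a, b)$p.value), 0.01)
})

test_that("the add-one estimator never returns zero and handles ties", {
  expect_equal(mc_p_value(1000, 1:999), 1 / 1000)  # observed beats all nulls
  expect_equal(mc_p_value(0, 1:999, "greater"), 1)
  expect_equal(mc_p_value(5, rep(5, 9), "greater"), 1)  # ties count as >=
  p <- mc_p_value(3, stats::rnorm(99), "two.sided")
  expect_gt(p, 0)
  expect_lte(p, 1)
})
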