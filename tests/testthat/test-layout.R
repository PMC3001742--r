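test_that("a single node sits at the centre of the box", {
  net <- build_network(data.frame(), genes = "g1")
  lay <- fr_layout(net, dims = 3, iterations = 10, seed = 1)
  expect_equal(unname(lay$coords["g1", ]), c(0.5, 0.5, 0.5))
})

test_that("two connected nodes settle at the optimal distance kappa", {
  # force balance d^2/kappa = kappa^2/d has the unique solution d = kappa
  net <- make_net("D1", "g1", "up")
  for (dims in c(2, 3)) {
    lay <- fr_layout(net, dims = dims, iterations = 1000, seed = 7,
                     rescale = FALSE)
    d <- sqrt(sum((lay$coords[1, ] - lay$coords[2, ])^2))
    expect_lt(abs(d - lay$kappa) / lay$kappa, 0.02)
  }
})

test_that("layouts are deterministic given the seed", {
  t1 <- t1_network()
  a <- fr_layout(t1, dims = 3, iterations = 50, seed = 5)
  b <- fr_layout(t1, dims = 3, iterations = 50, seed = 5)
  expect_identical(a$coords, b$coords)
  c <- fr_layout(t1, dims = 3, iterations = 50, seed = 6)
  expect_false(identical(a$coords, c$coords))
})

test_that("relabelling nodes relabels coordinates and nothing else", {
  t1 <- t1_network()
  e2 <- t1$edges
  map <- c(D1 = "X1", D2 = "X2", g1 = "y1", g2 = "y2", g3 = "y3")
  e2$disease <- map[e2$disease]
  e2$gene <- map[e2$gene]
  net2 <- build_network(e2)
  a <- fr_layout(t1, dims = 2, iterations = 80, seed = 3)
  b <- fr_layout(net2, dims = 2, iterations = 80, seed = 3)
  expect_equal(unname(a$coords), unname(b$coords))
  expect_equal(rownames(b$coords), unname(map[rownames(a$coords)]))
})

test_that("node radii increase affinely with degree; edges colour by sign", {
  t1 <- t1_network()
  lay <- fr_layout(t1, dims = 2, iterations = 10, seed = 1,
                   r_min = 0.01, r_max = 0.05)
  r <- lay$node_radius
  expect_equal(unname(r["g2"]), 0.05)       # max degree (2)
  expect_equal(unname(r["g1"]), 0.01 + 0.04 * 1 / 2)
  expect_gt(r["g2"], r["g1"])               # strictly increasing in degree
  expect_equal(unname(lay$edge_color["D1|g1"]), "yellow")
  expect_equal(unname(lay$edge_color["D1|g2"]), "blue")
})

test_that("the energy proxy decreases over the run", {
  net <- generate_network(default_generator_config(seed = 41, n_genes = 150))
  ok <- 0
  for (s in 1:10) {
    early <- fr_layout(net, dims = 2, iterations = 1, seed = s,
                       rescale = FALSE)
    late <- fr_layout(net, dims = 2, iterations = 300, seed = s,
                      rescale = FALSE)
    e1 <- dgnet:::fr_energy(early$coords, net, early$kappa)
    e2 <- dgnet:::fr_energy(late$coords, net, late$kappa)
    if (e2 <= e1) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("high-degree genes are pulled to the disease centroid", {
  net <- generate_network(default_generator_config(seed = 23, n_genes = 250))
  neg <- 0
  for (s in 1:10) {
    lay <- fr_layout(net, dims = 3, iterations = 300, seed = s)
    if (centre_periphery_score(lay, net) < 0) neg <- neg + 1
  }
  expect_gte(neg, 9)
})

test_that("centre_periphery_score handles hand-built and degenerate cases", {
  # degree-5 gene at the disease centroid, degree-1 genes on a shell
  df <- rbind(
    data.frame(disease = paste0("D", 1:5), gene = "hub", sign = "down"),
    data.frame(disease = "D1", gene = paste0("p", 1:3), sign = "up"))
  net <- build_network(df)
  co <- rbind(
    matrix(c(0, 0, 1, 0, 0, 1, -1, 0, 0, -1), ncol = 2, byrow = TRUE),
    c(0, 0),
    matrix(c(3, 0, 0, 3, -3, 0), ncol = 2, byrow = TRUE))
  rownames(co) <- c(paste0("D", 1:5), "hub", paste0("p", 1:3))
  lay <- structure(list(coords = co, dims = 2), class = "fr_layout")
  expect_equal(centre_periphery_score(lay, net), -1)

  few <- make_net(c("D1", "D1"), c("g1", "g2"), c("up", "up"))
  lf <- fr_layout(few, dims = 2, iterations = 5, seed = 1)
  expect_error(centre_periphery_score(lf, few), "3 genes")
})

test_that("3D layouts spread high-degree genes more than 2D layouts", {
  net <- generate_network(default_generator_config(seed = 61, n_genes = 250))
  gd <- degree_table(net)$gene_degree
  hi <- names(gd)[gd >= 3]
  nn_mean <- function(coords) {
    d <- as.matrix(stats::dist(coords[hi, , drop = FALSE]))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  wins <- 0
  n_pairs <- 12
  for (s in 1:n_pairs) {
    l2 <- fr_layout(net, dims = 2, iterations = 300, seed = s)
    l3 <- fr_layout(net, dims = 3, iterations = 300, seed = s)
    if (nn_mean(l3$coords) > nn_mean(l2$coords)) wins <- wins + 1
  }
  # one-sided sign test at alpha = 0.05
  expect_lte(stats::binom.test(wins, n_pairs, alternative = "greater")$p.value,
             0.05)
})

test_that("layout exports round-trip and respect conventions", {
  net <- generate_network(default_generator_config(seed = 9, n_genes = 40))
  lay3 <- fr_layout(net, dims = 3, iterations = 60, seed = 2)
  p3 <- file.path(tempdir(), "lay3.net")
  export_layout(net, lay3, p3, "pajek_net")
  back <- read_pajek(p3)
  expect_true(same_network(back, net))
  expect_lt(max(abs(attr(back, "coords") - lay3$coords)), 5.001e-7)

  # 2D export writes z = 0.5 and flags dims=2 in a comment
  lay2 <- fr_layout(net, dims = 2, iterations = 60, seed = 2)
  p2 <- file.path(tempdir(), "lay2.net")
  export_layout(net, lay2, p2, "pajek_net")
  lines <- readLines(p2)
  expect_true(any(grepl("^% dims=2", lines)))
  back2 <- read_pajek(p2)
  expect_true(all(attr(back2, "coords")[, "z"] == 0.5))

  # csv: node table row count = n nodes, edge table row count = |E|
  pc <- file.path(tempdir(), "lay3.csv")
  export_layout(net, lay3, pc, "csv")
  nodes <- read.csv(pc)
  edges <- read.csv(file.path(tempdir(), "lay3_edges.csv"))
  expect_equal(nrow(nodes), length(net$diseases) + length(net$genes))
  expect_equal(nrow(edges), n_edges(net))
  expect_true(same_network(read_edge_list(file.path(tempdir(), "lay3_edges.csv")),
                           net))
  expect_error(export_layout(net, lay3, pc, "svg"), "unknown format")
})
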