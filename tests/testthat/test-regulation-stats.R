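test_that("down_regulation_curve computes per-degree edge proportions", {
  rc <- down_regulation_curve(t1_network(), min_genes_per_degree = 1)
  expect_equal(rc$curve$degree, c(1, 2))
  expect_equal(rc$curve$prop_down, c(0.0, 1.0))
  expect_equal(rc$curve$n_edges, c(2L, 2L))
  expect_equal(rc$curve$n_genes, c(2L, 1L))
  expect_equal(nrow(rc$excluded), 0)
  # n_edges[k] = k * n_genes[k]
  expect_equal(rc$curve$n_edges, rc$curve$degree * rc$curve$n_genes)

  ad <- all_down_net(3, 4)
  rca <- down_regulation_curve(ad, min_genes_per_degree = 1)
  expect_true(all(rca$curve$prop_down == 1.0))

  empty <- build_network(data.frame(), diseases = "D1", genes = "g1")
  expect_error(down_regulation_curve(empty), "no edges")
})

test_that("degrees with too few genes are excluded, not plotted", {
  # 5 diseases; 6 genes of degree 1, two genes of degree 5
  df <- rbind(
    data.frame(disease = paste0("D", 1:5)[c(1, 2, 3, 4, 5, 1)],
               gene = paste0("s", 1:6), sign = "up"),
    data.frame(disease = paste0("D", 1:5), gene = "h1", sign = "down"),
    data.frame(disease = paste0("D", 1:5), gene = "h2", sign = "down"))
  net <- build_network(df)
  rc <- down_regulation_curve(net, min_genes_per_degree = 3)
  expect_equal(rc$curve$degree, 1)
  expect_equal(rc$excluded$degree, 5)
  expect_equal(rc$excluded$n_genes, 2L)
  # gene totals are conserved across included + excluded
  expect_equal(sum(rc$curve$n_genes) + sum(rc$excluded$n_genes), 8L)
})

test_that("concordance is the unanimity fraction among multi-degree genes", {
  expect_equal(concordance(t1_network()), 1.0)  # g2: down, down
  mixed <- make_net(c("D1", "D2", "D1"), c("g1", "g1", "g2"),
                    c("up", "down", "up"))
  expect_equal(concordance(mixed), 0.0)
  deg1 <- make_net(c("D1", "D2"), c("g1", "g2"), c("up", "down"))
  expect_error(concordance(deg1), "degree >= 2")
})

test_that("sample skewness matches the moment-formula oracle", {
  x <- c(rep(1, 25), rep(3, 5))  # 30 genes: 25 at degree 1, 5 at degree 3
  m <- mean(x)
  g1 <- mean((x - m)^3) / mean((x - m)^2)^1.5  # textbook g1, by hand
  expect_equal(sample_skewness(x), g1)
  skip_if_not_installed("e1071")
  expect_equal(sample_skewness(x), e1071::skewness(x, type = 1))
  expect_error(sample_skewness(rep(2, 10)), "constant")
})

test_that("degree-distribution test flags right-skewed degree sequences", {
  net <- generate_network(default_generator_config(seed = 31, n_genes = 300))
  t <- degree_distribution_test(net, n_replicates = 199, seed = 1)
  expect_gt(t$p.value, 0)
  expect_lte(t$p.value, 1)
  expect_gte(t$p.value, 1 / 200)  # add-one floor
  expect_equal(unname(t$statistic),
               sample_skewness(as.numeric(degree_table(net)$gene_degree)))
  # constant degree sequence: statistic undefined
  cb <- all_down_net(2, 3)
  expect_error(degree_distribution_test(cb, n_replicates = 9), "constant")
})

test_that("disease_down_test counts mostly-down diseases strictly", {
  # T1: both diseases at exactly 1/2 down, not > 0.5
  t <- disease_down_test(t1_network(), n_replicates = 49, seed = 1)
  expect_equal(unname(t$statistic), 0)

  ad <- all_down_net(3, 4)
  t2 <- disease_down_test(ad, n_replicates = 9, seed = 1)
  expect_equal(unname(t2$statistic), 3)  # every disease with >= 1 edge

  # a disease declared but unconnected is excluded with a message
  net <- build_network(t1_network()$edges, diseases = c("D1", "D2", "D9"))
  expect_message(disease_down_test(net, n_replicates = 9, seed = 1), "D9")
})

test_that("concordance_test null matches exact hypergeometric enumeration", {
  # one degree-2 gene (down, down) among 2 up and 2 down labels:
  # P(concordant under shuffling) = 2 * C(2,2) / C(4,2) = 1/3
  net <- make_net(c("D1", "D2", "D1", "D2"), c("g1", "g1", "g2", "g3"),
                  c("down", "down", "up", "up"))
  B <- 3000
  t <- concordance_test(net, n_replicates = B, seed = 42)
  expect_equal(unname(t$statistic), 1.0)
  q <- 1 / 3
  se <- sqrt(q * (1 - q) / B)
  expect_lt(abs(mean(t$null_values) - q), 4 * se)
  # observed = 1 >= null iff the replicate is concordant
  expect_equal(t$p.value, (1 + sum(t$null_values == 1)) / (B + 1))
})

test_that("concordance_test fast path equals the generic ensemble route", {
  net <- generate_network(default_generator_config(seed = 55, n_genes = 60))
  t <- concordance_test(net, n_replicates = 50, seed = 9)
  generic <- null_ensemble(net, concordance, scheme = "label_shuffle",
                           n_replicates = 50, seed = 9)
  expect_equal(t$null_values, generic)
})

test_that("genes of degree 1 only make the concordance test undefined", {
  deg1 <- make_net(c("D1", "D2"), c("g1", "g2"), c("up", "down"))
  expect_error(concordance_test(deg1, n_replicates = 9), "degree >= 2")
})

test_that("discordant high-degree genes are majority-up and sorted", {
  expect_equal(nrow(discordant_high_degree_genes(all_down_net(4, 3))), 0)

  df <- rbind(
    data.frame(disease = paste0("D", 1:4), gene = "gUp", sign = "up"),
    data.frame(disease = paste0("D", 1:5), gene = "gUp5", sign = "up"),
    data.frame(disease = paste0("D", 1:4), gene = "gDown", sign = "down"),
    data.frame(disease = paste0("D", 1:4), gene = "gMix",
               sign = c("up", "up", "up", "down")),
    data.frame(disease = "D1", gene = "gLow", sign = "up"))
  net <- build_network(df)
  disc <- discordant_high_degree_genes(net, min_degree = 4)
  expect_equal(disc$gene, c("gUp5", "gMix", "gUp"))  # degree desc, then id
  expect_equal(disc$degree, c(5L, 4L, 4L))
  expect_equal(disc$up_fraction, c(1, 0.75, 1))

  # under full concordance every listed gene is unanimously up
  net2 <- generate_network(default_generator_config(seed = 12))
  d2 <- discordant_high_degree_genes(net2)
  expect_true(all(d2$up_fraction == 1.0))
})
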