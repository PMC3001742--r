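#!/usr/bin/env Rscript

# Stage 2: test the three regularities of the network against their
# appropriate null models (B = 1000 each):
#   - gene degree distribution skewness  vs. uniform rewiring
#   - number of mostly-down diseases     vs. degree-preserving rewiring
#   - regulation concordance             vs. sign-label shuffling
# Requires results/network.net from stage 1.

suppressPackageStartupMessages(library(dgnet))

net <- read_pajek("results/network.net")
B <- 1000L
seed <- 1L

dd <- degree_distribution_test(net, n_replicates = B,
                               seed = child_seed(seed, 1))
print(dd)

md <- disease_down_test(net, n_replicates = B, seed = child_seed(seed, 2))
print(md)

ct <- concordance_test(net, n_replicates = B, seed = child_seed(seed, 3))
print(ct)

write.csv(data.frame(
  test = c("degree_distribution", "disease_down", "concordance"),
  statistic = c(unname(dd$statistic), unname(md$statistic),
                unname(ct$statistic)),
  p_value = c(dd$p.value, md$p.value, ct$p.value),
  n_replicates = B),
  "results/null_model_tests.csv", row.names = FALSE)
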