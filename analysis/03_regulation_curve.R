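#!/usr/bin/env Rscript

# Stage 3: the degree -> proportion-down regulation curve, its 99.9%
# Monte-Carlo envelope under sign-label shuffling, and the discordant
# high-degree genes. Requires results/network.net from stage 1.

suppressPackageStartupMessages(library(dgnet))

net <- read_pajek("results/network.net")

env <- curve_envelope(net, n_replicates = 10000, level = 0.999, seed = 42)
print(env)
write.csv(env$envelope, "results/curve_envelope.csv", row.names = FALSE)

pdf("results/curve_envelope.pdf", width = 6, height = 5)
plot(env)
dev.off()

disc <- discordant_high_degree_genes(net, min_degree = 4)
cat("\nDiscordant high-degree genes (majority up among degree >= 4):\n")
print(disc)
write.csv(disc, "results/discordant_genes.csv", row.names = FALSE)
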