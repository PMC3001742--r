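#!/usr/bin/env Rscript

# Stage 4: 2D and 3D Fruchterman-Reingold layouts, the centre-periphery
# diagnostic, and layout exports. Requires results/network.net from stage 1.

suppressPackageStartupMessages(library(dgnet))

net <- read_pajek("results/network.net")

for (d in c(2, 3)) {
  lay <- fr_layout(net, dims = d, iterations = 500, seed = 11)
  score <- centre_periphery_score(lay, net)
  cat(sprintf("%dD layout: centre-periphery score = %.3f\n", d, score))
  export_layout(net, lay, sprintf("results/layout_%dd.net", d), "pajek_net")
  export_layout(net, lay, sprintf("results/layout_%dd.csv", d), "csv")
  if (d == 2) {
    pdf("results/layout_2d.pdf", width = 7, height = 7)
    plot(lay, net)
    dev.off()
  }
}
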