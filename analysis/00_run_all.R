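#!/usr/bin/env Rscript

# Convenience driver: the whole analysis in one call via run_pipeline(),
# equivalent to stages 1-4 with shared defaults. Writes results/pipeline/.

suppressPackageStartupMessages(library(dgnet))

cfg <- run_config(generator = default_generator_config(),
                  out_dir = "results/pipeline", seed = 1L, plot = TRUE)
report <- run_pipeline(cfg)
str(report$tests, max.level = 2)
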