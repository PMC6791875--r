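#!/usr/bin/env Rscript
# Stage 2 — window the alignment and apply the informative-site filter.
#
# Reads the simulated MAF back from disk (the stage boundary is the file,
# as it would be with a downloaded alignment), tiles the reference
# coordinates into fixed windows, and drops windows with fewer than 10%
# informative positions.

suppressMessages(library(phyloscan))

config <- read_pipeline_config(
  system.file("extdata", "demo_config.yaml", package = "phyloscan")
)
cfgs <- phyloscan:::build_configs(config)

blocks <- read_maf("results/run/alignment.maf")
windows <- partition_windows(blocks, cfgs$scan)
filt <- filter_windows(windows, cfgs$scan)
write.table(filt$log, "results/run/window_filter.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d windows tiled; %d retained, %d excluded (threshold %d informative bp)\n",
            length(windows), length(filt$retained), length(filt$excluded),
            as.integer(cfgs$scan$min_informative_fraction *
                         cfgs$scan$window_size)))
st <- alignment_stats(filt$retained[[1]])
cat(sprintf("first retained window: %d aligned columns, %d determined, %.1f%% gaps, %d patterns\n",
            st$aligned_length, st$length_determined,
            100 * st$gap_fraction, st$n_patterns))
cat("wrote results/run/window_filter.tsv\n")
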