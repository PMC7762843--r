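#!/usr/bin/env Rscript
# Stage 2: region-based pairwise decoding.
#
# Downsampled epochs -> pseudo-trials -> 3-PC features per subject x region
# -> leave-one-per-class-out LDA accuracy for all 28 condition pairs at
# every 10 ms bin of the 0-300 ms analysis window: the empirical RDMs.

suppressPackageStartupMessages(library(sourcemvpa))

ds <- load_dataset("results/dataset.rds")
cfg <- pipeline_config(analysis_window_ms = c(0, 300), rng_seed = 2026L)
rdms <- compute_empirical_rdms(ds, cfg)
print(rdms)
saveRDS(rdms, "results/rdms.rds")

# long summary: mean accuracy per region x component x timebin
pairs <- rdms$pairs
long <- do.call(rbind, lapply(dimnames(rdms$acc)[[2]], function(r) {
  do.call(rbind, lapply(levels(pairs$component), function(cm) {
    sel <- pairs$component == cm
    data.frame(region = r, component = cm, bin_ms = rdms$bin_ms,
               accuracy = apply(rdms$acc[, r, sel, , drop = FALSE], 4, mean))
  }))
}))
write.csv(long, "results/decoding_by_component.csv", row.names = FALSE)

peak <- subset(long, bin_ms >= 80 & bin_ms <= 200)
cat("mean accuracy, 80-200 ms window:\n")
print(round(with(peak, tapply(accuracy, list(component, region), mean)), 3))
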