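#!/usr/bin/env Rscript
# Stage 3: RSA against the recognition model RDM, and RDM profiles.
#
# Per subject/region/timebin, Spearman correlation of the 28 decoding
# accuracies with the binary model (high dissimilarity across the
# recognized/unrecognized boundary), Fisher-z, one-sided group t-tests,
# BH-FDR over all region x timebin cells; then the nine-component profile
# decomposition with its canonical contrasts in each effect window.

suppressPackageStartupMessages(library(sourcemvpa))

rdms <- readRDS("results/rdms.rds")
emap <- searchlight_effect_map(rdms)
write.csv(as.data.frame(emap), "results/effect_map.csv", row.names = FALSE)
sig <- emap[emap$significant, ]
cat("FDR-significant cells by region:\n")
print(table(sig$region))

windows <- list(rIO = c(80, 160), rInsula = c(100, 200))
contrast_rows <- list()
for (r in names(windows)) {
  prof <- window_profiles(rdms, r, windows[[r]])
  write.csv(data.frame(subject = rownames(prof), prof),
            sprintf("results/profile_%s.csv", r), row.names = FALSE)
  for (cn in c("dR-dU", "dNa-dN", "sNa", "RN-UN", "sRU-sNa")) {
    side <- if (cn %in% c("RN-UN", "sRU-sNa")) "greater" else "two.sided"
    ct <- profile_contrast(prof, cn, alternative = side)
    contrast_rows[[paste(r, cn)]] <- data.frame(
      region = r, window = paste(windows[[r]], collapse = "-"),
      contrast = cn, mean = mean(ct$values), t = ct$t$statistic,
      df = ct$t$df, p = ct$t$p, sided = side)
  }
}
contrasts <- do.call(rbind, contrast_rows)
rownames(contrasts) <- NULL
write.csv(contrasts, "results/profile_contrasts.csv", row.names = FALSE)
cat("\nprofile contrasts:\n")
print(contrasts, digits = 3)
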