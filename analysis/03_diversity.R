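#!/usr/bin/env Rscript
# Stage 3: weed-community structure. Per-sample diversity indices,
# rare-species removal by occupancy, Hellinger standardization, and
# the index-species correlation screen (|r| > 0.4; no p-values, since
# the indices are functions of the species data themselves).

suppressPackageStartupMessages(library(cropdyn))

ds <- read_dataset("results/data")
cm <- community_matrix(ds$weeds)
idx <- diversity_indices(cm)

cm_red <- filter_rare(cm, threshold = 0.05)
removed <- attr(cm_red, "removed")
screen <- correlation_screen(idx, hellinger(cm_red), threshold = 0.4)

diversity <- cbind(sample = rownames(cm), idx)
write.csv(diversity, "results/diversity.csv", row.names = FALSE)
write.csv(screen, "results/screen.csv", row.names = FALSE)

cat("Diversity over", nrow(cm), "samples:",
    sprintf("Shannon %.2f +/- %.2f, richness %.1f +/- %.1f\n",
            mean(idx$shannon), sd(idx$shannon),
            mean(idx$richness), sd(idx$richness)))
cat("Rare-species filter removed:",
    if (length(removed)) paste(removed, collapse = ", ") else "none", "\n")
cat("Correlation screen retained", nrow(screen), "index-species pairs\n")
if (nrow(screen)) { cat("Strongest:\n"); print(head(screen, 3)) }
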