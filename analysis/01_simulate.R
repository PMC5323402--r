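#!/usr/bin/env Rscript
# Stage 1: generate the synthetic long-term cropping dataset.
#
# A maize-like series whose rate of increase follows a vertical
# (additive) perturbation of the Ricker R-function by weed Shannon
# diversity: six replicate blocks, ten successive harvests three years
# apart, process noise sd 0.05 on the rate scale, plus a mild quadratic
# calendar-year trend standing in for management/genetic improvement.
# Ground truth is embedded so later stages can be checked against it.

suppressPackageStartupMessages(library(cropdyn))

seed <- as.integer(Sys.getenv("CROPDYN_SEED", "1"))
out <- "results/data"

cfg <- synthetic_config(
  crop = "maize", form = "V",
  r_max = 1.0, a = 0.9, c = -7.9, b = 0.3,
  noise_sd = 0.05, n_blocks = 6, n_cycles = 10,
  trend = c(0.01, 0.0005), seed = seed)

ds <- generate_dataset(cfg)
paths <- write_dataset(ds, out)

cat("Generated synthetic experiment:\n")
cat("  yields :", nrow(ds$yields), "rows,",
    length(unique(ds$yields$year)), "harvest years x",
    max(ds$yields$replicate), "blocks\n")
cat("  weeds  :", nrow(ds$weeds), "rows,",
    length(unique(ds$weeds$species_code)), "species\n")
cat("  climate:", nrow(ds$climate), "daily records\n")
cat("  truth  : form", ds$truth$form, "with a =", cfg$a,
    ", c =", cfg$c, ", b =", cfg$b, "\n")
cat("Files written under", out, "\n")
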