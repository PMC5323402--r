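#!/usr/bin/env Rscript
# Stage 4: feedback diagnosis. The partial rate correlation function
# measures the (partial) correlation of R_t with lagged levels Y_{t-i};
# a dominant negative PRCF(1) outside the +/-2/sqrt(n) band indicates
# first-order negative feedback, i.e. the rate responds to the previous
# harvest's level -- the regulation the R-function models capture.

suppressPackageStartupMessages(library(cropdyn))

levels <- read.csv("results/levels.csv")
tab <- prcf(levels, max_lag = 4)
write.csv(tab, "results/prcf.csv", row.names = FALSE)

print(tab)
sig <- !is.na(tab$prcf) & abs(tab$prcf) > tab$band
cat("Lags outside the band:",
    if (any(sig)) paste(tab$lag[sig], collapse = ", ") else "none", "\n")
if (sig[1] && tab$prcf[1] < 0)
  cat("First-order negative feedback detected: fit first-order",
      "R-function models (d = 1).\n")
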