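#!/usr/bin/env Rscript
# Non-binding runtime-scaling benchmark: seconds per simulated event vs
# number of species N for DM / PDM / SPDM / PSSA-CR on the weakly coupled
# cyclic chain and the strongly coupled colloidal aggregation networks.
# Absolute numbers are hardware-dependent; the point is the scaling shape
# (DM grows with reaction count, PDM/SPDM with species count, PSSA-CR
# roughly flat on the weakly coupled chain).
#
# Usage: Rscript scripts/benchmark.R [--out <path.tsv>]

suppressPackageStartupMessages(library(ppsim))

args <- commandArgs(trailingOnly = TRUE)
out <- if (length(i <- which(args == "--out"))) args[i + 1] else "benchmark.tsv"

res <- rbind(
  benchmarkScaling("cyclic_chain", sizes = c(10L, 50L, 200L, 500L), tEnd = 5),
  benchmarkScaling("colloidal_aggregation", sizes = c(6L, 12L, 24L, 48L),
                   tEnd = 2))
res$nsPerEvent <- res$secondsPerEvent * 1e9
print(res, digits = 3)
write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
cat("written:", out, "\n")
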