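#!/usr/bin/env Rscript
# Stage 1: generate the seeded synthetic study inputs.
#
# Everything downstream works from this fixture bundle: a 50-protein
# proteome in which 20 proteins carry a planted 50-residue domain (10% of
# copies truncated below half length, emulating incomplete gene models), a
# 5-row seed alignment for the domain profile, and a 20-reference ortholog
# family (300 columns) carrying a duplicated paralog pair in which
# "paralogB" departs from deep conservation at exactly 4 planted columns.

library(paraldiv)

seed <- 20L
outdir <- file.path("results", "fixtures")
paths <- simulate_fixtures(outdir, seed = seed)

cat("Fixture bundle written under", outdir, "\n")
truth <- read.delim(paths$proteome_truth, comment.char = "#")
cat(sprintf("  planted domains: %d (%d truncated)\n",
            nrow(truth), sum(truth$truncated)))
div <- read.delim(paths$divergence_truth, comment.char = "#")
cat(sprintf("  planted divergent columns: %s\n",
            paste(div$column, collapse = ", ")))
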