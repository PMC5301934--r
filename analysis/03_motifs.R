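#!/usr/bin/env Rscript
# Stage 3: secondary-motif screen.
#
# Two synthetic motifs are planted into disjoint halves of a protein set
# (emulating subfamily-specific motifs such as the APB motif of the PIF
# subfamily); a calibrated catalog is screened across the full-length
# proteins at the permissive E <= 1 cutoff and summarised per group.

library(paraldiv)

seed <- 22L
outdir <- file.path("results", "motifs")
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

set.seed(seed)
consA <- paste(sample(aa_alphabet(), 25, replace = TRUE), collapse = "")
consB <- paste(sample(aa_alphabet(), 20, replace = TRUE), collapse = "")
mk_seed <- function(cons) {
  rows <- vapply(1:4, function(i) paste(
    paraldiv:::mutate_sequence(strsplit(cons, "")[[1]], 0.05, aa_background()),
    collapse = ""), character(1))
  msa(sprintf("r%d", 1:4), rows)
}
catalog <- motif_catalog(list(motif14 = mk_seed(consA), motif23 = mk_seed(consB)),
                         seed = seed)

prots <- protein_set(sprintf("P%02d", 1:16),
                     vapply(1:16, function(i)
                       paraldiv:::sample_residues(250), character(1)))
prots <- plant_motifs(prots, "motif14", consA, sprintf("P%02d", 1:8),
                      seed = seed + 1)$proteins
prots <- plant_motifs(prots, "motif23", consB, sprintf("P%02d", 9:16),
                      seed = seed + 2)$proteins

M <- screen_motifs(prots, catalog, evalue_cutoff = 1)
groups <- setNames(rep(c("famA", "famB"), each = 8), prots$id)
tab <- summarize_by_group(M, groups)
cat("per-group motif frequencies:\n")
print(tab, digits = 3)

pres <- attr(M, "presence")
cells <- ifelse(pres, formatC(unclass(M), format = "g", digits = 3), ".")
write.table(data.frame(protein_id = rownames(M), cells, check.names = FALSE),
            file.path(outdir, "motif_matrix.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(tab, file.path(outdir, "motif_by_group.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
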