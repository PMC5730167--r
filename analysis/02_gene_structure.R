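#!/usr/bin/env Rscript
# Comparative gene structure: recover exon/intron boundaries of the
# simulated family by splice-aware alignment and verify them against the
# emitted truth; then summarise the shipped ortholog exon/intron length
# table (totals, group means, per-feature variability, reference-relative
# exon-3 deltas) and classify intron phases from exon lengths.

suppressMessages(library(orthoarch))
dir.create("results", showWarnings = FALSE)

genomic <- orthoarch:::read_fasta_dna("results/family/genomic.fa")
cdna <- orthoarch:::read_fasta_dna("results/family/cdna.fa")
truth <- read_gff3_exons("results/family/truth.gff3")

exact <- 0L
models <- list()
for (sp in names(genomic)) {
  m <- spliced_align(cdna[[sp]], genomic[[sp]], species = sp)
  models[[sp]] <- m
  exact <- exact + identical(unname(m$exons), unname(truth[[sp]]))
}
cat(sprintf("Boundary recovery on the simulated family: %d/%d species exact\n",
            exact, length(genomic)))
write.table(exon_intron_table(models), "results/family_structure.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

tab <- ssiii_length_table()
s <- summarize_lengths(tab)
write.table(s$species_totals, "results/length_totals.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Reference (maize) exome:",
    s$species_totals$exon_total[s$species_totals$species == "maize"], "bp\n")
cat("Dicot mean total intron length:",
    s$group_mean_totals$intron_total[s$group_mean_totals$group == "dicot"],
    "bp\n")
d3 <- exon_length_delta(tab, "maize", 3)
cat("Exon 3 net deletions vs maize: rice", d3[["rice"]], "bp, arabidopsis",
    d3[["arabidopsis"]], "bp\n")
nw <- summarize_lengths(tab, exclude = "wheat")
cat(sprintf("Intron 13 sd %.2f bp (wheat excluded as draft-assembly outlier)\n",
            nw$feature_sd[["intron13"]]))

phases <- t(vapply(seq_len(nrow(tab)), function(i)
  suppressWarnings(classify_intron_phases(
    as.integer(tab[i, paste0("exon", 1:16)]))), integer(15)))
rownames(phases) <- tab$species
colnames(phases) <- paste0("intron", 1:15)
write.table(data.frame(species = rownames(phases), phases),
            "results/intron_phases.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Intron phase distribution:",
    paste(sprintf("phase %d: %d%%", 0:2,
                  round(100 * tabulate(factor(phases + 1, levels = 1:3)) /
                          length(phases))), collapse = ", "), "\n")
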