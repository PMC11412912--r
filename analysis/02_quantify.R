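#!/usr/bin/env Rscript
# Protein-level quantification: per-channel peptide intensity sums per
# protein, reference-set normalization, and compositional renormalization of
# phosphopeptide-bearing proteins to the fixed 2,000,000 per-channel total.

library(synaptoform)

dird <- "results/data"
out <- "results/quantify"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
reference <- read_gene_list(file.path(dird, "reference.txt"))

for (tag in c("celltype", "genotype")) {
  peptides <- read_peptide_table(file.path(dird, paste0(tag, "_peptides.tsv")))
  prot <- sum_protein_intensities(peptides)
  prot <- normalize_channels(prot, reference)
  write.table(prot, file.path(out, paste0(tag, "_proteins.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  phos_acc <- sort(unique(peptides$protein[peptides$is_phospho]))
  renorm <- do.call(rbind, lapply(phos_acc, function(acc)
    renormalize_phospho(peptides[peptides$protein == acc, ])))
  write.table(renorm, file.path(out, paste0(tag, "_phospho.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  sums <- colSums(renorm[renorm$protein == phos_acc[1],
                         channel_names(renorm)])
  cat(sprintf("%s: %d proteins quantified; phospho renormalized for %d proteins (channel totals %s)\n",
              tag, nrow(prot), length(phos_acc),
              paste(unique(round(sums)), collapse = ", ")))
}
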