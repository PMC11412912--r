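#!/usr/bin/env Rscript
# Two-tier differential analysis of both comparisons: one-tailed Welch t at
# the protein level and the two-way ANOVA genotype-by-peptide interaction at
# the peptide (isoform) level, then a Fisher comparison of how many proteins
# each tier flags.

library(synaptoform)

dird <- "results/data"
dirq <- "results/quantify"
out <- "results/differential"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

groups <- list(
  celltype = setNames(rep(c("iSPN", "dSPN"), each = 5), paste0("ch", 1:10)),
  genotype = setNames(rep(c("wt", "ko"), each = 5), paste0("ch", 1:10)))

counts <- list()
for (tag in names(groups)) {
  peptides <- read_peptide_table(file.path(dird, paste0(tag, "_peptides.tsv")))
  prot <- read.delim(file.path(dirq, paste0(tag, "_proteins.tsv")),
                     check.names = FALSE)
  prot <- select_primary_accession(prot)
  res <- differential_analysis(peptides, prot, groups[[tag]])
  write.table(res, file.path(out, paste0(tag, "_differential.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  counts[[tag]] <- c(protein = sum(res$is_protein_divergent, na.rm = TRUE),
                     isoform = sum(res$is_isoform_divergent, na.rm = TRUE),
                     total = nrow(res))
  cat(sprintf("%s: %d/%d proteins divergent at the protein level, %d/%d at the isoform level\n",
              tag, counts[[tag]]["protein"], nrow(res),
              counts[[tag]]["isoform"], nrow(res)))
}

# is the isoform tier flagging more proteins than the protein tier?
m <- matrix(c(counts$genotype["protein"],
              counts$genotype["total"] - counts$genotype["protein"],
              counts$genotype["isoform"],
              counts$genotype["total"] - counts$genotype["isoform"]),
            2, byrow = TRUE)
cat(sprintf("Fisher test, protein-level vs isoform-level flags (genotype comparison): p = %.3g\n",
            fisher_compare(m)))

# heteroscedasticity profile of the multi-isoform gene in the ko comparison
peptides <- read_peptide_table(file.path(dird, "genotype_peptides.tsv"))
rows <- peptides$protein == "GENE1.full"
mat <- as.matrix(peptides[rows, paste0("ch", 1:10)])
rownames(mat) <- peptides$peptide[rows]
prof <- peptide_fold_profile(mat, groups$genotype)
write.table(prof$qq, file.path(out, "gene1_qq.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("GENE1 peptide log-fold variance %.2f, Brown-Forsythe p = %.3g\n",
            prof$log_ratio_var, prof$levene_p))
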