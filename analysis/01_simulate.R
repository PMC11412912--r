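#!/usr/bin/env Rscript
# Generates the synthetic study inputs: a 22-exon multi-isoform gene with a
# full-length and an exon-17-start isoform, its exon-13-16 deletion variant,
# and two 10-plex reporter-ion experiments -- a cell-type comparison
# (iSPN vs dSPN) and a genotype comparison (wild type vs knockout) in which
# the deletion silences the full-length isoform's unique peptides.

library(synaptoform)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260929L

model <- make_gene_model(22, exon_len_range = c(40, 90), n_isoforms = 2,
                         seed = 5, isoform_starts = 17, gene = "GENE1")
ko_model <- delete_exons(model, as.character(13:16))
write_gene_model(model, file.path(out, "gene1.json"))

full <- translate_isoform(model, "GENE1.full")$sequence
short <- translate_isoform(model, "GENE1.e17")$sequence
cat(sprintf("gene model: %d exons; full isoform %.1f kDa, e17 isoform %.1f kDa\n",
            nrow(model$exons), theoretical_mw(full), theoretical_mw(short)))

# cell-type comparison: shared genotype, a handful of abundance effects
des_ct <- simulation_design(
  channels = paste0("ch", 1:10),
  groups = rep(c("iSPN", "dSPN"), each = 5),
  n_proteins = 40, noise_cv = 0.2,
  effects = list(PROT0001 = c(iSPN = 2.0, dSPN = 1),
                 PROT0002 = c(iSPN = 0.5, dSPN = 1)),
  isoform_effects = list(),
  seed = seed)
sim_ct <- simulate_experiment(des_ct, models = list(GENE1 = model))
write_peptide_table(sim_ct$peptides, file.path(out, "celltype_peptides.tsv"))

# genotype comparison: exon 13-16 deletion in the ko channels
des_ko <- simulation_design(
  channels = paste0("ch", 1:10),
  groups = rep(c("wt", "ko"), each = 5),
  n_proteins = 40, noise_cv = 0.2,
  effects = list(PROT0003 = c(ko = 0.4, wt = 1)),
  seed = seed + 1L)
sim_ko <- simulate_experiment(des_ko, models = list(GENE1 = model),
                              group_models = list(ko = list(GENE1 = ko_model)))
write_peptide_table(sim_ko$peptides, file.path(out, "genotype_peptides.tsv"))

# reference (cytosolic/ER-like) proteins for normalization
writeLines(sprintf("PROT%04d", 21:40), file.path(out, "reference.txt"))

cat(sprintf("cell-type table: %d peptides; genotype table: %d peptides (%d silenced in ko)\n",
            nrow(sim_ct$peptides), nrow(sim_ko$peptides),
            nrow(sim_ko$truth$silenced)))
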