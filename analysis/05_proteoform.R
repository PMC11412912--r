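#!/usr/bin/env Rscript
# Proteoform fingerprinting of the multi-isoform gene: per-isoform standard
# exon detection-frequency tables, gel-slice candidate gating, observed
# fingerprints per genotype group and distance-based isoform assignment with
# a t-SNE view.

library(synaptoform)

dird <- "results/data"
out <- "results/proteoform"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

model <- read_gene_model(file.path(dird, "gene1.json"))
stds <- standard_tables(model)
for (nm in names(stds))
  write.table(stds[[nm]],
              file.path(out, paste0("standard_", sub(".*\\.", "", nm), ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

mws <- vapply(names(model$isoforms), function(nm)
  theoretical_mw(translate_isoform(model, nm)$sequence), numeric(1))
cat("isoform MWs (kDa):",
    paste(sprintf("%s %.1f", names(mws), mws), collapse = ", "), "\n")

# gel-slice gating: a high-MW and a low-MW window
slices <- list(gel_slice("I", c(max(mws) * 0.8, max(mws) * 1.2)),
               gel_slice("II", c(min(mws) * 0.8, min(mws) * 1.2)))
for (sl in slices)
  cat(sprintf("slice %s [%.0f-%.0f kDa] candidates: %s\n", sl$label,
              sl$mw_range[1], sl$mw_range[2],
              paste(filter_isoforms_by_slice(model, sl), collapse = ", ")))

# observed fingerprints per genotype group from the simulated experiment
peptides <- read_peptide_table(file.path(dird, "genotype_peptides.tsv"))
groups <- setNames(rep(c("wt", "ko"), each = 5), paste0("ch", 1:10))
gene_rows <- grepl("^GENE1\\.", peptides$protein)
for (g in c("wt", "ko")) {
  chs <- names(groups)[groups == g]
  detected <- rowMeans(as.matrix(peptides[gene_rows, chs])) > 1000
  obs <- profile_detections(model, peptides$peptide[gene_rows][detected])
  assign <- assign_isoform(obs, stds, method = "embedding", seed = 11)
  write.table(assign, file.path(out, paste0("assignment_", g, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  emb <- attr(assign, "embedding")
  write.table(data.frame(point = rownames(emb), x = emb[, 1], y = emb[, 2]),
              file.path(out, paste0("tsne_", g, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d detection events; nearest standard: %s (distance %.3f)\n",
              g, sum(detected), assign$isoform[assign$rank == 1],
              assign$distance[assign$rank == 1]))
}
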