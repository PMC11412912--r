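# on-disk synthetic fixture for the end-to-end pipeline tests: a 10-channel
# wild-type vs exon-13-16-deletion design with one multi-isoform gene and a
# protein-level fold effect
make_fixture <- function(dir, seed = 40) {
  m <- make_gene_model(22, n_isoforms = 2, seed = 5, isoform_starts = 17)
  ko <- delete_exons(m, as.character(13:16))
  des <- simulation_design(channels = paste0("ch", 1:10),
                           groups = rep(c("wt", "ko"), each = 5),
                           n_proteins = 10, noise_cv = 0.2,
                           effects = list(PROT0002 = c(ko = 2.5, wt = 1)),
                           seed = seed)
  sim <- simulate_experiment(des, models = list(GENE1 = m),
                             group_models = list(ko = list(GENE1 = ko)))
  write_peptide_table(sim$peptides, file.path(dir, "peptides.tsv"))
  writeLines(sprintf("PROT%04d", 6:10), file.path(dir, "reference.txt"))
  write_gene_model(m, file.path(dir, "gene1.json"))
  list(peptides = file.path(dir, "peptides.tsv"),
       reference = file.path(dir, "reference.txt"),
       groups = as.list(des$groups),
       gene_models = list(file.path(dir, "gene1.json")),
       seed = seed, min_detect = 1000,
       outdir = file.path(dir, "out"))
}
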