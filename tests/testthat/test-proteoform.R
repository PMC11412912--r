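toy_model <- function() {
  gene_model("G",
             data.frame(exon = c("20", "21", "22"),
                        segment = c("AAAAAAAK", "CCCCDDDD", "EEEEFFFFK")),
             list(iso = list(exons = c("20", "21", "22"))))
}

test_that("molecular weight matches single-residue closed form and additivity", {
  expect_equal(theoretical_mw("G"), (57.0519 + 18.01528) / 1000,
               tolerance = 1e-9)
  expect_error(theoretical_mw(""), "non-empty")
  set.seed(4)
  for (i in 1:20) {
    s1 <- random_aa_string(sample(5:60, 1))
    s2 <- random_aa_string(sample(5:60, 1))
    expect_equal(theoretical_mw(paste0(s1, s2)),
                 theoretical_mw(s1) + theoretical_mw(s2) - 18.01528 / 1000,
                 tolerance = 1e-12)
  }
})

test_that("hand-summed MW of ACDEFGHIK is reproduced", {
  masses <- c(71.0788, 103.1388, 115.0886, 129.1155, 147.1766, 57.0519,
              137.1411, 113.1594, 128.1741)
  expect_equal(theoretical_mw("ACDEFGHIK"),
               (sum(masses) + 18.01528) / 1000, tolerance = 1e-9)
})

test_that("peptides map to single exons, junctions, and chained labels", {
  m <- toy_model()
  tr <- translate_isoform(m, "iso")
  expect_identical(map_peptide_to_exons(1, 8, tr$residue_labels), "20")
  expect_identical(map_peptide_to_exons(5, 12, tr$residue_labels), "20 & 21")
  expect_identical(map_peptide_to_exons(5, 20, tr$residue_labels),
                   "20 & 21 & 22")
  expect_error(map_peptide_to_exons(20, 30, tr$residue_labels),
               "out of range")
})

test_that("exon mapping equals a per-residue label-scan oracle", {
  set.seed(5)
  m <- make_gene_model(12, c(15, 40), n_isoforms = 1, seed = 8)
  tr <- translate_isoform(m, names(m$isoforms)[1])
  pep <- digest_trypsin(tr$sequence)
  for (i in seq_len(nrow(pep))) {
    labs <- unique(tr$residue_labels[pep$start[i]:pep$end[i]])
    expect_identical(map_peptide_to_exons(pep$start[i], pep$end[i],
                                          tr$residue_labels),
                     paste(labs, collapse = " & "))
  }
})

test_that("frequency tables follow the count-over-total formula", {
  t1 <- exon_frequency_table("5")
  expect_equal(t1$frequency, 1)
  t2 <- exon_frequency_table(c("5", "5", "5 & 6"))
  expect_equal(t2$frequency[t2$label == "5"], 2 / 3)
  expect_equal(t2$frequency[t2$label == "5 & 6"], 1 / 3)
  expect_identical(t2$type, c("exon", "junction"))
  expect_identical(attr(t2, "m"), 1L)
  expect_identical(attr(t2, "n"), 1L)
  expect_error(exon_frequency_table(character(0)), "no detection events")
})

test_that("frequencies sum to one for random detection sets", {
  set.seed(6)
  for (i in 1:200) {
    labels <- sample(c(as.character(1:9), "1 & 2", "4 & 5", "AST:x"),
                     sample(1:40, 1), replace = TRUE)
    tbl <- exon_frequency_table(labels)
    expect_equal(sum(tbl$frequency), 1, tolerance = 1e-12)
    expect_identical(tbl$count,
                     as.integer(table(labels)[tbl$label]))
  }
})

test_that("gel-slice filtering equals direct interval membership", {
  m <- make_gene_model(10, c(20, 50), n_isoforms = 3, seed = 10)
  mws <- vapply(names(m$isoforms), function(nm)
    theoretical_mw(translate_isoform(m, nm)$sequence), numeric(1))
  set.seed(7)
  for (i in 1:20) {
    w <- sort(runif(2, 0, max(mws) * 1.2))
    sl <- gel_slice("X", w)
    expect_setequal(filter_isoforms_by_slice(m, sl),
                    names(mws)[mws >= w[1] & mws <= w[2]])
  }
  expect_identical(
    filter_isoforms_by_slice(m, gel_slice("none", c(1e4, 1e5))),
    character(0))
  expect_error(gel_slice("bad", c(5, 2)), "increasing")
})

test_that("untranslatable isoforms never pass the slice filter", {
  m <- make_gene_model(22, n_isoforms = 2, seed = 5, isoform_starts = 17)
  ko <- delete_exons(m, as.character(13:16))
  sl <- gel_slice("wide", c(0, 1e4))
  expect_identical(filter_isoforms_by_slice(ko, sl), names(m$isoforms)[2])
})

test_that("standard tables: one-exon support, suffix containment, determinism", {
  m1 <- gene_model("G", data.frame(exon = "1", segment = "AAAAAAAKCCCCCCCK"),
                   list(iso = list(exons = "1")))
  s1 <- standard_tables(m1)$iso
  expect_identical(s1$label, "1")
  expect_equal(s1$frequency, 1)

  m <- make_gene_model(22, n_isoforms = 2, seed = 5, isoform_starts = 17)
  stds <- standard_tables(m)
  # downstream of its start, the suffix isoform shares every cleavage site
  # with the full chain, so at most its N-terminal peptide's label can fall
  # outside the full isoform's support
  extra <- setdiff(stds[[2]]$label, stds[[1]]$label)
  first_label <- isoform_peptides(m, names(m$isoforms)[2])$exon_label[1]
  expect_true(all(extra %in% first_label))
  expect_identical(standard_tables(m), stds)
})

test_that("isoform assignment: self-match, permutation invariance", {
  m <- make_gene_model(22, n_isoforms = 2, seed = 5, isoform_starts = 17)
  stds <- standard_tables(m)
  for (nm in names(stds)) {
    a <- assign_isoform(stds[[nm]], stds)
    expect_identical(a$isoform[a$rank == 1], nm)
    expect_equal(a$distance[a$rank == 1], 0)
  }
  a1 <- assign_isoform(stds[[1]], stds)
  a2 <- assign_isoform(stds[[1]], rev(stds))
  expect_identical(a1$isoform, a2$isoform)
  expect_equal(a1$distance, a2$distance)
  expect_error(assign_isoform(stds[[1]], list()), "no standard")
})

test_that("exon-deletion genotype is assigned to the surviving isoform", {
  m <- make_gene_model(22, n_isoforms = 2, seed = 5, isoform_starts = 17)
  stds <- standard_tables(m)
  short <- names(m$isoforms)[2]
  obs <- exon_frequency_table(isoform_peptides(m, short)$exon_label)
  a <- assign_isoform(obs, stds)
  expect_identical(a$isoform[a$rank == 1], short)
})

test_that("the embedding layout is deterministic and attached", {
  m <- make_gene_model(14, n_isoforms = 4, seed = 12)
  stds <- standard_tables(m)
  a1 <- assign_isoform(stds[[2]], stds, method = "embedding", seed = 3)
  a2 <- assign_isoform(stds[[2]], stds, method = "embedding", seed = 3)
  emb <- attr(a1, "embedding")
  expect_identical(dim(emb), c(5L, 2L))
  expect_identical(emb, attr(a2, "embedding"))
  # ranking identical to the distance method
  expect_identical(a1$isoform, assign_isoform(stds[[2]], stds)$isoform)
})
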