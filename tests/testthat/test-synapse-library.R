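toy_ann <- function() {
  annotation_sets(
    broad_postsynaptic = c("a", "b", "c", "d", "preX"),
    curated_presynaptic = c("preX", "preY", "both1"),
    curated_postsynaptic = c("c", "e", "both1"),
    nonsynaptic_membrane = c("m1", "m2"),
    cytosolic_er = c("cy1", "cy2", "a"))
}

test_that("training-set merge/clean follows the two-database rules", {
  ts <- build_training_set(toy_ann())
  pos <- ts$gene[ts$label == "postsynaptic"]
  # dual-annotated gene counts as postsynaptic
  expect_true("both1" %in% pos)
  # exclusively presynaptic gene removed from the broad set
  expect_false("preX" %in% pos)
  expect_setequal(pos, c("a", "b", "c", "d", "e", "both1"))
  # negatives: exclusive presynaptic + membrane + cytosolic, minus positives
  neg <- ts$gene[ts$label == "negative"]
  expect_setequal(neg, c("preX", "preY", "m1", "m2", "cy1", "cy2"))
})

test_that("training-set size matches the set-algebra oracle on random sets", {
  set.seed(20)
  pool <- paste0("g", 1:60)
  for (i in 1:20) {
    ann <- annotation_sets(sample(pool, 25), sample(pool, 12),
                           sample(pool, 12), sample(pool, 8),
                           sample(pool, 8))
    ts <- tryCatch(build_training_set(ann), error = function(e) NULL)
    if (is.null(ts)) next
    pre_only <- setdiff(ann$curated_presynaptic, ann$curated_postsynaptic)
    want_pos <- union(setdiff(ann$broad_postsynaptic, pre_only),
                      ann$curated_postsynaptic)
    expect_setequal(ts$gene[ts$label == "postsynaptic"], want_pos)
  }
})

test_that("training set is invariant to input ordering and detects namespace mismatch", {
  a <- toy_ann()
  b <- annotation_sets(rev(a$broad_postsynaptic), rev(a$curated_presynaptic),
                       rev(a$curated_postsynaptic),
                       rev(a$nonsynaptic_membrane), rev(a$cytosolic_er))
  expect_identical(build_training_set(a), build_training_set(b))
  bad <- annotation_sets(c("x1", "x2"), c("y1"), c("y2"), "y3", "y4")
  expect_error(build_training_set(bad), "namespace")
})

test_that("feature extraction applies the two-peptide rule and computes folds/coverage", {
  seqs <- c(P1 = paste0(paste(rep("A", 22), collapse = ""), "K",
                        paste(rep("C", 7), collapse = ""), "K"),
            P2 = paste0(paste(rep("D", 30), collapse = ""), "R"))
  # P1 has 2 peptides; P2 only 1 -> dropped
  tbl <- toy_peptide_table(
    c(paste0(paste(rep("A", 22), collapse = ""), "K"),
      paste0(paste(rep("C", 7), collapse = ""), "K"),
      paste0(paste(rep("D", 30), collapse = ""), "R")),
    c("P1", "P1", "P2"),
    list(pre = c(10, 10, 5), cyto = c(10, 10, 5), post = c(40, 40, 20)),
    spec_count = c(2L, 3L, 1L))
  fv <- extract_features(tbl, c(pre = "pre", cyto = "cyto", post = "post"),
                         seqs, reference = "P1")
  expect_identical(fv$protein, "P1")
  expect_equal(fv$fold_post_over_cyto, 4)
  expect_equal(fv$fold_pre_over_cyto, 1)
  expect_equal(fv$sequence_coverage, 1)
  expect_equal(fv$spec_count, 5L)
  expect_equal(fv$molecular_weight, theoretical_mw(seqs[["P1"]]))
})

test_that("coverage uses the interval union of peptide matches", {
  # 100-aa protein, peptides covering 1-30 and 21-50 -> 0.50
  prot <- paste0(paste(rep("A", 20), collapse = ""),
                 paste(rep("C", 10), collapse = ""),
                 paste(rep("D", 20), collapse = ""),
                 paste(rep("E", 50), collapse = ""))
  peps <- c(substr(prot, 1, 30), substr(prot, 21, 50))
  tbl <- toy_peptide_table(peps, "P1", list(pre = c(1, 1), cyto = c(1, 1),
                                            post = c(1, 1)))
  fv <- extract_features(tbl, c(pre = "pre", cyto = "cyto", post = "post"),
                         c(P1 = prot), reference = "P1")
  expect_equal(fv$sequence_coverage, 0.5)
  expect_equal(fv$sequence_coverage, oracle_coverage(prot, peps))
  expect_error(
    extract_features(tbl, c(pre = "pre", cyto = "cyto", post = "post"),
                     c(OTHER = prot), reference = "P1"),
    "missing sequence")
})

test_that("isoelectric point behaves like a pH-scale charge balance", {
  # basic sequence -> high pI; acidic -> low pI
  expect_gt(isoelectric_point("KKKKRRRR"), 10)
  expect_lt(isoelectric_point("DDDDEEEE"), 4.5)
  expect_gt(isoelectric_point("AAAAAALG"), 5)
})

test_that("classifier separates classes when separated and not otherwise", {
  null_sim <- simulate_classifier_proteome(100, separation = 0, seed = 21)
  lab <- ifelse(null_sim$truth == "postsynaptic", "postsynaptic", "negative")
  s0 <- train_and_classify(null_sim$features, lab, ntree = 300, seed = 1)
  r0 <- roc_curve(s0, lab[names(s0)])
  expect_gt(r0$auc, 0.42)
  expect_lt(r0$auc, 0.58)

  sep_sim <- simulate_classifier_proteome(100, separation = 4, seed = 21)
  lab2 <- ifelse(sep_sim$truth == "postsynaptic", "postsynaptic", "negative")
  s1 <- train_and_classify(sep_sim$features, lab2, ntree = 300, seed = 1)
  expect_gt(roc_curve(s1, lab2[names(s1)])$auc, 0.9)
  expect_error(
    train_and_classify(sep_sim$features,
                       setNames(rep("postsynaptic", nrow(sep_sim$features)),
                                sep_sim$features$gene)),
    "both classes")
})

test_that("identical feature rows receive identical scores", {
  sim <- simulate_classifier_proteome(30, separation = 2, seed = 22)
  f <- sim$features
  f2 <- rbind(f, transform(f[1, ], gene = "DUP1"),
              transform(f[1, ], gene = "DUP2"))
  lab <- ifelse(sim$truth == "postsynaptic", "postsynaptic", "negative")
  s <- train_and_classify(f2, lab, ntree = 200, seed = 2)
  # identical unlabeled feature rows get identical scores
  expect_identical(s[["DUP1"]], s[["DUP2"]])
  # and the whole scoring is deterministic under a fixed seed
  expect_identical(s, train_and_classify(f2, lab, ntree = 200, seed = 2))
})

test_that("ROC equals the pairwise-concordance oracle and pROC cross-check", {
  set.seed(23)
  scores <- runif(40)
  labels <- sample(c(TRUE, FALSE), 40, TRUE)
  r <- roc_curve(scores, labels)
  expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
  # tied scores
  scores2 <- round(scores, 1)
  expect_equal(roc_curve(scores2, labels)$auc,
               oracle_auc(scores2, labels), tolerance = 1e-12)
  skip_if_not_installed("pROC")
  pr <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("perfect and random separation hit the AUROC endpoints", {
  lab <- rep(c(TRUE, FALSE), each = 20)
  expect_equal(roc_curve(c(rep(1, 20), rep(0, 20)), lab)$auc, 1)
  set.seed(24)
  big <- roc_curve(runif(4000), sample(c(TRUE, FALSE), 4000, TRUE))
  expect_lt(abs(big$auc - 0.5), 0.05)
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("library assembly enforces the two-experiment rule", {
  sc <- list(c(a = 0.9, b = 0.2, c = 0.7), c(a = 0.8, b = 0.9, c = 0.3),
             c(a = 0.1, b = 0.95, c = 0.2))
  lib <- assemble_library(sc, threshold = 0.5)
  expect_true(lib$included[lib$gene == "a"])   # positive in 2 of 3
  expect_true(lib$included[lib$gene == "b"])   # positive in 2 of 3
  expect_false(lib$included[lib$gene == "c"])  # positive in only 1 of 3
  expect_identical(lib$n_experiments_positive, c(2L, 2L, 1L))
  expect_true(all(lib$included == (lib$n_experiments_positive >= 2L)))
  expect_error(assemble_library(sc[1]), "two experiments")
})

test_that("library assembly equals a brute-force count-and-filter oracle", {
  set.seed(25)
  genes <- paste0("g", 1:30)
  sc <- lapply(1:4, function(i)
    setNames(runif(25), sample(genes, 25)))
  lib <- assemble_library(sc, threshold = 0.6)
  for (g in lib$gene) {
    n <- sum(vapply(sc, function(s) !is.na(s[g]) && s[g] >= 0.6, logical(1)))
    expect_identical(lib$n_experiments_positive[lib$gene == g], n)
    expect_identical(lib$included[lib$gene == g], n >= 2L)
  }
})

test_that("library FDRs are the annotated contaminant fractions", {
  ann <- toy_ann()
  lib <- data.frame(gene = c(paste0("ok", 1:97), "preY", "m1", "m2"),
                    included = TRUE)
  fdr <- estimate_library_fdr(lib, ann)
  expect_equal(fdr$fdr_presynaptic, 0.01)
  expect_equal(fdr$fdr_nonsynaptic_membrane, 0.02)
  clean <- data.frame(gene = paste0("ok", 1:10), included = TRUE)
  fdr0 <- estimate_library_fdr(clean, ann)
  expect_equal(fdr0$fdr_presynaptic, 0)
  expect_equal(fdr0$fdr_nonsynaptic_membrane, 0)
})
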