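test_that("primary-accession selection keeps the highest-total accession", {
  tbl <- data.frame(protein = c("Q1", "Q2", "Q3"),
                    gene = c("g1", "g1", "g2"), n_peptides = 2L,
                    ch1 = c(10, 20, 5), ch2 = c(0, 0, 1))
  out <- select_primary_accession(tbl)
  expect_setequal(out$protein, c("Q2", "Q3"))
  single <- tbl[3, , drop = FALSE]
  expect_equal(select_primary_accession(single)$protein, "Q3")
})

test_that("primary-accession selection equals an argmax-per-gene oracle with lexicographic ties", {
  set.seed(12)
  n <- 80
  tbl <- data.frame(protein = paste0("ACC", sprintf("%03d", sample(n))),
                    gene = sample(paste0("g", 1:15), n, TRUE),
                    n_peptides = 2L,
                    ch1 = sample(1:10, n, TRUE) * 1.0,
                    ch2 = sample(1:10, n, TRUE) * 1.0)
  out <- select_primary_accession(tbl)
  for (g in unique(tbl$gene)) {
    rows <- tbl[tbl$gene == g, ]
    tot <- rows$ch1 + rows$ch2
    best <- sort(rows$protein[tot == max(tot)])[1]
    expect_identical(out$protein[out$gene == g], best)
  }
})

test_that("one-tailed t-test: symmetry gives p = 0.5 and folds are ratios of means", {
  r <- protein_level_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p, 0.5)
  expect_equal(protein_level_test(c(2, 2), c(1, 1))$fold, 2)
  expect_error(protein_level_test(1, c(1, 2)), "at least 2")
})

test_that("one-tailed t-test is invariant to common rescaling of both groups", {
  set.seed(13)
  x <- rlnorm(5); y <- rlnorm(5)
  a <- protein_level_test(x, y, direction = "greater")
  b <- protein_level_test(10 * x, 10 * y, direction = "greater")
  expect_equal(a$p, b$p)
  expect_equal(a$fold, b$fold)
})

test_that("fixed-direction t-test type-I error is near nominal (quick check)", {
  set.seed(14)
  rej <- mean(replicate(400, {
    protein_level_test(rnorm(5), rnorm(5), direction = "greater")$p < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("noise-free additive peptides give zero interaction sum of squares", {
  m <- outer(c(100, 500, 1000), c(1, 1, 1, 4, 4, 4))  # common fold of 4
  rownames(m) <- paste0("p", 1:3)
  r <- isoform_level_test(m, rep(c("g1", "g2"), each = 3))
  expect_true(r$assessable)
  expect_equal(r$ss_interaction, 0, tolerance = 1e-12)
  expect_false(isTRUE(r$is_isoform_divergent))
})

test_that("a silenced peptide subset drives the interaction term", {
  set.seed(15)
  m <- matrix(rlnorm(5 * 10, log(1e5), 0.2), 5, 10)
  m[4:5, 6:10] <- m[4:5, 6:10] * 1e-3
  r <- isoform_level_test(m, rep(c("wt", "ko"), each = 5))
  expect_lt(r$p_interaction, 1e-6)
  expect_true(r$is_isoform_divergent)
})

test_that("single-peptide proteins are flagged not assessable", {
  m <- matrix(rlnorm(6, 10, 0.1), 1, 6)
  r <- isoform_level_test(m, rep(c("a", "b"), each = 3))
  expect_false(r$assessable)
  expect_true(is.na(r$p_interaction))
})

test_that("fold profile: identical folds give zero variance, mixtures inflate it", {
  m <- outer(c(10, 20, 40, 80), c(1, 1, 1, 2, 2, 2))
  p <- peptide_fold_profile(m, rep(c("a", "b"), each = 3))
  expect_equal(p$log_ratio_var, 0, tolerance = 1e-12)
  expect_equal(unname(p$fold), rep(0.5, 4))

  set.seed(16)
  null_var <- mean(replicate(40, {
    mm <- matrix(rlnorm(8 * 10, log(1e4), 0.2), 8, 10)
    peptide_fold_profile(mm, rep(c("a", "b"), each = 5))$log_ratio_var
  }))
  mm <- matrix(rlnorm(8 * 10, log(1e4), 0.2), 8, 10)
  mm[1:4, 6:10] <- mm[1:4, 6:10] * 0.1   # half the peptides at fold 0.1
  alt <- peptide_fold_profile(mm, rep(c("a", "b"), each = 5))
  expect_gt(alt$log_ratio_var, 10 * null_var)
  expect_lt(alt$levene_p, 0.05)
})

test_that("Q-Q pairs of near-normal log-ratios track the diagonal", {
  set.seed(17)
  m <- matrix(rlnorm(200 * 8, log(1e4), 0.2), 200, 8)
  p <- peptide_fold_profile(m, rep(c("a", "b"), each = 4))
  expect_true(all(diff(p$qq$empirical) >= 0))
  mid <- abs(p$qq$theoretical) < 1.5
  expect_lt(max(abs(p$qq$theoretical[mid] - p$qq$empirical[mid])), 0.35)
})

test_that("Fisher p-values match closed forms and full enumeration", {
  expect_equal(fisher_compare(matrix(1, 2, 2)), 1)
  expect_equal(fisher_compare(matrix(0, 2, 2)), 1)
  m <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(fisher_compare(m), oracle_fisher(m), tolerance = 1e-12)
  set.seed(18)
  for (i in 1:50) {
    m <- matrix(sample(0:8, 4, TRUE), 2)
    if (sum(m) == 0) next
    expect_equal(fisher_compare(m), oracle_fisher(m), tolerance = 1e-9)
  }
  expect_error(fisher_compare(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  expect_error(fisher_compare(matrix(1, 3, 3)), "2x2")
})

test_that("differential_analysis flags injected protein and isoform effects", {
  m <- make_gene_model(22, n_isoforms = 2, seed = 5, isoform_starts = 17)
  ko <- delete_exons(m, as.character(13:16))
  des <- simulation_design(
    channels = paste0("ch", 1:10), groups = rep(c("wt", "ko"), each = 5),
    n_proteins = 12, noise_cv = 0.2,
    effects = list(PROT0002 = c(ko = 3, wt = 1)), seed = 19)
  sim <- simulate_experiment(des, models = list(GENE1 = m),
                             group_models = list(ko = list(GENE1 = ko)))
  prot <- normalize_channels(sum_protein_intensities(sim$peptides),
                             sprintf("PROT%04d", 5:12))
  res <- differential_analysis(sim$peptides, prot, des$groups)
  g1 <- res[res$gene == "GENE1", ]
  expect_true(g1$is_isoform_divergent)
  p2 <- res[res$protein == "PROT0002", ]
  expect_lt(p2$p_protein, 0.01)
  expect_gt(p2$mean_fold, 2)   # groups sorted: ko/wt
  # null background proteins are mostly quiet at the isoform level
  bg <- res[!res$protein %in% c("GENE1.full", "PROT0002"), ]
  expect_lt(mean(bg$is_isoform_divergent, na.rm = TRUE), 0.3)
})
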