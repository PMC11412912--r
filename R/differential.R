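#' Keep one accession per gene: the highest-total-intensity one
#'
#' For genes quantified under multiple isoform accessions, only the accession
#' with the highest total reporter-ion intensity (summed over all channels)
#' is retained; ties break lexicographically by accession so the result is
#' deterministic.
#'
#' @param proteins protein-level table with a `gene` column.
#' @return the filtered table, one row per gene.
#' @export
select_primary_accession <- function(proteins) {
  if (is.null(proteins$gene)) stop("table must carry gene symbols")
  ch <- channel_names(proteins)
  total <- rowSums(as.matrix(proteins[, ch, drop = FALSE]))
  ord <- order(proteins$gene, -total, proteins$protein)
  proteins <- proteins[ord, , drop = FALSE]
  out <- proteins[!duplicated(proteins$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-tailed Welch t-test between two groups of protein intensities
#'
#' Welch's t-test (unequal variances assumed throughout) with a one-tailed
#' p-value, plus the ratio of group means. With `direction = "auto"` the test
#' is run in the direction of the observed mean difference; this convention
#' is anticonservative under the null (p is capped at 0.5) and exists because
#' one-tailed p-values are routinely reported for both up- and down-regulated
#' proteins; use a fixed direction for calibration work.
#'
#' @param values_g1,values_g2 numeric vectors, >= 2 values each.
#' @param direction `"greater"` (mean1 > mean2), `"less"`, or `"auto"`.
#' @return list with `p`, `fold` (mean1 / mean2) and the `direction` tested.
#' @export
protein_level_test <- function(values_g1, values_g2,
                               direction = c("auto", "greater", "less")) {
  direction <- match.arg(direction)
  if (length(values_g1) < 2L || length(values_g2) < 2L)
    stop("each group needs at least 2 values")
  if (direction == "auto")
    direction <- if (mean(values_g1) >= mean(values_g2)) "greater" else "less"
  se2 <- stats::var(values_g1) / length(values_g1) +
    stats::var(values_g2) / length(values_g2)
  delta <- mean(values_g1) - mean(values_g2)
  if (se2 <= (.Machine$double.eps * max(abs(values_g1), abs(values_g2)))^2) {
    # degenerate zero-variance groups (e.g. the median reference protein
    # after normalization): the t statistic is 0/0 or +/-Inf
    p <- if (delta == 0) 0.5
         else if ((delta > 0) == (direction == "greater")) 0 else 1
  } else {
    p <- t.test(values_g1, values_g2, alternative = direction,
                var.equal = FALSE)$p.value
  }
  list(p = p, fold = mean(values_g1) / mean(values_g2),
       direction = direction)
}

#' Two-way ANOVA isoform-level test on a protein's peptide matrix
#'
#' Fits intensity ~ genotype * peptide on log2-transformed values (reporter
#' ion noise is multiplicative) and reports the genotype, peptide and
#' genotype-by-peptide interaction p-values (type-II sums of squares; the
#' simulated designs are balanced, where type I and II coincide). A protein
#' whose peptides respond non-uniformly to the group contrast -- the isoform
#' signature -- shows up in the interaction term. With a single peptide the
#' interaction is undefined and the protein is flagged not assessable.
#'
#' @param peptide_matrix numeric matrix, peptides x channels, positive
#'   entries (use [simulate_experiment()]'s silencing floor, or add an offset
#'   before calling, if zeros can occur).
#' @param group_labels factor/character of length `ncol(peptide_matrix)`.
#' @param alpha significance level for the divergence call.
#' @return list with `assessable`, `p_genotype`, `p_peptide`,
#'   `p_interaction`, `ss_interaction` and `is_isoform_divergent`.
#' @export
isoform_level_test <- function(peptide_matrix, group_labels, alpha = 0.05) {
  m <- as.matrix(peptide_matrix)
  group_labels <- as.factor(group_labels)
  if (ncol(m) != length(group_labels))
    stop("one group label per channel is required")
  if (min(table(group_labels)) < 2L)
    stop("need >= 2 channels per group")
  if (nrow(m) < 2L)
    return(list(assessable = FALSE, p_genotype = NA_real_,
                p_peptide = NA_real_, p_interaction = NA_real_,
                ss_interaction = NA_real_, is_isoform_divergent = NA))
  if (any(m <= 0)) stop("peptide intensities must be positive on log scale")
  if (is.null(rownames(m))) rownames(m) <- paste0("pep", seq_len(nrow(m)))
  d <- data.frame(
    y = log2(as.vector(m)),
    peptide = factor(rep(rownames(m), times = ncol(m))),
    genotype = factor(rep(group_labels, each = nrow(m)))
  )
  fit <- lm(y ~ genotype * peptide, data = d)
  ss_int <- suppressWarnings(anova(fit)["genotype:peptide", "Sum Sq"])
  if (sum(stats::residuals(fit)^2) < 1e-20) {
    # saturated noise-free fit: F undefined; interaction SS decides
    p_int <- if (ss_int < 1e-12) NA_real_ else 0
    return(list(assessable = TRUE, p_genotype = NA_real_,
                p_peptide = NA_real_, p_interaction = p_int,
                ss_interaction = ss_int,
                is_isoform_divergent = isTRUE(p_int < alpha)))
  }
  a2 <- car::Anova(fit, type = 2)
  p <- a2[["Pr(>F)"]]
  names(p) <- rownames(a2)
  list(assessable = TRUE,
       p_genotype = unname(p["genotype"]),
       p_peptide = unname(p["peptide"]),
       p_interaction = unname(p["genotype:peptide"]),
       ss_interaction = ss_int,
       is_isoform_divergent = unname(p["genotype:peptide"] < alpha))
}

#' Per-peptide fold profile and heteroscedasticity diagnostics
#'
#' Computes, for one protein, the per-peptide ratio of group means, the
#' variance of the log2 ratios, and paired theoretical-normal vs empirical
#' quantiles of the standardized log2 ratios for Q-Q display. As a scalar
#' summary it also reports a Brown-Forsythe (median-centred Levene)
#' variance-homogeneity p-value comparing, between the two groups, the spread
#' across peptides of group-centred peptide mean log-intensities: isoform
#' silencing inflates the affected group's across-peptide spread, which is
#' the quantitative counterpart of a heteroscedastic Q-Q fan.
#'
#' @inheritParams isoform_level_test
#' @return list with `fold` (named per-peptide ratios), `log_ratio_var`,
#'   `qq` (data frame `theoretical`, `empirical`), and `levene_p`.
#' @export
peptide_fold_profile <- function(peptide_matrix, group_labels) {
  m <- as.matrix(peptide_matrix)
  group_labels <- as.factor(group_labels)
  if (ncol(m) != length(group_labels))
    stop("one group label per channel is required")
  if (nlevels(group_labels) != 2L) stop("exactly two groups are required")
  if (min(table(group_labels)) < 2L) stop("need >= 2 channels per group")
  if (any(m <= 0)) stop("peptide intensities must be positive")
  if (is.null(rownames(m))) rownames(m) <- paste0("pep", seq_len(nrow(m)))
  g <- levels(group_labels)
  m1 <- rowMeans(m[, group_labels == g[1], drop = FALSE])
  m2 <- rowMeans(m[, group_labels == g[2], drop = FALSE])
  fold <- m1 / m2
  lr <- log2(fold)
  v <- stats::var(lr)
  z <- if (length(lr) > 1L && v > 0) (lr - mean(lr)) / sqrt(v) else lr * 0
  qq <- data.frame(theoretical = qnorm(ppoints(length(z))),
                   empirical = sort(z))
  lm1 <- log2(m1); lm2 <- log2(m2)
  lev <- data.frame(
    value = c(lm1 - mean(lm1), lm2 - mean(lm2)),
    group = factor(rep(g, each = nrow(m)))
  )
  levene_p <- tryCatch(
    car::leveneTest(value ~ group, data = lev,
                    center = median)[1, "Pr(>F)"],
    error = function(e) NA_real_)
  list(fold = stats::setNames(fold, rownames(m)), log_ratio_var = v,
       qq = qq, levene_p = levene_p)
}

#' Two-sided Fisher's exact test on a 2x2 count table
#'
#' Exact hypergeometric p-value; an all-zero table returns 1 by convention.
#'
#' @param counts_2x2 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_compare <- function(counts_2x2) {
  m <- as.matrix(counts_2x2)
  if (!all(dim(m) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(m != round(m))) stop("counts must be integers")
  if (sum(m) == 0) return(1)
  fisher.test(m, alternative = "two.sided")$p.value
}

#' Protein- and isoform-level differential analysis of a quantified experiment
#'
#' Runs the one-tailed protein-level test on normalized protein intensities
#' and the two-way ANOVA isoform-level test on each protein's peptide matrix,
#' for a two-group channel design. Raw p-values are reported (as in
#' supplementary-table convention); Benjamini-Hochberg adjusted columns are
#' added as a convenience.
#'
#' @param peptides peptide quantification table.
#' @param proteins normalized protein table ([normalize_channels()]).
#' @param groups named character/factor vector channel -> group (two groups).
#' @param alpha significance level.
#' @param gene_map optional accession -> gene map (see
#'   [sum_protein_intensities()]).
#' @return data frame, one row per protein: `protein`, `gene`, `mean_fold`,
#'   `p_protein`, `p_genotype`, `p_peptide`, `p_interaction`,
#'   `is_protein_divergent`, `is_isoform_divergent`, plus BH-adjusted
#'   `padj_protein` and `padj_interaction`.
#' @export
differential_analysis <- function(peptides, proteins, groups, alpha = 0.05,
                                  gene_map = NULL) {
  groups <- stats::setNames(as.character(groups), names(groups))
  ch <- channel_names(proteins)
  if (!all(ch %in% names(groups)))
    stop("groups must label every channel: missing ",
         paste(setdiff(ch, names(groups)), collapse = ", "))
  glev <- sort(unique(groups[ch]))
  if (length(glev) != 2L) stop("exactly two groups are required")
  ch1 <- ch[groups[ch] == glev[1]]
  ch2 <- ch[groups[ch] == glev[2]]
  norm_cols <- paste0("norm_", ch)
  use_norm <- all(norm_cols %in% names(proteins))
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    acc <- proteins$protein[i]
    cols1 <- if (use_norm) paste0("norm_", ch1) else ch1
    cols2 <- if (use_norm) paste0("norm_", ch2) else ch2
    pt <- protein_level_test(as.numeric(proteins[i, cols1]),
                             as.numeric(proteins[i, cols2]))
    # peptide matrix for this accession (shared peptides included)
    hit <- vapply(strsplit(peptides$protein, ";", fixed = TRUE),
                  function(a) acc %in% a, logical(1))
    m <- as.matrix(peptides[hit, ch, drop = FALSE])
    rownames(m) <- peptides$peptide[hit]
    it <- isoform_level_test(m, groups[ch], alpha = alpha)
    data.frame(protein = acc, gene = proteins$gene[i],
               mean_fold = pt$fold, p_protein = pt$p,
               p_genotype = it$p_genotype, p_peptide = it$p_peptide,
               p_interaction = it$p_interaction,
               is_protein_divergent = pt$p < alpha,
               is_isoform_divergent = it$is_isoform_divergent,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj_protein <- p.adjust(out$p_protein, method = "BH")
  out$padj_interaction <- p.adjust(out$p_interaction, method = "BH")
  out
}
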