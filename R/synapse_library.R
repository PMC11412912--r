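# pKa set for the Henderson-Hasselbalch charge sum (EMBOSS values)
PKA_POS <- c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
PKA_NEG <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

#' Isoelectric point of a protein sequence
#'
#' Bisection on the Henderson-Hasselbalch net-charge sum with the EMBOSS pKa
#' set (N-terminus 8.6, K 10.8, R 12.5, H 6.5; C-terminus 3.6, D 3.9, E 4.1,
#' C 8.5, Y 10.1).
#'
#' @param sequence amino-acid string.
#' @param tol bisection tolerance in pH units.
#' @return estimated pI in pH units.
#' @export
isoelectric_point <- function(sequence, tol = 1e-4) {
  chars <- check_sequence(sequence)
  counts <- table(chars)
  n_pos <- c(Nterm = 1, K = counts["K"], R = counts["R"], H = counts["H"])
  n_neg <- c(Cterm = 1, D = counts["D"], E = counts["E"], C = counts["C"],
             Y = counts["Y"])
  n_pos[is.na(n_pos)] <- 0
  n_neg[is.na(n_neg)] <- 0
  charge <- function(ph) {
    pos <- sum(n_pos / (1 + 10^(ph - PKA_POS)))
    neg <- sum(n_neg / (1 + 10^(PKA_NEG - ph)))
    pos - neg
  }
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (charge(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Assemble annotation sets for training and FDR estimation
#'
#' @param broad_postsynaptic broad postsynaptic gene set (deep-coverage,
#'   proteomics-derived; may contain misclassified presynaptic genes).
#' @param curated_presynaptic,curated_postsynaptic curated (experimentally
#'   validated) pre-/postsynaptic gene sets.
#' @param nonsynaptic_membrane,cytosolic_er gene sets used for FDR estimation
#'   and channel normalization.
#' @return list of class `annotation_sets`.
#' @export
annotation_sets <- function(broad_postsynaptic, curated_presynaptic,
                            curated_postsynaptic, nonsynaptic_membrane,
                            cytosolic_er) {
  structure(list(broad_postsynaptic = unique(as.character(broad_postsynaptic)),
                 curated_presynaptic = unique(as.character(curated_presynaptic)),
                 curated_postsynaptic = unique(as.character(curated_postsynaptic)),
                 nonsynaptic_membrane = unique(as.character(nonsynaptic_membrane)),
                 cytosolic_er = unique(as.character(cytosolic_er))),
            class = "annotation_sets")
}

#' Genes exclusively presynaptic in the curated source
#' @param ann an [annotation_sets()].
#' @export
exclusive_presynaptic <- function(ann) {
  setdiff(ann$curated_presynaptic, ann$curated_postsynaptic)
}

#' Build the labelled training set from two annotation databases
#'
#' Merge/clean procedure: genes curated as both pre- and postsynaptic count
#' as postsynaptic; the exclusively presynaptic curated set is subtracted
#' from the broad postsynaptic set; the cleaned broad set is unioned with the
#' curated postsynaptic set to form the positives. Negatives are the
#' exclusively presynaptic, non-synaptic membrane and cytosolic/ER genes not
#' among the positives (mirroring the two contaminant categories the library
#' FDR is reported against).
#'
#' @param ann an [annotation_sets()].
#' @return data frame with columns `gene` and `label`
#'   (`"postsynaptic"`/`"negative"`), sorted by gene so the result is
#'   invariant to input-set ordering.
#' @export
build_training_set <- function(ann) {
  stopifnot(inherits(ann, "annotation_sets"))
  if (length(ann$broad_postsynaptic) == 0L ||
      length(ann$curated_presynaptic) + length(ann$curated_postsynaptic) == 0L)
    stop("annotation sets must be non-empty")
  curated <- union(ann$curated_presynaptic, ann$curated_postsynaptic)
  if (length(intersect(ann$broad_postsynaptic, curated)) == 0L)
    stop("identifier namespaces do not overlap between the broad and the ",
         "curated annotation sets")
  pre_only <- exclusive_presynaptic(ann)
  cleaned_broad <- setdiff(ann$broad_postsynaptic, pre_only)
  positives <- union(cleaned_broad, ann$curated_postsynaptic)
  negatives <- setdiff(
    Reduce(union, list(pre_only, ann$nonsynaptic_membrane, ann$cytosolic_er)),
    positives)
  out <- data.frame(
    gene = c(positives, negatives),
    label = rep(c("postsynaptic", "negative"),
                c(length(positives), length(negatives))),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

interval_union_length <- function(starts, ends) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  total <- 0L; cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= cur_e + 1L) cur_e <- max(cur_e, ends[i])
    else { total <- total + cur_e - cur_s + 1L; cur_s <- starts[i]; cur_e <- ends[i] }
  }
  total + cur_e - cur_s + 1L
}

#' Extract the ten classifier features per protein
#'
#' From a peptide quantification table of a 3-plex probe experiment (one
#' channel per probe: presynaptic, cytosolic, postsynaptic), computes per
#' protein: spectral count, sequence coverage (interval union of peptide
#' matches on the protein sequence), molecular weight (kDa, average masses),
#' isoelectric point, log10(total peptide intensity / protein length), the
#' pre/cyto and post/cyto fold changes, and the three reference-normalized
#' channel values. Proteins with fewer than two quantified peptides are
#' dropped; for genes with several isoform accessions only the
#' highest-total-intensity accession is kept.
#'
#' @param peptides peptide quantification table.
#' @param channel_roles named character vector mapping roles `pre`, `cyto`,
#'   `post` to channel names.
#' @param sequences named character vector accession -> protein sequence.
#' @param reference accessions of cytosolic/ER proteins used as the
#'   normalization reference.
#' @param gene_map optional accession -> gene map.
#' @return data frame: `gene`, `protein`, then the ten features in fixed
#'   order (`spec_count`, `sequence_coverage`, `molecular_weight`,
#'   `isoelectric_point`, `log_density`, `fold_pre_over_cyto`,
#'   `fold_post_over_cyto`, `norm_pre`, `norm_cyto`, `norm_post`).
#' @export
extract_features <- function(peptides, channel_roles, sequences, reference,
                             gene_map = NULL) {
  roles <- c("pre", "cyto", "post")
  if (!all(roles %in% names(channel_roles)))
    stop("channel_roles must name channels for pre, cyto and post probes")
  validate_peptide_table(peptides)
  prot <- sum_protein_intensities(peptides, gene_map = gene_map)
  prot <- prot[prot$n_peptides >= 2L, , drop = FALSE]
  prot <- select_primary_accession(prot)
  missing_seq <- setdiff(prot$protein, names(sequences))
  if (length(missing_seq))
    stop("missing sequence for accession(s): ",
         paste(missing_seq, collapse = ", "))
  prot <- normalize_channels(prot, reference)
  pre <- channel_roles[["pre"]]; cyto <- channel_roles[["cyto"]]
  post <- channel_roles[["post"]]
  rows <- lapply(seq_len(nrow(prot)), function(i) {
    acc <- prot$protein[i]
    seqp <- sequences[[acc]]
    hit <- vapply(strsplit(peptides$protein, ";", fixed = TRUE),
                  function(a) acc %in% a, logical(1))
    pp <- peptides[hit, , drop = FALSE]
    # locate peptides on the sequence for coverage
    starts <- integer(0); ends <- integer(0)
    for (p in unique(pp$peptide)) {
      at <- gregexpr(p, seqp, fixed = TRUE)[[1]]
      if (at[1] > 0) {
        starts <- c(starts, as.integer(at))
        ends <- c(ends, as.integer(at) + nchar(p) - 1L)
      }
    }
    coverage <- if (length(starts))
      interval_union_length(starts, ends) / nchar(seqp) else 0
    total_int <- sum(as.matrix(pp[, channel_names(peptides), drop = FALSE]))
    data.frame(
      gene = prot$gene[i], protein = acc,
      spec_count = sum(pp$spec_count),
      sequence_coverage = coverage,
      molecular_weight = theoretical_mw(seqp),
      isoelectric_point = isoelectric_point(seqp),
      log_density = log10(total_int / nchar(seqp)),
      fold_pre_over_cyto = prot[[pre]][i] / prot[[cyto]][i],
      fold_post_over_cyto = prot[[post]][i] / prot[[cyto]][i],
      norm_pre = prot[[paste0("norm_", pre)]][i],
      norm_cyto = prot[[paste0("norm_", cyto)]][i],
      norm_post = prot[[paste0("norm_", post)]][i],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

FEATURE_COLUMNS <- c("spec_count", "sequence_coverage", "molecular_weight",
                     "isoelectric_point", "log_density",
                     "fold_pre_over_cyto", "fold_post_over_cyto",
                     "norm_pre", "norm_cyto", "norm_post")

#' Train the random-forest postsynaptic classifier and score every protein
#'
#' Fits a random forest on the labelled rows and returns a postsynaptic
#' probability score for every row. Labelled rows are scored with their
#' out-of-bag votes, so downstream ROC evaluation on the training genes is
#' free of training-set leakage; unlabelled rows are scored by the full
#' forest. Deterministic under a fixed seed.
#'
#' @param features feature table from [extract_features()] (or
#'   [simulate_classifier_proteome()]), with a `gene` column and the ten
#'   feature columns.
#' @param labels named character/factor vector gene -> label
#'   (`"postsynaptic"` vs anything else); genes absent from `labels` are
#'   scored but not trained on.
#' @param ntree number of trees.
#' @param seed integer seed.
#' @return named numeric vector of postsynaptic scores in `[0, 1]`, one per
#'   row of `features`.
#' @export
train_and_classify <- function(features, labels, ntree = 500L, seed = 1L) {
  x <- features[, FEATURE_COLUMNS, drop = FALSE]
  genes <- features$gene
  lab <- labels[genes]
  trained <- !is.na(lab)
  y <- factor(ifelse(lab[trained] == "postsynaptic", "pos", "neg"),
              levels = c("neg", "pos"))
  if (nlevels(droplevels(y)) < 2L)
    stop("training labels must contain both classes")
  set.seed(seed)
  rf <- randomForest::randomForest(x = x[trained, , drop = FALSE], y = y,
                                   ntree = ntree)
  scores <- numeric(nrow(x))
  scores[trained] <- rf$votes[, "pos"]          # out-of-bag
  if (any(!trained))
    scores[!trained] <- stats::predict(rf, x[!trained, , drop = FALSE],
                                       type = "prob")[, "pos"]
  stats::setNames(scores, genes)
}

#' ROC curve and AUROC by threshold sweep
#'
#' Standard ROC: thresholds sweep the observed scores, the area is the
#' trapezoid rule over (FPR, TPR). Equivalent to the Wilcoxon pairwise
#' concordance probability.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical or two-level vector; `TRUE`/`"postsynaptic"`-level
#'   marks positives.
#' @param positive value of `labels` counted as positive when `labels` is
#'   not logical.
#' @return list with `fpr`, `tpr`, `thresholds`, `auc`.
#' @export
roc_curve <- function(scores, labels, positive = "postsynaptic") {
  pos <- if (is.logical(labels)) labels else labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  pos <- pos[o]
  tp <- cumsum(pos); fp <- cumsum(!pos)
  # collapse tied scores to the last index of each tie block
  s <- scores[o]
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, tp[keep] / sum(pos))
  fpr <- c(0, fp[keep] / sum(!pos))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(fpr = fpr, tpr = tpr,
       thresholds = c(Inf, s[keep]), auc = auc)
}

#' Apply the two-experiment inclusion rule
#'
#' A gene enters the library when it is classified postsynaptic (score >=
#' `threshold`) in at least two independent experiments.
#'
#' @param per_experiment_scores list (length >= 2) of named score vectors,
#'   one per experiment.
#' @param threshold classification threshold on the score.
#' @return data frame: `gene`, one `score_<i>` column per experiment,
#'   `n_experiments_positive`, `included`.
#' @export
assemble_library <- function(per_experiment_scores, threshold = 0.5) {
  if (length(per_experiment_scores) < 2L)
    stop("at least two experiments are required")
  genes <- sort(unique(unlist(lapply(per_experiment_scores, names))))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  npos <- integer(length(genes))
  for (i in seq_along(per_experiment_scores)) {
    s <- per_experiment_scores[[i]][genes]
    out[[paste0("score_", i)]] <- unname(s)
    npos <- npos + as.integer(!is.na(s) & s >= threshold)
  }
  out$n_experiments_positive <- npos
  out$included <- npos >= 2L
  out
}

#' Class-specific false discovery rates of an assembled library
#'
#' Fraction of included library genes annotated as non-synaptic membrane
#' proteins, and fraction annotated as exclusively presynaptic -- the two
#' contaminant categories a postsynaptic library is audited against.
#'
#' @param library_table output of [assemble_library()].
#' @param ann an [annotation_sets()].
#' @return list with `fdr_nonsynaptic_membrane` and `fdr_presynaptic`
#'   (fractions in `[0, 1]`).
#' @export
estimate_library_fdr <- function(library_table, ann) {
  stopifnot(inherits(ann, "annotation_sets"))
  inc <- library_table$gene[library_table$included]
  if (length(inc) == 0L)
    return(list(fdr_nonsynaptic_membrane = 0, fdr_presynaptic = 0))
  list(
    fdr_nonsynaptic_membrane = mean(inc %in% ann$nonsynaptic_membrane),
    fdr_presynaptic = mean(inc %in% exclusive_presynaptic(ann))
  )
}

#' Read a plain-text gene list (one symbol per line)
#' @param path file path.
#' @return character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  unique(x[nzchar(x)])
}
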