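#' Simulation design for a multiplexed reporter-ion experiment
#'
#' Describes the channel layout (one group label per channel, e.g. cell type
#' x genotype), the background proteome size, the multiplicative log-normal
#' noise level and the injected effects. Effects come in two kinds: per-group
#' protein fold changes (`effects`), and isoform-level silencing/fold effects
#' on a subset of a protein's peptides in one group (`isoform_effects`),
#' which is how exon-deletion genotypes manifest at the peptide level.
#'
#' @param channels character vector of channel names.
#' @param groups group label per channel (same length as `channels`).
#' @param n_proteins number of background proteins.
#' @param peptide_range length-2 integer range of peptides per protein.
#' @param noise_cv coefficient of variation of the multiplicative log-normal
#'   noise (0 for noise-free data).
#' @param effects named list: protein accession -> named numeric vector of
#'   per-group fold changes (strictly positive; groups not listed get 1).
#' @param isoform_effects list of lists with fields `protein`, `peptides`
#'   (subset of that protein's peptides; checked at simulation time), `group`
#'   and `fold` (strictly positive, or 0 meaning silenced to the floor).
#' @param phospho_frac fraction of peptides flagged as phosphopeptides.
#' @param seed integer seed.
#' @return list of class `simulation_design`.
#' @export
simulation_design <- function(channels, groups, n_proteins = 40L,
                              peptide_range = c(4L, 12L), noise_cv = 0.2,
                              effects = list(), isoform_effects = list(),
                              phospho_frac = 0.2, seed = 1L) {
  if (length(channels) != length(groups))
    stop("every channel needs exactly one group label")
  if (anyDuplicated(channels)) stop("channel names must be unique")
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  for (f in effects)
    if (any(unlist(f) <= 0)) stop("fold changes must be strictly positive")
  for (e in isoform_effects)
    if (e$fold < 0) stop("isoform fold must be non-negative")
  structure(list(channels = as.character(channels),
                 groups = stats::setNames(as.character(groups), channels),
                 n_proteins = n_proteins, peptide_range = peptide_range,
                 noise_cv = noise_cv, effects = effects,
                 isoform_effects = isoform_effects,
                 phospho_frac = phospho_frac, seed = seed),
            class = "simulation_design")
}

lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)   # unit mean
}

random_peptide <- function(len) random_segment(len, cleavage_rate = 0)

# floor applied to silenced peptides: a small positive multiple of baseline
# keeps log/ratio arithmetic defined downstream
SILENCE_FLOOR <- 1e-3

#' Simulate a multiplexed peptide quantification experiment
#'
#' Generates a peptide table with known ground truth. Background proteins get
#' random peptides; each supplied gene model contributes the retained tryptic
#' peptides of its full-length isoform. Per peptide and channel, intensity =
#' baseline x group fold x isoform-subset fold x log-normal noise. Peptides
#' that a group's genotype variant cannot produce (they are not a substring
#' of any translatable isoform of that group's model, e.g. after an exon
#' deletion) are silenced to `1e-3 x baseline` in that group's channels. A
#' fixed seed reproduces the table exactly.
#'
#' @param design a [simulation_design()].
#' @param models named list of reference [gene_model()]s (may be empty).
#' @param group_models optional nested list: group label -> (gene ->
#'   [gene_model()] variant) describing genotype-specific models (e.g. from
#'   [delete_exons()]); groups not listed use the reference model.
#' @return list with `peptides` (the quantification table) and `truth`
#'   (list: `fold` protein x group matrix of injected protein folds;
#'   `silenced` data frame of (group, protein, peptide) silencing events;
#'   `baseline` named per-peptide baselines).
#' @export
simulate_experiment <- function(design, models = list(),
                                group_models = list()) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  ch <- design$channels
  grp <- design$groups
  pep_rows <- list()

  add_protein <- function(accession, pep_seqs) {
    data.frame(peptide = pep_seqs, protein = accession,
               stringsAsFactors = FALSE)
  }

  # background proteome
  if (design$n_proteins > 0L) {
    for (i in seq_len(design$n_proteins)) {
      npep <- sample(seq.int(design$peptide_range[1],
                             design$peptide_range[2]), 1L)
      seqs <- unique(vapply(sample(8:20, npep, replace = TRUE),
                            random_peptide, character(1)))
      pep_rows[[length(pep_rows) + 1L]] <-
        add_protein(sprintf("PROT%04d", i), seqs)
    }
  }

  # gene-model proteins: tryptic peptides of the full-length isoform
  model_pep <- list()
  for (g in names(models)) {
    full <- names(models[[g]]$isoforms)[1]
    pp <- isoform_peptides(models[[g]], full)
    model_pep[[g]] <- pp
    pep_rows[[length(pep_rows) + 1L]] <-
      add_protein(paste0(g, ".full"), pp$sequence)
  }

  tbl <- do.call(rbind, pep_rows)
  if (is.null(tbl) || nrow(tbl) == 0L) stop("design produced no peptides")
  n <- nrow(tbl)
  tbl$is_phospho <- runif(n) < design$phospho_frac
  tbl$spec_count <- rpois(n, 3) + 1L
  baseline <- 10^runif(n, 4, 6)

  # per-(protein, group) fold factors
  fold_of <- function(protein, group) {
    f <- design$effects[[protein]]
    if (is.null(f) || is.na(f[group])) 1 else unname(f[group])
  }
  prot_acc <- sort(unique(tbl$protein))
  fold_mat <- matrix(1, length(prot_acc), length(unique(grp)),
                     dimnames = list(prot_acc, sort(unique(grp))))
  for (p in prot_acc)
    for (g in colnames(fold_mat)) fold_mat[p, g] <- fold_of(p, g)

  # silencing map from genotype variants
  silenced <- data.frame(group = character(0), protein = character(0),
                         peptide = character(0), stringsAsFactors = FALSE)
  silenced_idx <- function(group) {
    idx <- integer(0)
    gm <- group_models[[group]]
    if (is.null(gm)) return(idx)
    for (g in names(gm)) {
      variant <- gm[[g]]
      nms <- names(variant$isoforms)
      nms <- nms[vapply(nms, function(nm)
        isTRUE(variant$isoforms[[nm]]$translatable), logical(1))]
      seqs <- vapply(nms, function(nm)
        translate_isoform(variant, nm)$sequence, character(1))
      acc <- paste0(g, ".full")
      rows <- which(tbl$protein == acc)
      ok <- vapply(tbl$peptide[rows], function(p)
        any(vapply(seqs, function(s) grepl(p, s, fixed = TRUE),
                   logical(1))), logical(1))
      idx <- c(idx, rows[!ok])
    }
    idx
  }

  # isoform_effects: explicit peptide-subset folds
  iso_factor <- matrix(1, n, length(ch), dimnames = list(NULL, ch))
  for (e in design$isoform_effects) {
    rows <- which(tbl$protein == e$protein & tbl$peptide %in% e$peptides)
    if (length(rows) < length(unique(e$peptides)))
      stop("isoform effect peptides must be a subset of '", e$protein,
           "' peptides")
    cols <- ch[grp[ch] == e$group]
    iso_factor[rows, cols] <- max(e$fold, SILENCE_FLOOR)
  }
  for (gl in unique(grp)) {
    rows <- silenced_idx(gl)
    if (length(rows)) {
      cols <- ch[grp[ch] == gl]
      iso_factor[rows, cols] <- SILENCE_FLOOR
      silenced <- rbind(silenced, data.frame(
        group = gl, protein = tbl$protein[rows],
        peptide = tbl$peptide[rows], stringsAsFactors = FALSE))
    }
  }

  for (cn in ch) {
    g <- grp[[cn]]
    f <- fold_mat[tbl$protein, g]
    tbl[[cn]] <- baseline * f * iso_factor[, cn] *
      lognormal_noise(n, design$noise_cv)
  }
  rownames(tbl) <- NULL
  list(peptides = tbl,
       truth = list(fold = fold_mat, silenced = silenced,
                    baseline = stats::setNames(baseline, tbl$peptide)))
}

#' Simulate a ten-feature proteome for classifier evaluation
#'
#' Draws the ten classifier features from class-conditional distributions for
#' four protein classes (postsynaptic, presynaptic, cytosolic/ER,
#' non-synaptic membrane). Postsynaptic proteins are enriched in the
#' post-probe channel (elevated post/cyto fold and normalized post-channel
#' value) and presynaptic proteins in the pre-probe channel; `separation`
#' scales the class mean shifts on the log scale, with 0 making all classes
#' indistinguishable.
#'
#' @param n_per_class proteins per class (>= 10).
#' @param separation non-negative effect size (log2-scale mean shift).
#' @param seed integer seed.
#' @return list with `features` (data frame: `gene`, `class`, then the ten
#'   features) and `truth` (named class per gene).
#' @export
simulate_classifier_proteome <- function(n_per_class = 200L, separation = 1,
                                         seed = 1L) {
  if (n_per_class < 10L) stop("n_per_class must be >= 10")
  if (separation < 0) stop("separation must be non-negative")
  set.seed(seed)
  classes <- c("postsynaptic", "presynaptic", "cytosolic_er",
               "nonsynaptic_membrane")
  n <- n_per_class * length(classes)
  cls <- rep(classes, each = n_per_class)
  is_post <- cls == "postsynaptic"
  is_pre <- cls == "presynaptic"
  lf_post <- rnorm(n, mean = separation * is_post, sd = 1)
  lf_pre <- rnorm(n, mean = separation * is_pre, sd = 1)
  feats <- data.frame(
    gene = sprintf("G%04d", seq_len(n)),
    class = cls,
    spec_count = rpois(n, 20) + 1L,
    sequence_coverage = rbeta(n, 2, 4),
    molecular_weight = rlnorm(n, log(60), 0.5),
    isoelectric_point = rnorm(n, 7, 1.5),
    log_density = rnorm(n, 2, 0.6),
    fold_pre_over_cyto = 2^lf_pre,
    fold_post_over_cyto = 2^lf_post,
    norm_pre = rlnorm(n, 11 + 0.3 * separation * is_pre, 0.7),
    norm_cyto = rlnorm(n, 11, 0.7),
    norm_post = rlnorm(n, 11 + 0.3 * separation * is_post, 0.7),
    stringsAsFactors = FALSE
  )
  list(features = feats,
       truth = stats::setNames(cls, feats$gene))
}
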