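#' Read / write peptide quantification tables (TSV)
#'
#' Tab-separated, header `peptide  protein  is_phospho  spec_count` followed
#' by one column per channel. Reading validates the schema and invariants and
#' reports offending file line numbers; writing is deterministic, so a
#' written table re-read and re-written is byte-identical.
#'
#' @param path file path.
#' @return `read_peptide_table` returns the validated data frame.
#' @export
read_peptide_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tbl <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("peptide", "protein", "is_phospho", "spec_count")
  missing <- setdiff(required, names(tbl))
  if (length(missing))
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  tbl$is_phospho <- as.logical(tbl$is_phospho)
  for (cn in channel_names(tbl)) {
    bad <- which(!is.finite(tbl[[cn]]) | tbl[[cn]] < 0)
    if (length(bad))
      stop("invalid intensity in '", cn, "' at file line(s) ",
           paste(bad + 1L, collapse = ", "), " of ", path)
  }
  validate_peptide_table(tbl)
  tbl
}

#' @rdname read_peptide_table
#' @param tbl a peptide quantification table.
#' @export
write_peptide_table <- function(tbl, path) {
  write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' The accession is the header token before the first whitespace; sequences
#' are upper-cased.
#'
#' @param path FASTA file path.
#' @return named character vector accession -> sequence.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  if (any(Biostrings::width(ss) == 0L)) stop("empty FASTA record in ", path)
  acc <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  stats::setNames(toupper(as.character(ss)), acc)
}

#' Write sequences as FASTA
#' @param sequences named character vector accession -> sequence.
#' @param path output path.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

write_tsv_with_schema <- function(df, path, schema) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Validate a pipeline run configuration
#'
#' A run configuration is a list (typically read from YAML) with fields:
#' `peptides` (TSV path), `reference` (gene-list path of cytosolic/ER
#' accessions), `groups` (named map channel -> group), `alpha`, `seed`,
#' `outdir`, and optionally `gene_models` (paths to gene-model JSON files for
#' proteoform profiling) and `min_detect` (intensity floor below which a
#' peptide does not count as detected in a group).
#'
#' @param config list or path to a YAML file.
#' @return the validated config list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (fld in c("peptides", "reference", "groups", "outdir"))
    if (is.null(config[[fld]])) stop("config is missing field '", fld, "'")
  for (fld in c("peptides", "reference"))
    if (!file.exists(config[[fld]]))
      stop("config path does not exist: ", config[[fld]])
  for (p in config$gene_models)
    if (!file.exists(p)) stop("config path does not exist: ", p)
  if (is.null(config$alpha)) config$alpha <- 0.05
  if (is.null(config$seed)) config$seed <- 1L
  config$seed <- as.integer(config$seed)
  if (is.null(config$min_detect)) config$min_detect <- 0
  config$groups <- unlist(config$groups)
  config
}

#' Observed proteoform fingerprint of a gene in one sample group
#'
#' Matches detected peptide sequences onto the model's translatable isoforms
#' (longest first), labels each with its exon/junction, and builds the
#' observed exon detection-frequency table.
#'
#' @param model a [gene_model()].
#' @param peptide_seqs character vector of detected peptide sequences (one
#'   entry per detection event).
#' @return an [exon_frequency_table()], or `NULL` if nothing maps.
#' @export
profile_detections <- function(model, peptide_seqs) {
  nms <- names(model$isoforms)
  nms <- nms[vapply(nms, function(nm)
    isTRUE(model$isoforms[[nm]]$translatable), logical(1))]
  trs <- lapply(nms, function(nm) translate_isoform(model, nm))
  names(trs) <- nms
  ord <- order(-vapply(trs, function(t) nchar(t$sequence), numeric(1)))
  trs <- trs[ord]
  labels <- character(0)
  for (p in peptide_seqs) {
    for (tr in trs) {
      at <- regexpr(p, tr$sequence, fixed = TRUE)
      if (at > 0) {
        labels <- c(labels,
                    map_peptide_to_exons(as.integer(at),
                                         as.integer(at) + nchar(p) - 1L,
                                         tr$residue_labels))
        break
      }
    }
  }
  if (length(labels) == 0L) return(NULL)
  exon_frequency_table(labels)
}

#' Run the full analysis pipeline on a quantified experiment
#'
#' Orchestrates quantification, normalization, protein- and isoform-level
#' differential analysis, phosphopeptide renormalization and (when gene
#' models are configured) proteoform fingerprinting per group, writing TSV
#' results with sidecar schema files, a machine-readable run log and summary
#' plots into `config$outdir`. Identical config and inputs give identical
#' numeric outputs.
#'
#' @param config run configuration (list or YAML path); see
#'   [read_run_config()].
#' @return invisibly, a list with the main result tables.
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)

  peptides <- tryCatch(read_peptide_table(config$peptides),
                       error = function(e)
                         stop("stage 'read': ", conditionMessage(e)))
  reference <- read_gene_list(config$reference)

  prot <- tryCatch({
    p <- sum_protein_intensities(peptides)
    normalize_channels(p, reference)
  }, error = function(e) stop("stage 'quantify': ", conditionMessage(e)))
  prot <- select_primary_accession(prot)
  write_tsv_with_schema(prot, out("protein_quant.tsv"), list(
    protein = "protein accession",
    gene = "gene symbol",
    n_peptides = "number of distinct quantified peptides",
    channels = "summed reporter-ion intensity per channel",
    norm_channels = "reference-normalized intensity per channel"))

  diff <- tryCatch(
    differential_analysis(peptides, prot, config$groups,
                          alpha = config$alpha),
    error = function(e) stop("stage 'differential': ", conditionMessage(e)))
  write_tsv_with_schema(diff, out("differential.tsv"), list(
    protein = "protein accession", gene = "gene symbol",
    mean_fold = "ratio of group means (group1/group2)",
    p_protein = "one-tailed Welch t-test p-value",
    p_genotype = "two-way ANOVA group main-effect p-value",
    p_peptide = "two-way ANOVA peptide main-effect p-value",
    p_interaction = "two-way ANOVA group-by-peptide interaction p-value",
    is_protein_divergent = "p_protein < alpha",
    is_isoform_divergent = "p_interaction < alpha",
    padj_protein = "Benjamini-Hochberg adjusted p_protein",
    padj_interaction = "Benjamini-Hochberg adjusted p_interaction"))

  # phosphopeptide compositional renormalization, per phospho-protein
  phos_acc <- unique(peptides$protein[peptides$is_phospho])
  phos_rows <- lapply(sort(phos_acc), function(acc) {
    renormalize_phospho(peptides[peptides$protein == acc, , drop = FALSE])
  })
  phospho <- if (length(phos_rows)) do.call(rbind, phos_rows) else
    peptides[0, , drop = FALSE]
  write_tsv_with_schema(phospho, out("phospho_renormalized.tsv"), list(
    peptide = "peptide sequence", protein = "protein accession",
    is_phospho = "phosphopeptide flag",
    spec_count = "spectral count",
    channels = "per-channel intensities renormalized to a 2,000,000 total"))

  # proteoform fingerprinting per configured gene model and group
  profiles <- list()
  for (path in config$gene_models) {
    model <- read_gene_model(path)
    stds <- standard_tables(model)
    for (grp in sort(unique(config$groups))) {
      chs <- names(config$groups)[config$groups == grp]
      acc_rows <- grepl(paste0("^", model$gene, "\\."), peptides$protein)
      m <- as.matrix(peptides[acc_rows, chs, drop = FALSE])
      detected <- rowMeans(m) > config$min_detect
      obs <- profile_detections(model, peptides$peptide[acc_rows][detected])
      if (is.null(obs)) next
      rank <- assign_isoform(obs, stds)
      rank$gene <- model$gene
      rank$group <- grp
      profiles[[paste(model$gene, grp)]] <- rank
      write_tsv_with_schema(obs,
        out(sprintf("fingerprint_%s_%s.tsv", model$gene, grp)), list(
          label = "exon, AST or junction label",
          type = "exon or junction",
          count = "detection events",
          frequency = "detection frequency (sums to 1)"))
    }
  }
  if (length(profiles)) {
    assign_tbl <- do.call(rbind, profiles)
    rownames(assign_tbl) <- NULL
    write_tsv_with_schema(assign_tbl, out("isoform_assignment.tsv"), list(
      isoform = "candidate isoform",
      distance = "Euclidean distance to observed fingerprint",
      rank = "1 = nearest standard", gene = "gene", group = "sample group"))
  }

  # plots: volcano and a Q-Q panel for the most isoform-divergent protein
  grDevices::pdf(out("plots.pdf"), width = 9, height = 4.5)
  graphics::par(mfrow = c(1, 2))
  graphics::plot(log2(diff$mean_fold), -log10(diff$p_protein),
                 xlab = "log2 fold (group1/group2)",
                 ylab = "-log10 p (protein)", pch = 20,
                 col = ifelse(diff$is_protein_divergent, "red", "grey40"),
                 main = "Protein-level volcano")
  top <- diff$protein[order(diff$p_interaction)][1]
  hit <- vapply(strsplit(peptides$protein, ";", fixed = TRUE),
                function(a) top %in% a, logical(1))
  m <- as.matrix(peptides[hit, names(config$groups), drop = FALSE])
  if (nrow(m) >= 2L) {
    prof <- peptide_fold_profile(m, config$groups[colnames(m)])
    graphics::plot(prof$qq$theoretical, prof$qq$empirical,
                   xlab = "theoretical quantiles",
                   ylab = "standardized log2 peptide fold",
                   main = paste("Q-Q:", top), pch = 20)
    graphics::abline(0, 1, lty = 2)
  }
  grDevices::dev.off()

  log <- list(config = config[setdiff(names(config), "outdir")],
              package_version = as.character(utils::packageVersion("synaptoform")),
              n_peptides = nrow(peptides), n_proteins = nrow(prot))
  yaml::write_yaml(log, out("run_log.yaml"))

  invisible(list(proteins = prot, differential = diff, phospho = phospho,
                 profiles = profiles))
}
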