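#' Peptide-level quantification tables
#'
#' The universal quantitative substrate is a data frame with one row per
#' peptide and the columns `peptide` (sequence), `protein` (accession, or
#' several accessions separated by `";"`), `is_phospho` (logical),
#' `spec_count` (non-negative integer), followed by one non-negative
#' intensity column per reporter channel.
#'
#' @param tbl a data frame.
#' @return `tbl`, invisibly, after validation.
#' @export
validate_peptide_table <- function(tbl) {
  required <- c("peptide", "protein", "is_phospho", "spec_count")
  missing <- setdiff(required, names(tbl))
  if (length(missing))
    stop("peptide table is missing column(s): ",
         paste(missing, collapse = ", "))
  ch <- channel_names(tbl)
  if (length(ch) == 0L) stop("peptide table has no intensity channels")
  for (cn in ch) {
    bad <- which(!is.finite(tbl[[cn]]) | tbl[[cn]] < 0)
    if (length(bad))
      stop("negative or non-finite intensity in channel '", cn,
           "' at row(s): ", paste(head(bad, 5L), collapse = ", "))
  }
  if (any(tbl$spec_count < 0)) stop("spec_count must be non-negative")
  invisible(tbl)
}

#' Channel (intensity) column names of a peptide or protein table
#' @param tbl a peptide- or protein-level table.
#' @export
channel_names <- function(tbl) {
  reserved <- c("peptide", "protein", "gene", "is_phospho", "spec_count",
                "n_peptides")
  setdiff(names(tbl), c(reserved, grep("^norm_", names(tbl), value = TRUE)))
}

default_gene_map <- function(accessions) {
  # synthetic accessions are "<gene>.<isoform tag>"; anything without a dot
  # maps to itself
  stats::setNames(sub("\\..*$", "", accessions), accessions)
}

#' Sum peptide reporter-ion intensities to protein level
#'
#' Protein quantification by summing all reporter-ion intensities of a
#' protein's peptides, per channel. Peptides assigned to multiple accessions
#' (`";"`-separated) contribute to every listed accession: no razor-peptide
#' assignment is applied, so subset proteins remain represented.
#'
#' @param peptides a peptide quantification table
#'   (see [validate_peptide_table()]).
#' @param gene_map optional named character vector accession -> gene symbol;
#'   by default the accession's prefix before the first `"."`.
#' @return protein-level data frame with columns `protein`, `gene`,
#'   `n_peptides` (distinct quantified peptide sequences) and one summed
#'   intensity column per channel.
#' @export
sum_protein_intensities <- function(peptides, gene_map = NULL) {
  ch <- channel_names(peptides)
  if (nrow(peptides) == 0L) {
    out <- data.frame(protein = character(0), gene = character(0),
                      n_peptides = integer(0))
    for (cn in ch) out[[cn]] <- numeric(0)
    return(out)
  }
  validate_peptide_table(peptides)
  acc_list <- strsplit(peptides$protein, ";", fixed = TRUE)
  idx <- rep(seq_len(nrow(peptides)), lengths(acc_list))
  acc <- unlist(acc_list)
  prot <- sort(unique(acc))
  out <- data.frame(protein = prot, stringsAsFactors = FALSE)
  if (is.null(gene_map)) gene_map <- default_gene_map(prot)
  out$gene <- unname(gene_map[out$protein])
  out$n_peptides <- as.integer(tapply(peptides$peptide[idx], acc,
                                      function(p) length(unique(p)))[prot])
  for (cn in ch)
    out[[cn]] <- as.numeric(tapply(peptides[[cn]][idx], acc, sum)[prot])
  rownames(out) <- NULL
  out
}

#' Normalize protein intensities across channels by a reference protein set
#'
#' For each channel, the normalization factor is the median summed intensity
#' of the reference proteins (annotated cytosolic or endoplasmic-reticulum)
#' in that channel. Intensities are divided by the factor and rescaled by the
#' grand mean of the factors, so cross-channel comparability is achieved
#' while magnitudes stay on the input scale; after normalization the median
#' normalized intensity of reference proteins is identical in every channel.
#'
#' @param proteins protein-level table from [sum_protein_intensities()].
#' @param reference character vector of reference protein accessions.
#' @return `proteins` with one additional `norm_<channel>` column per channel.
#' @export
normalize_channels <- function(proteins, reference) {
  if (length(reference) == 0L) stop("reference protein set is empty")
  ch <- channel_names(proteins)
  in_ref <- proteins$protein %in% reference
  if (!any(in_ref))
    stop("no reference protein quantified; missing set: ",
         paste(head(sort(reference), 10L), collapse = ", "))
  factors <- vapply(ch, function(cn) median(proteins[[cn]][in_ref]),
                    numeric(1))
  if (any(factors <= 0)) stop("non-positive normalization factor")
  scale <- mean(factors)
  for (cn in ch)
    proteins[[paste0("norm_", cn)]] <- proteins[[cn]] / factors[[cn]] * scale
  proteins
}

#' Compositional renormalization of a protein's peptide intensities
#'
#' Within each channel, every peptide intensity of a single protein
#' (phosphorylated and unmodified peptides together) is rescaled to the fixed
#' total 2,000,000: renormalized value = intensity / (channel sum) * 2e6.
#' Missing values are treated as 0; a channel whose intensities are all zero
#' yields zeros (not an error), since zero-total channels are legal under the
#' zero-fill convention.
#'
#' @param peptides_of_protein peptide table subset in which all rows share
#'   one protein accession.
#' @return the subset with every channel column renormalized.
#' @export
renormalize_phospho <- function(peptides_of_protein) {
  tbl <- peptides_of_protein
  if (nrow(tbl) == 0L) stop("empty peptide subset")
  if (length(unique(tbl$protein)) != 1L)
    stop("renormalize_phospho expects peptides of a single protein; got: ",
         paste(unique(tbl$protein), collapse = ", "))
  total <- 2e6
  for (cn in channel_names(tbl)) {
    v <- tbl[[cn]]
    v[is.na(v)] <- 0
    s <- sum(v)
    tbl[[cn]] <- if (s > 0) v / s * total else rep(0, length(v))
  }
  tbl
}
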