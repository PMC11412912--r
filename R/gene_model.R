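#' Exon-structured gene models
#'
#' A gene model is an ordered chain of exons, each carrying an in-frame
#' amino-acid segment, plus a set of isoform definitions. Isoforms are either
#' the full exon chain or truncations starting at an internal exon (modelling
#' alternatively spliced transcripts); a truncated isoform may additionally
#' carry a short alternative N-terminal segment (AST) of its own.
#'
#' @param gene gene identifier.
#' @param exons data frame with columns `exon` (character id) and `segment`
#'   (amino-acid string).
#' @param isoforms named list; each element is a list with `exons` (ordered
#'   character vector of exon ids), optional `ast` (amino-acid string placed
#'   before the first exon) and `translatable` (logical).
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene, exons, isoforms) {
  stopifnot(is.character(gene), length(gene) == 1L)
  exons$exon <- as.character(exons$exon)
  if (anyDuplicated(exons$exon)) stop("exon ids must be unique")
  for (nm in names(isoforms)) {
    iso <- isoforms[[nm]]
    if (!all(iso$exons %in% exons$exon))
      stop("isoform '", nm, "' references unknown exons")
    idx <- match(iso$exons, exons$exon)
    if (is.unsorted(idx, strictly = TRUE))
      stop("isoform '", nm, "' exon list is not an ordered sublist")
    if (is.null(iso$translatable)) isoforms[[nm]]$translatable <- TRUE
  }
  structure(list(gene = gene, exons = exons, isoforms = isoforms),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene, ": ", nrow(x$exons), " exons, ",
      length(x$isoforms), " isoform(s)\n", sep = "")
  invisible(x)
}

# amino-acid alphabet used for generated sequences; no ambiguous codes so
# molecular weight and digestion stay exact
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M",
    "N", "P", "Q", "S", "T", "V", "W", "Y", "K", "R")
}

random_segment <- function(len, cleavage_rate = 1 / 15) {
  aa <- aa_alphabet()
  noncleave <- setdiff(aa, c("K", "R"))
  p <- c(rep((1 - cleavage_rate) / length(noncleave), length(noncleave)),
         rep(cleavage_rate / 2, 2))
  paste(sample(c(noncleave, "K", "R"), len, replace = TRUE, prob = p),
        collapse = "")
}

#' Generate a synthetic exon-structured gene model
#'
#' Creates a gene whose exons carry random in-frame amino-acid segments, with
#' lysine/arginine placed at about one per 15 residues so that tryptic
#' peptides mostly fall inside the 8-35 aa retained window. Isoform 1 is the
#' full exon chain; further isoforms are truncations starting at internal
#' exons, mimicking alternative transcription starts.
#'
#' @param n_exons number of exons (>= 2).
#' @param exon_len_range length-2 integer range of exon segment lengths (aa).
#' @param n_isoforms number of isoforms (>= 1); the first is always full-length.
#' @param seed integer seed; fixed seed gives a byte-identical model.
#' @param isoform_starts optional integer vector of start exons for the
#'   truncated isoforms (length `n_isoforms - 1`); sampled when `NULL`.
#' @param ast_len length of the alternative N-terminal segment given to each
#'   truncated isoform (0 for none).
#' @param gene gene identifier.
#' @return a [gene_model()].
#' @export
make_gene_model <- function(n_exons, exon_len_range = c(20L, 60L),
                            n_isoforms = 1L, seed = 1L,
                            isoform_starts = NULL, ast_len = 0L,
                            gene = "GENE1") {
  if (n_exons < 2L) stop("n_exons must be >= 2")
  if (n_isoforms < 1L) stop("n_isoforms must be >= 1")
  if (any(exon_len_range <= 0)) stop("exon lengths must be positive")
  if (ast_len < 0L) stop("ast_len must be non-negative")
  set.seed(seed)
  lens <- sample(seq.int(exon_len_range[1], exon_len_range[2]), n_exons,
                 replace = TRUE)
  exons <- data.frame(exon = as.character(seq_len(n_exons)),
                      segment = vapply(lens, random_segment, character(1)),
                      stringsAsFactors = FALSE)
  isoforms <- list()
  isoforms[[paste0(gene, ".full")]] <-
    list(exons = exons$exon, ast = NULL, translatable = TRUE)
  if (n_isoforms > 1L) {
    if (is.null(isoform_starts)) {
      pool <- seq.int(2L, n_exons)
      isoform_starts <- sort(sample(pool, n_isoforms - 1L))
    }
    if (length(isoform_starts) != n_isoforms - 1L)
      stop("isoform_starts must have length n_isoforms - 1")
    if (any(isoform_starts < 2L | isoform_starts > n_exons))
      stop("isoform starts must be internal exons")
    for (s in isoform_starts) {
      ast <- if (ast_len > 0L) random_segment(ast_len) else NULL
      isoforms[[paste0(gene, ".e", s)]] <-
        list(exons = exons$exon[s:n_exons], ast = ast, translatable = TRUE)
    }
  }
  gene_model(gene, exons, isoforms)
}

#' Delete exons from a gene model (genotype variant)
#'
#' Returns a variant of the model in which the listed exons are removed, as in
#' knockout lines generated by replacing a block of exons. Isoforms requiring
#' any deleted exon are marked untranslatable; isoforms that do not overlap the
#' deletion are unchanged.
#'
#' @param model a [gene_model()].
#' @param exon_ids character (or coercible) ids of exons to delete; may be
#'   empty, in which case the model is returned unchanged.
#' @return a [gene_model()].
#' @export
delete_exons <- function(model, exon_ids) {
  stopifnot(inherits(model, "gene_model"))
  exon_ids <- as.character(exon_ids)
  if (length(exon_ids) == 0L) return(model)
  unknown <- setdiff(exon_ids, model$exons$exon)
  if (length(unknown))
    stop("unknown exon id(s): ", paste(unknown, collapse = ", "))
  model$exons <- model$exons[!model$exons$exon %in% exon_ids, , drop = FALSE]
  for (nm in names(model$isoforms)) {
    iso <- model$isoforms[[nm]]
    if (any(iso$exons %in% exon_ids)) {
      model$isoforms[[nm]]$translatable <- FALSE
    }
  }
  model
}

#' Translate an isoform and label every residue with its exon of origin
#'
#' Concatenates the isoform's exon segments (alternative N-terminal segment
#' first, when present) into a protein sequence, and returns the per-residue
#' exon label map used for peptide-to-exon assignment. AST residues are
#' labelled `"AST:<isoform>"`.
#'
#' @param model a [gene_model()].
#' @param isoform isoform name.
#' @return list with `sequence` (string) and `residue_labels` (character
#'   vector, one label per residue).
#' @export
translate_isoform <- function(model, isoform) {
  stopifnot(inherits(model, "gene_model"))
  if (!isoform %in% names(model$isoforms))
    stop("isoform '", isoform, "' not defined in model")
  iso <- model$isoforms[[isoform]]
  if (!isTRUE(iso$translatable))
    stop("isoform '", isoform, "' is untranslatable (required exon deleted)")
  segs <- model$exons$segment[match(iso$exons, model$exons$exon)]
  labels <- rep(iso$exons, nchar(segs))
  seq <- paste(segs, collapse = "")
  if (!is.null(iso$ast) && nzchar(iso$ast)) {
    labels <- c(rep(paste0("AST:", isoform), nchar(iso$ast)), labels)
    seq <- paste0(iso$ast, seq)
  }
  list(sequence = seq, residue_labels = labels)
}

#' Write / read gene models as structured JSON text
#'
#' @param model a [gene_model()].
#' @param path file path.
#' @return `write_gene_model` returns `path` invisibly; `read_gene_model`
#'   returns a [gene_model()].
#' @export
write_gene_model <- function(model, path) {
  stopifnot(inherits(model, "gene_model"))
  obj <- list(
    gene = model$gene,
    exons = model$exons,
    isoforms = lapply(model$isoforms, function(iso) {
      list(exons = iso$exons,
           ast = if (is.null(iso$ast)) "" else iso$ast,
           translatable = isTRUE(iso$translatable))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_gene_model
#' @export
read_gene_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  isoforms <- lapply(obj$isoforms, function(iso) {
    list(exons = as.character(unlist(iso$exons)),
         ast = if (!nzchar(iso$ast)) NULL else iso$ast,
         translatable = isTRUE(iso$translatable))
  })
  gene_model(obj$gene, as.data.frame(obj$exons), isoforms)
}
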