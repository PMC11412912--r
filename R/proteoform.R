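# average residue masses (Da); monoisotopic masses are not used because gel
# slice windows and the reference isoform MW are quoted on the average scale
AA_AVG_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_AVG_MASS <- 18.01528

check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("sequence must be a single string")
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% names(AA_AVG_MASS))
  if (length(bad))
    stop("illegal amino-acid character '", chars[bad[1]], "' at position ",
         bad[1])
  chars
}

#' Theoretical average molecular weight of a protein sequence
#'
#' Sum of average residue masses plus one water, reported in kDa.
#'
#' @param sequence amino-acid string over the standard 20-letter alphabet.
#' @return molecular weight in kDa.
#' @export
theoretical_mw <- function(sequence) {
  chars <- check_sequence(sequence)
  (sum(AA_AVG_MASS[chars]) + WATER_AVG_MASS) / 1000
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to lysine and arginine with zero missed cleavages and
#' retains peptides within a length window (default 8-35 aa, the window in
#' which reporter-ion experiments typically identify fully tryptic peptides).
#' Coordinates are 1-based inclusive on the input sequence.
#'
#' @param sequence amino-acid string.
#' @param min_len,max_len retained-length window (inclusive). Set
#'   `min_len = 1, max_len = Inf` to obtain every fragment.
#' @param proline_rule if `TRUE`, do not cleave K/R-P bonds (some search
#'   engines apply this exception; off by default).
#' @return data frame with columns `sequence`, `start`, `end`.
#' @export
digest_trypsin <- function(sequence, min_len = 8L, max_len = 35L,
                           proline_rule = FALSE) {
  chars <- check_sequence(sequence)
  n <- length(chars)
  cut_after <- chars %in% c("K", "R")
  if (proline_rule && n > 1L) {
    next_is_p <- c(chars[-1] == "P", FALSE)
    cut_after <- cut_after & !next_is_p
  }
  cut_after[n] <- TRUE            # C-terminal fragment always ends here
  ends <- which(cut_after)
  starts <- c(1L, head(ends, -1L) + 1L)
  pep <- data.frame(
    sequence = vapply(seq_along(ends), function(i)
      substr(sequence, starts[i], ends[i]), character(1)),
    start = starts, end = ends, stringsAsFactors = FALSE
  )
  len <- pep$end - pep$start + 1L
  pep[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Map a peptide to its exon (or exon-junction) label
#'
#' A peptide lying entirely within one exon gets that exon's id; a peptide
#' spanning two adjacent exons gets the junction label `"A & B"`; peptides
#' spanning three or more exons get the chained label `"A & B & C"` so the
#' frequency denominator stays well defined.
#'
#' @param start,end 1-based inclusive residue coordinates on the isoform.
#' @param residue_labels per-residue exon labels from [translate_isoform()].
#' @return a single label string.
#' @export
map_peptide_to_exons <- function(start, end, residue_labels) {
  n <- length(residue_labels)
  if (start < 1L || end > n || start > end)
    stop("peptide coordinates [", start, ", ", end,
         "] out of range for isoform of length ", n)
  paste(rle(residue_labels[start:end])$values, collapse = " & ")
}

#' Gel-slice definition
#'
#' @param label slice label (e.g. `"I"`, `"II"`).
#' @param mw_range length-2 numeric, lower < upper, in kDa.
#' @return list of class `gel_slice`.
#' @export
gel_slice <- function(label, mw_range) {
  if (length(mw_range) != 2L || mw_range[1] >= mw_range[2])
    stop("mw_range must be an increasing kDa interval")
  structure(list(label = label, mw_range = as.numeric(mw_range)),
            class = "gel_slice")
}

#' Candidate isoforms for a gel slice
#'
#' Keeps translatable isoforms whose theoretical MW lies inside the slice's
#' molecular-weight window (inclusive bounds).
#'
#' @param model a [gene_model()].
#' @param slice a [gel_slice()].
#' @return character vector of isoform names (possibly empty).
#' @export
filter_isoforms_by_slice <- function(model, slice) {
  stopifnot(inherits(model, "gene_model"), inherits(slice, "gel_slice"))
  nms <- names(model$isoforms)
  nms <- nms[vapply(nms, function(nm)
    isTRUE(model$isoforms[[nm]]$translatable), logical(1))]
  keep <- vapply(nms, function(nm) {
    mw <- theoretical_mw(translate_isoform(model, nm)$sequence)
    mw >= slice$mw_range[1] && mw <= slice$mw_range[2]
  }, logical(1))
  nms[keep]
}

#' Exon detection-frequency table
#'
#' Given one detection event per identified peptide occurrence (each carrying
#' the peptide's exon or junction label), computes the detection frequency of
#' each exon/AST and each junction: the event count divided by the total
#' number of events (exon/AST events plus junction events), so all
#' frequencies sum to 1.
#'
#' @param labels character vector of exon/junction labels, one per detection
#'   event.
#' @return data frame of class `exon_frequency_table` with columns `label`,
#'   `type` (`"exon"` or `"junction"`), `count`, `frequency`; attributes `m`
#'   (number of distinct exons/ASTs detected) and `n` (distinct junctions).
#' @export
exon_frequency_table <- function(labels) {
  if (length(labels) == 0L) stop("no detection events supplied")
  tab <- table(labels)
  out <- data.frame(label = names(tab),
                    count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$type <- ifelse(grepl(" & ", out$label, fixed = TRUE),
                     "junction", "exon")
  out$frequency <- out$count / sum(out$count)
  out <- out[order(out$label), c("label", "type", "count", "frequency")]
  rownames(out) <- NULL
  attr(out, "m") <- sum(out$type == "exon")
  attr(out, "n") <- sum(out$type == "junction")
  class(out) <- c("exon_frequency_table", "data.frame")
  out
}

#' Theoretical peptides of an isoform, with exon labels
#'
#' Digests the isoform's translation and maps each retained peptide to its
#' exon or junction label.
#'
#' @param model a [gene_model()].
#' @param isoform isoform name.
#' @inheritParams digest_trypsin
#' @return data frame with `sequence`, `start`, `end`, `exon_label`.
#' @export
isoform_peptides <- function(model, isoform, min_len = 8L, max_len = 35L,
                             proline_rule = FALSE) {
  tr <- translate_isoform(model, isoform)
  pep <- digest_trypsin(tr$sequence, min_len = min_len, max_len = max_len,
                        proline_rule = proline_rule)
  pep$exon_label <- vapply(seq_len(nrow(pep)), function(i)
    map_peptide_to_exons(pep$start[i], pep$end[i], tr$residue_labels),
    character(1))
  pep
}

#' Standard per-isoform exon detection-frequency tables
#'
#' For each translatable isoform, the frequency table of its complete
#' theoretical retained tryptic peptide set, each theoretical peptide counted
#' as one detection event. These are the reference fingerprints observed
#' samples are matched against.
#'
#' @param model a [gene_model()].
#' @inheritParams digest_trypsin
#' @return named list of [exon_frequency_table()]s.
#' @export
standard_tables <- function(model, min_len = 8L, max_len = 35L,
                            proline_rule = FALSE) {
  nms <- names(model$isoforms)
  nms <- nms[vapply(nms, function(nm)
    isTRUE(model$isoforms[[nm]]$translatable), logical(1))]
  if (length(nms) == 0L) stop("model has no translatable isoform")
  out <- lapply(nms, function(nm) {
    pep <- isoform_peptides(model, nm, min_len, max_len, proline_rule)
    exon_frequency_table(pep$exon_label)
  })
  names(out) <- nms
  out
}

freq_vector <- function(tbl, universe) {
  v <- stats::setNames(rep(0, length(universe)), universe)
  v[tbl$label] <- tbl$frequency
  v
}

#' Assign an observed fingerprint to candidate isoforms
#'
#' Ranks the per-isoform standard tables by Euclidean distance to the observed
#' exon detection-frequency table on union-aligned frequency vectors (labels
#' missing from a table contribute 0). The distance ranking is the decision
#' rule; `method = "embedding"` additionally computes a t-SNE 2-D layout of
#' the observed table together with the standards for visual inspection, but
#' the reported assignment is always the distance ranking.
#'
#' @param observed an [exon_frequency_table()].
#' @param standards named list of standard tables, e.g. from
#'   [standard_tables()].
#' @param method `"distance"` (default) or `"embedding"`.
#' @param seed seed for the embedding layout.
#' @param perplexity t-SNE perplexity; defaults to `min(5, n - 1)` where `n`
#'   is the number of tables embedded.
#' @return data frame with `isoform`, `distance`, `rank` (rank 1 = best
#'   match); when `method = "embedding"` the coordinates are attached as the
#'   `embedding` attribute (rows: `"observed"` then the standards).
#' @export
assign_isoform <- function(observed, standards,
                           method = c("distance", "embedding"),
                           seed = 1L, perplexity = NULL) {
  method <- match.arg(method)
  if (length(standards) == 0L) stop("no standard tables supplied")
  universe <- sort(unique(c(observed$label,
                            unlist(lapply(standards, `[[`, "label")))))
  obs <- freq_vector(observed, universe)
  std <- t(vapply(standards, freq_vector, numeric(length(universe)),
                  universe = universe))
  d <- sqrt(rowSums((std - matrix(obs, nrow(std), length(obs),
                                  byrow = TRUE))^2))
  out <- data.frame(isoform = names(standards), distance = unname(d),
                    stringsAsFactors = FALSE)
  out <- out[order(out$distance, out$isoform), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (method == "embedding") {
    X <- rbind(observed = obs, std)
    if (is.null(perplexity)) perplexity <- min(5, nrow(X) - 1)
    emb <- tsne_layout(X, perplexity = perplexity, seed = seed)
    rownames(emb) <- c("observed", names(standards))
    attr(out, "embedding") <- emb
  }
  out
}
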