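#' Classify a dendritic spine from its measured geometry
#'
#' Rule-based classification of dendritic protrusions:
#' mushroom -- a distinct head wider than 0.5 um or more than twice the neck
#' width; stubby -- a short protrusion (up to 0.5 um long) with an indistinct
#' head; thin/filopodia -- a protrusion longer than 0.5 um with a head
#' narrower than 0.5 um or no distinct head. Mushroom takes precedence when
#' rules overlap (its criterion is head-based regardless of length); an
#' indistinct head is encoded as `NA` head width. Measurements matching no
#' rule (e.g. length exactly 0.5 um with a head exactly 0.5 um wide) are
#' flagged `"unclassified"` rather than silently assigned.
#'
#' @param length protrusion length in um (required, > 0).
#' @param head_width head width in um, or `NA` for an indistinct head.
#' @param neck_width neck width in um, or `NA`.
#' @return one of `"mushroom"`, `"stubby"`, `"thin_filopodia"`,
#'   `"unclassified"`.
#' @export
classify_spine <- function(length, head_width = NA_real_,
                           neck_width = NA_real_) {
  if (is.na(length) || length <= 0) stop("length must be present and > 0")
  if (!is.na(head_width) && head_width <= 0) stop("head_width must be > 0")
  if (!is.na(neck_width) && neck_width <= 0) stop("neck_width must be > 0")
  has_head <- !is.na(head_width)
  if (has_head &&
      (head_width > 0.5 ||
       (!is.na(neck_width) && head_width > 2 * neck_width)))
    return("mushroom")
  if (!has_head && length <= 0.5) return("stubby")
  if (length > 0.5 && (!has_head || head_width < 0.5))
    return("thin_filopodia")
  "unclassified"
}

#' Classify a table of spine measurements
#'
#' @param spines data frame with columns `length`, `head_width`,
#'   `neck_width` (um; `NA` = absent/indistinct).
#' @return `spines` with an added `class` column.
#' @export
classify_spines <- function(spines) {
  spines$class <- vapply(seq_len(nrow(spines)), function(i)
    classify_spine(spines$length[i], spines$head_width[i],
                   spines$neck_width[i]), character(1))
  spines
}

#' Particle localization proportions from immuno-EM counts
#'
#' Proportions of labelled synapses with the particle in the synaptic cleft
#' vs within the spine head, as raw fractions and as integer percentages for
#' reporting.
#'
#' @param cleft,intra_spine non-negative counts; their total must be > 0.
#' @return list with `pct_cleft`, `pct_intra` (integer percent) and
#'   `frac_cleft`, `frac_intra` (exact fractions summing to 1).
#' @export
particle_proportions <- function(cleft, intra_spine) {
  if (cleft < 0 || intra_spine < 0) stop("counts must be non-negative")
  total <- cleft + intra_spine
  if (total == 0) stop("total particle count must be > 0")
  list(pct_cleft = as.integer(round(100 * cleft / total)),
       pct_intra = as.integer(round(100 * intra_spine / total)),
       frac_cleft = cleft / total,
       frac_intra = intra_spine / total)
}
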