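# Independent brute-force oracles used to pin down expected values.
# These deliberately share no code with the implementation.

# tryptic digestion: walk residue by residue, start a new fragment after
# every K/R, then filter by length
oracle_digest <- function(sequence, min_len = 8, max_len = 35) {
  chars <- strsplit(sequence, "")[[1]]
  frags <- list()
  cur <- character(0)
  cur_start <- 1L
  for (i in seq_along(chars)) {
    cur <- c(cur, chars[i])
    if (chars[i] %in% c("K", "R") || i == length(chars)) {
      frags[[length(frags) + 1L]] <-
        list(seq = paste(cur, collapse = ""), start = cur_start, end = i)
      cur <- character(0)
      cur_start <- i + 1L
    }
  }
  keep <- Filter(function(f) {
    n <- nchar(f$seq); n >= min_len && n <= max_len
  }, frags)
  data.frame(sequence = vapply(keep, `[[`, character(1), "seq"),
             start = vapply(keep, `[[`, numeric(1), "start"),
             end = vapply(keep, `[[`, numeric(1), "end"),
             stringsAsFactors = FALSE)
}

# two-sided Fisher p by full enumeration over fixed-margin 2x2 tables
oracle_fisher <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (n == 0) return(1)
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(a_range, r1, r2, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUROC as pairwise concordance probability
oracle_auc <- function(scores, positive) {
  s_pos <- scores[positive]
  s_neg <- scores[!positive]
  grid <- outer(s_pos, s_neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(grid)
}

# sequence coverage by residue-level marking
oracle_coverage <- function(protein_seq, peptides) {
  covered <- rep(FALSE, nchar(protein_seq))
  for (p in peptides) {
    at <- gregexpr(p, protein_seq, fixed = TRUE)[[1]]
    for (a in at) if (a > 0) covered[a:(a + nchar(p) - 1L)] <- TRUE
  }
  mean(covered)
}

random_aa_string <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M", "N",
                 "P", "Q", "S", "T", "V", "W", "Y", "K", "R"),
               len, replace = TRUE), collapse = "")
}

# minimal peptide table builder for unit tests
toy_peptide_table <- function(peptide, protein, intensities,
                              is_phospho = FALSE, spec_count = 1L) {
  n <- length(peptide)
  tbl <- data.frame(peptide = peptide,
                    protein = rep_len(protein, n),
                    is_phospho = rep_len(is_phospho, n),
                    spec_count = rep_len(spec_count, n),
                    stringsAsFactors = FALSE)
  for (cn in names(intensities)) tbl[[cn]] <- intensities[[cn]]
  tbl
}
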