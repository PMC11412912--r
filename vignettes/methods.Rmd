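---
title: "Methods: quantification, isoform-level inference and proteoform fingerprinting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantification, isoform-level inference and proteoform fingerprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptoform)
```

## The problem

Neuron-type-specific postsynaptic proteomes can be profiled in vivo by
targeting a promiscuous biotin ligase (a BirA* probe) to the postsynaptic
membrane of a chosen cell type, affinity-purifying the biotinylated
proteins, and quantifying them by multiplexed isobaric (TMT) reporter-ion
mass spectrometry. Two analytical problems follow:

1. **Differential analysis at two tiers.** Bulk protein-level comparisons
   miss biology that happens at the *protein isoform* level: two cell types
   can express the same total amount of a gene's protein while expressing
   different splice isoforms of it. The pipeline therefore tests each
   protein twice -- once on summed protein intensities and once on the full
   peptide-by-channel matrix, where isoform differences surface as a
   genotype-by-peptide interaction.
2. **Proteoform fingerprinting.** When the isoform tier flags a gene, the
   question becomes *which* isoforms are present. Peptides are mapped to the
   exons (and exon junctions) that encode them; the normalized profile of
   exon detection events -- the exon detection-frequency table -- is a
   fingerprint that can be matched against the theoretical fingerprint of
   each annotated isoform. Gel-slice molecular-weight gating (GeLC-MS^2^)
   restricts which isoforms are eligible in which slice.

The motivating application is the striatum, where spiny projection neurons
(SPNs) of the direct and indirect pathways (dSPNs/iSPNs) express distinct
isoform complements of the postsynaptic scaffold Shank3, and where an
exon-13-16 deletion (the *Shank3B* knockout) silences full-length Shank3
while sparing short isoforms whose transcription starts downstream
(e.g. a Shank3E-like isoform encoded by exons 17-22).

## Quantification model

Let $I_{ic}$ be the reporter-ion intensity of peptide $i$ in channel $c$.

* **Protein summation.** Protein intensity is
  $S_{pc} = \sum_{i \in p} I_{ic}$. Peptides listing several accessions
  contribute to each (no razor assignment); subset proteins therefore stay
  represented, matching the inclusive protein-inference convention of the
  upstream search output this pipeline consumes.
* **Reference-set normalization.** For each channel, the factor $f_c$ is the
  median $S_{pc}$ over a reference set of cytosolic/ER proteins (these are
  labelled by every probe equally, so their median tracks channel loading,
  not biology). Normalized values are $S_{pc} / f_c \cdot \bar f$, where
  $\bar f$ is the grand mean of the factors. The rescale by $\bar f$ is a
  declared convention of this package: only cross-channel comparability is
  required, and keeping magnitudes on the input scale makes tables easier to
  audit. The operation is idempotent, and the reference median is equal in
  every channel afterwards.
* **Phosphopeptide compositional renormalization.** Within one protein and
  one channel, every peptide intensity (phosphorylated and unmodified
  together) is rescaled to the fixed total $2{,}000{,}000$:
  $\tilde I_{ic} = I_{ic} / \sum_j I_{jc} \times 2 \times 10^6$, with
  missing values treated as 0. A channel whose intensities are all zero
  yields zeros rather than an error, since zero-total channels are legal
  under the zero-fill convention. This makes phosphopeptide changes
  interpretable relative to the protein's own signal rather than its
  abundance.

## Differential testing

* **Protein tier.** One-tailed Welch $t$ (variances are always treated as
  unequal) on normalized protein intensities, reported with the ratio of
  group means. The default `direction = "auto"` tests in the direction of
  the observed difference; this matches the convention of reporting
  one-tailed p-values for both up- and down-regulated proteins but is
  anticonservative under the null (p is effectively capped at 0.5), so the
  calibration tests and any formal error-rate claims use a fixed direction.
  Degenerate zero-variance inputs (e.g. the median reference protein, which
  is exactly constant after normalization) are resolved analytically
  (p = 0.5 at zero difference) instead of erroring.
* **Isoform tier.** Two-way ANOVA of $\log_2$ intensity on genotype,
  peptide, and their interaction. The log transform is a package decision:
  reporter-ion noise is multiplicative, and on the log scale a pure
  abundance change is additive across peptides, so the interaction term
  isolates exactly the non-uniform, isoform-driven peptide behaviour.
  Type-II sums of squares are used; the simulated designs are balanced,
  where type I and type II coincide. A protein with a single peptide has no
  interaction and is flagged not assessable rather than given a p-value.
  When the fit is saturated (noise-free synthetic data) the interaction sum
  of squares decides directly.
* **Heteroscedasticity profile.** For Q-Q display the per-peptide
  $\log_2$ fold changes are standardized and paired with normal quantiles.
  As a scalar summary the package adds (its own addition -- the display
  itself is the published diagnostic) a Brown-Forsythe (median-centred
  Levene) p-value comparing, between the two groups, the spread across
  peptides of group-centred peptide mean log-intensities: silencing part of
  a gene's peptides in one group inflates that group's across-peptide
  spread, which is precisely what a heteroscedastic Q-Q fan shows.
* **Count comparisons** between analysis tiers or conditions use the exact
  two-sided Fisher test; the all-zero table returns p = 1 by convention.
* No multiple-testing correction is applied to the per-protein p-values
  (supplementary-table convention); Benjamini-Hochberg columns are emitted
  alongside as a convenience.

## Postsynaptic proteome library

Training labels come from two annotation sources: a broad, deep-coverage
postsynaptic set (proteomics-derived, known to contain some misclassified
presynaptic proteins) and a smaller curated synaptic database. Genes curated
as both pre- and postsynaptic count as postsynaptic; the exclusively
presynaptic curated genes are removed from the broad set; the cleaned broad
set is unioned with the curated postsynaptic set to form the positives. The
negative class is not specified by the source procedure; this package uses
the exclusively presynaptic, non-synaptic membrane and cytosolic/ER genes,
mirroring the two contaminant categories the library FDR is audited against.

Ten features feed a random forest (500 trees, `sqrt(p)` features per split,
fixed seed): spectral count, sequence coverage (interval union of peptide
matches), molecular weight (average residue masses), isoelectric point
(bisection on the Henderson-Hasselbalch charge sum with the EMBOSS pKa set),
$\log_{10}$(total peptide intensity / protein length), the pre/cyto and
post/cyto channel folds, and the three normalized channel values. Proteins
need two or more quantified peptides; for genes with several isoform
accessions only the highest-total-intensity accession is used. Labelled rows
are scored by their out-of-bag votes, so the ROC computed on training genes
has no training-set leakage. The ROC/AUROC is a plain threshold sweep with
trapezoid integration (cross-checked in the tests against pairwise
concordance and an independent ROC implementation). A gene enters the
library when its score reaches the threshold (default 0.5) in at least two
independent experiments; the reported FDRs are the fractions of included
genes annotated non-synaptic membrane or exclusively presynaptic.

## Proteoform fingerprinting

* **Digestion.** Fully tryptic, zero missed cleavages, cleaving after K/R.
  The "not before proline" exception is off by default (search engines
  differ; both dialects are supported via `proline_rule`). Retained peptides
  are 8-35 aa inclusive -- the window outside of which reporter-ion
  experiments essentially never identify fully tryptic peptides.
* **Exon mapping.** Isoform translations carry a per-residue exon label
  (alternative N-terminal segments are labelled as AST residues). A peptide
  within one exon gets that exon's label; one spanning two exons gets the
  junction label "A & B". Peptides spanning three or more exons get a
  chained label ("A & B & C") -- only two-exon junctions are defined by the
  source procedure, and the chained label keeps the frequency denominator
  well defined.
* **Frequency tables.** The detection frequency of exon (or AST) $i$ is
  $E_i / (\sum E + \sum EJ)$ and of junction $i$ is
  $EJ_i / (\sum E + \sum EJ)$: one shared denominator over all exon/AST and
  junction events, the only reading under which the frequencies sum to 1.
  Detection events are counted at the peptide level (one event per
  identified peptide occurrence), which is stable across instrument
  settings; spectral-count weighting can be emulated by repeating labels.
* **Standards and assignment.** Each isoform's standard table is built from
  its complete theoretical retained peptide set, one event per peptide.
  Observed and standard tables are union-aligned with zero fill, and
  assignment ranks standards by Euclidean distance -- a deterministic rule.
  A t-SNE layout (exact, non-Barnes-Hut, fixed seed, perplexity
  `min(5, n - 1)`) is provided for visual inspection only, because t-SNE
  distances are not metric-faithful; the reported assignment always comes
  from the distance ranking. Note that a suffix isoform's standard support
  is *almost* a subset of the full-length isoform's: all cleavage sites
  downstream of its start coincide, but its N-terminal peptide can carry a
  label the full-length digest never produces (the full-length peptide
  covering that region extends into the upstream exon).
* **Gel slices.** Isoform candidacy per slice is plain interval membership
  of the theoretical MW in the slice's kDa window. Slice windows are
  configuration: real cut points come from the ladder used at the bench.

## Synthetic data: what it emulates, and what not

The generator reproduces the statistical structure the methods rely on:
multi-channel designs with one group label per channel (the 10-plex
two-group and 3-plex three-probe layouts), multiplicative log-normal
peptide-channel noise with unit mean and configurable CV, per-group protein
fold effects, and genotypes defined by exon deletions whose unique peptides
are silenced in the affected group's channels. Silenced peptides receive a
floor of $10^{-3} \times$ baseline rather than exact zero so that log and
ratio arithmetic stays defined (zero handling belongs to the phospho
renormalization, which has its own convention). Gene models carry in-frame
amino-acid exon segments directly -- there is no nucleotide-level splice
simulation -- and generated sequences place K/R at about one residue in 15
so the 8-35 aa retention window is exercised without being degenerate.
Biological replicate variance is a free parameter (`noise_cv`, default 0.2
-- a typical reporter-ion CV for biological replicates); the source study
does not state its replicate variance structure.

Passing tests on these data show the machinery is correct under the stated
noise model; they do not show robustness to everything real data adds:
missing channels, interference/ratio compression in reporter ions,
semi-tryptic peptides, shared peptides across genes, or search-engine FDR
structure. Those inputs are consumed as given, not modelled.

## Numerical choices and problem sizes

* Medians use the midpoint convention for even counts (R's default).
* Accession ties in primary-accession selection break lexicographically.
* The silencing floor is $10^{-3}$, large enough to keep logs finite and
  small enough that a silenced subset is unambiguous at `noise_cv = 0.2`.
* Calibration tests run 2000 null simulations per test (type-I error bands
  [0.04, 0.06] at alpha 0.05, Kolmogorov-Smirnov distance < 0.05 from
  uniform) and 500 simulations for interaction power at n = 5
  channels/group; classifier checks use 200 proteins per class; proteoform
  recovery uses 100 dropout replicates at 30% dropout. These sizes give
  stable Monte-Carlo estimates while keeping the default suite fast.
* All randomness is seeded; generators are bit-reproducible at the
  text-serialization level under a fixed seed.

## Known limitations

* The one-tailed `direction = "auto"` convention is anticonservative; use
  fixed directions for error-rate work.
* The negative training class and the normalization rescale are package
  decisions where the source procedure is silent (both documented above).
* Real annotation databases and real MS data are not bundled; the library
  FDRs reported on synthetic data are formats, not reproductions of any
  published value. The theoretical-MW check against the canonical mouse
  Shank3 sequence (UniProt Q4ACU6-1) requires the user to download that
  sequence; third-party data are not shipped.
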