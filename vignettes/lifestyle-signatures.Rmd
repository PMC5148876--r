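---
title: "Reading lifestyle signatures from a fungal genome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading lifestyle signatures from a fungal genome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endosig)
```

# Scope

`endosig` implements the comparative analyses by which the genome of a fungal
root endophyte can be read against a panel of reference genomes with known
lifestyles: five plant pathogens, six saprotrophs, two ectomycorrhizal
species, and the focal endophyte (`species_panel()`). Each analysis answers a
different question — is a genome-defense process (RIP) active? were genes
acquired horizontally from bacteria? does the ortholog and domain inventory
look pathogen-like, saprotroph-like, or mycorrhizal? — and each is paired
with a seeded synthetic-data generator that plants a known signal, so every
stage can be validated against ground truth.

The package deliberately consumes the *outputs* of the heavy upstream
machinery (repeat detectors, ortholog inference, domain annotation, BLAST
searches) in simple tabular shapes, and re-implements the decision rules and
statistics applied to them. Running the upstream tools is out of scope.

# RIP dinucleotide analysis

Repeat-induced point mutation (RIP) is a fungal genome-defense process that
introduces C→T transitions in repeated sequence, converting CpA
dinucleotides to TpA (and, on the opposite strand, TpG to TpA on the forward
strand). Active or historical RIP therefore leaves a skew: TpA is enriched
in repeats relative to single-copy control sequence, while CpA and TpG are
depleted.

`count_dinucleotides()` counts overlapping dinucleotides on the forward
strand, within but never across sequences, skipping any pair containing `N`
(assembly gaps must not dilute frequencies). `fold_change()` reports, per
dinucleotide, the repeat/control frequency ratio (the headline statistic)
alongside the difference. Design choices worth knowing:

* **Control selection.** How control sequence should be chosen is
  underdetermined; we draw one non-repeat segment per repeat, of identical
  length, uniformly without overlap and under a caller-supplied seed
  (`sample_controls()`). This matches the repeat set in both total mass and
  length distribution, so composition biases that correlate with fragment
  length cancel.
* **Strandedness.** Counting is forward-strand only; the CpA/TpG symmetry of
  the RIP process itself is handled by the generator and interpreted jointly
  downstream.
* **Significance.** Over/underrepresentation is tested per dinucleotide with
  a chi-square goodness-of-fit of the repeat counts against the control
  frequency, Bonferroni-corrected across the 16 dinucleotides at α = 0.05.
  The choice of test is ours; the ratio remains the primary readout.
* **Normalization.** Frequencies are normalized within each region class
  (repeats; controls), not genome-wide.

`window_tracks()` supplies the standard 1 kb / 1 kb sliding-window gene,
repeat and GC fractions (half-open interval arithmetic; a trailing short
window is flagged partial), and `filter_repeat_candidates()` reproduces the
repeat-library filter: drop candidates under 50 bases or with fewer than 10
genomic hits, then collapse redundancy by greedy centroid clustering
(identity ≥ 0.90 with coverage ≥ 0.90 of the shorter sequence) keeping the
longest member (ties: smallest id) per cluster.

# The HGT screen

Candidate horizontally transferred genes are screened from per-gene homolog
hit tables (coverage ≥ 40%, identity ≥ 20%, best 1,000 hits retained by
`filter_hits()`). A gene is a candidate (`call_candidate()`) if

1. fewer than 15% of its hits are fungal (*taxonomic skew*), and/or
2. its best fungal bit score is below its best non-fungal bit score
   (*bit-score dominance*).

We compare maxima rather than means because the maximum is robust to
truncation of the hit list; a mean mode is available. A gene with no fungal
hits triggers both reasons; a gene with no hits at all is reported
not-evaluable rather than called. The rules are combined with OR and the
reasons reported, so an AND analysis remains possible downstream.

Candidates are then confirmed on a gene tree. Hit sequences are collapsed by
greedy centroid clustering (`greedy_cluster()`: length-sorted, first
centroid at identity ≥ threshold wins, founders are centroids) with an
adaptive threshold (`adaptive_cluster()`): start at 0.95 and lower in steps
of 0.05 until at most 40 clusters remain or the 0.50 floor is reached —
applied to non-fungal sequences, and to fungal sequences only when they
exceed the cap. Identity is global-alignment identity (match +1, mismatch
−1; a length-*k* gap costs 2 + (*k* − 1); identical positions divided by
full alignment length). The exact gap convention is a reproducibility
choice, not a scientific one. Cluster representatives plus the focal
sequence enter a neighbor-joining tree on 1 − identity distances
(`nj_tree()`, via ape), a deliberately lightweight surrogate for a full
alignment/ML pipeline: adequate here because the confirmation question is
only *which side of the tree the focal gene sits on*. `sister_clade_call()`
roots at the leaf farthest from the focal gene (midpoint rooting on ties —
trees from distance methods are unrooted, so some convention is required)
and reports whether the focal gene's smallest enclosing clade is entirely
non-fungal (supported HGT), entirely fungal, or mixed. A conserved
housekeeping-gene preset (`rpb2_control_settings()`: identity floor 0.75,
clustering at 0.90) supports a negative control.

# Ortholog-cluster lifestyle enrichment and PCA

On a binary cluster × species presence/absence matrix,
`select_enriched_clusters()` applies the lifestyle rule: a pathogen-enriched
cluster has at least 4 of the 5 pathogens, at most one saprotroph, at most
one mycorrhizal species, and the focal species present. The saprotroph
preset is the proportional analogue (≥ 5 of 6; pathogens and mycorrhizal
species capped at 1; focal required). The saprotroph thresholds are our
reading of "the same strategy" applied to a six-species group; every
threshold is exposed, so stricter or looser variants are one argument away.

`pca_placement()` performs centered, by default unscaled PCA (singular value
decomposition via `prcomp`) of a species × feature matrix — presence/absence
columns of selected clusters, lifestyle-skewed domain counts, or CAZyme
substrate totals. Two conventions make results deterministic and
comparable: within each component the loading of largest magnitude is made
positive, and lifestyle centroids in PC1/PC2 space exclude the focal
species (which is being placed, and must not pull its own centroid). A
zero-variance matrix is flagged degenerate instead of erroring.
`sharing_table()` gives pairwise cluster co-occurrence counts with
per-species totals on the diagonal, and `funcat_top_categories()` ranks
functional categories counting each (gene, category) pair once.

# Annotation (domain) enrichment

`ztest_enrichment()` compares the focal species' count of each annotation
accession against the mean of the 13 comparison species, standardized by
their sample standard deviation (n − 1), with a two-sided normal p-value at
α = 0.05 and no multiple-testing correction by default (the raw flagged
count is the headline number; Benjamini–Hochberg is available). The focal
species is excluded from both the mean and the standard deviation. When the
comparison standard deviation is zero, a focal count equal to the common
value is not significant; any other focal count is reported as a separate
degenerate-over/under status and counted as significant.

A known property of this statistic: because the focal count is itself
random, the null distribution of (focal − mean)/sd is √(1 + 1/13) × t with
12 degrees of freedom, so the realized type-I error at a nominal α = 0.05
is ≈ 0.08, not 0.05 — for any independent identically distributed null,
regardless of the count model. Users comparing flagged counts across
studies should keep this anticonservatism in mind; it is inherent to the
method, and we reproduce the method rather than silently "fixing" it to a
t-test.

`fold_screen()` (focal count strictly greater than *k* × comparison mean;
accessions absent from all comparison species qualify from an absolute
focal count of 3) and `lifestyle_fold_screen()` (target-lifestyle mean
strictly greater than *k* × the mean over the remaining comparison species,
focal excluded from both sides) are simple deterministic screens whose
outputs feed the PCA placement. `saturation_curve()` and `go_rollup()`
provide the distinct-vs-total accession summaries and GO-term rollups
(unmapped accessions fall into an `NA` bin; each accession counts once per
term).

# CAZyme substrate profiling

`module_counts()` counts CAZyme *modules*, not genes — a gene annotated
GH5;GH5;CBM1 contributes three modules — because module counts are the
published convention for these inventories. `substrate_profile()` sums
modules into the canonical plant-cell-wall substrate classes
(`default_substrate_map()`): cellulose (GH6, GH7, GH45), hemicellulose
(GH10, GH11, GH26, GH31, GH67, GH115, GH134), pectin (GH28, GH53, GH78,
GH79, GH88, GH105, GH106, GH127, PL1, PL3, PL4, PL9, PL11, CE8, CE12),
cutin (CE5), and a class of families acting on multiple substrates (GH12,
GH30, GH43, GH5, GH51, GH54, GH62, GH74, GH93). The "multiple" class is a
fifth PCA feature in its own right; families outside the map are excluded
from profiles but reported as an unassigned total, so module counts are
conserved. Ectomycorrhizal genomes, with their reduced wall-degrading
repertoires, separate on PC1 of these profiles — a geometry the test suite
checks on planted profiles.

# Secondary-metabolite key genes

`classify_architecture()` assigns PKS/NRPS classes from ordered domain
strings with a strict rule priority: KS with both C and A is a PKS-NRPS
hybrid; any other KS-containing architecture is a type I PKS (nonreducing
iff it has neither KR nor ER); a KS-less architecture carrying AT plus a
reducing domain is still a reducing type I PKS (a degraded PKS); C with A
and T is an NRPS; A with T alone is NRPS-like (A-T-R, A-T-TE, A-T-DUF and
variants). Two subtleties drove the rule shape: a *trailing* condensation
domain on a reducing PKS (lovastatin-nonaketide-like KS-AT-DH-MT-KR-T-C)
does not make a hybrid without an adenylation domain, and headless
AT-DH-MT-ER-KR-T architectures are curated as reducing PKSs. The shipped
table of 58 curated key genes of the *P. subalpina* genome
(`sm_key_gene_table()`) is the golden file: the classifier reproduces every
curated label, including exactly eight nonreducing type I PKSs. Type III
PKSs, DMATS and terpene synthases are identified by InterPro accessions
upstream and passed through unchanged.

`detect_sm_clusters()` reports a putative biosynthetic locus when at least
two tailoring-enzyme genes (acyl-/methyltransferases, oxidoreductases,
cytochrome P450s, transcription factors) lie within ten genes up- or
downstream of a key gene; the window of ten is our choice, exposed as an
argument. `copy_number_summary()` recomputes gene-family medians across
species (focal included; even panels use the central-pair mean); ambiguous
published cells such as `2(3)` resolve to their first integer with a
warning. On the shipped RNAi/RIP table the recomputed medians match the
published values for Argonaute (2), Dicer (2) and RdRP (3); the published
Dnmt1 median (1) is not reproducible from its printed row under any
convention we tested (the row's median is 2 with or without the focal
species), so that row is flagged rather than forced.

# The synthetic-data generators

`sim_config()` fixes the study conditions; one master seed drives
everything, with fixed per-stage offsets so stages regenerate
independently and bit-identically.

* **Ortholog matrices** — background cells i.i.d. Bernoulli(0.5); planted
  rows constructed to satisfy the target rule exactly.
* **Annotation counts** — negative binomial, mean 20, size 50 (variance
  μ + μ²/size = 28): counts large enough that the Z statistic's continuous
  approximation is meaningful, with mild extra-Poisson noise as seen across
  related genomes. Planted accessions multiply the focal mean by the
  configured fold (default 4).
* **RIP genomes** — a 500 kb scaffold at GC 0.459 (the focal genome's
  printed GC), 100 non-overlapping 600 bp repeats (60 kb of repeat, enough
  for stable dinucleotide frequencies) and 60 gene intervals of 1.5 kb;
  interval placement samples uniformly over feasible positions given the
  remaining gaps. Within repeats each CpA and TpG is converted to TpA
  independently with probability `rip_rate`; mutated positions are
  recorded as ground truth.
* **Hit tables** — 50 hits per gene; null genes are 85% fungal with fungal
  bit scores ~N(300, 30) dominating non-fungal ~N(200, 30); planted HGT
  genes invert both (5% fungal by default, 0% in the extreme setting).
  Per-hit sequences diverge 5% from the focal sequence on the dominant
  side and 40% on the other, so the tree stage sees the same signal as the
  score stage.

What the generators do *not* emulate: phylogenetic correlation among the
panel species (all cells are independent), realistic gene structure or
codon usage, compositional heterogeneity along the genome, taxonomically
structured hit lists, or sequencing error. Passing tests therefore
demonstrate that the decision rules and statistics behave as specified on
data matching their assumptions — not that those assumptions hold for any
particular real genome.

# Numerical and degenerate-input conventions

Coordinates are 0-based half-open throughout. Printed percentages use
half-up rounding (`proportion()`), matching how such ratios are
conventionally typeset — bankers' rounding would disagree on exact halves.
Ties are broken deterministically everywhere: cluster centroids by length
then id; category ranks by count then id; PCA signs by the largest loading.
Empty hit tables, zero-variance matrices, all-`N` sequences, and
unplaceable interval requests produce flagged results or descriptive
errors, never silent numbers.

Problem sizes in the shipped tests and acceptance script (500-cluster
matrices, 1,000-accession tables, 500 kb genomes, 200-gene hit panels) were
chosen as the smallest sizes at which the planted-signal recoveries are
stable to Monte-Carlo noise.

# Known limitations

* The Z-test's realized type-I error is ≈ 0.08 at nominal 0.05 (see above);
  it is reproduced, not corrected.
* Greedy centroid clustering is order-dependent by construction (as in
  uclust-style tools); the length sort makes it deterministic but not
  optimal.
* The neighbor-joining confirmation uses identity distances on unaligned
  cluster representatives; it is a screen, not a substitute for a proper
  phylogenetic analysis with alignment, trimming and support values.
* Repeat-candidate redundancy removal approximates a blastclust-style local
  criterion with a global-alignment identity; near-identical full-length
  copies collapse identically, but a short perfect fragment of a longer
  candidate is kept separate rather than merged.
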