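---
title: "Methods: paired primary-recurrence tumor evolution analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired primary-recurrence tumor evolution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recurdrift)
```

# Scope and model

recurdrift analyses matched pairs of a primary breast tumor (PT) and its
ipsilateral in-breast recurrence (IBTR) across three molecular layers —
somatic SNVs and copy number from DNA, transcript abundance, and protein
abundance — plus a clinical association layer. The question throughout is
how far the recurrence has drifted from the primary it arose from, and
whether that drift associates with clinical features.

Every stage is driven either by user-supplied tables or by the package's
seeded synthetic cohort generator, so the full pipeline is testable
without access to restricted patient data.

# Somatic SNV filter cascade

Variant calls arrive annotated (impact, consequence, population allele
frequencies, trinucleotide flanks); the package performs no alignment,
calling or annotation. Five filters are applied in a fixed order, and
each removed variant is attributed to the first filter it fails:

1. **Population allele frequency** — both population frequencies
   (gnomAD-style and SweFreq-style columns) must be 0 or missing. A
   missing frequency is deliberately distinct from 0; both pass.
2. **Allelic depth** — at least 2 supporting reads in the tumor; at most
   1 in the matched normal when one exists.
3. **Coverage** — at least 10 reads total depth in the tumor (and in the
   matched normal when present).
4. **Panel of normals** — the variant key (chrom, pos, ref, alt) must not
   occur in the blacklist built from keys seen in at least two normal
   samples. Keys include both alleles, so a different alternate allele at
   a blacklisted position still passes.
5. **Purity likelihood ratio** — see below.

The kept set equals the conjunction of the five predicates, so filter
order affects only the attribution counts, a property the test suite
asserts directly.

## The purity-scaled binomial likelihood ratio

For a sample with tumor purity $t$ and a variant with $s$ supporting
reads out of $c$, two binomial models are compared. The heterozygous
model uses success probability $p_{cancer} = t/2$ against a germline
background of $1/2$; the homozygous model uses $t$ against $1$. The
statistic is

$$\log_2\!\left(\frac{2\,P(s;c,p_{cancer})}{P(s;c,p_{background})}\right)$$

with $P(k;n,p)$ the binomial pmf, evaluated in log space via `dbinom(log
= TRUE)` so high depths cannot underflow. A variant is kept when any
defined model exceeds the threshold (default $-1$); samples without a
purity estimate skip the filter entirely.

The homozygous background $P(s;c,1)$ is exactly zero whenever $s < c$,
which taken literally would make that branch keep every subclonal
variant and render the filter vacuous. We therefore flag a model with
zero background probability as *non-informative* and decide on the
remaining model(s); if all models are non-informative the variant is
kept. The literal behaviour is available behind `literal_hom = TRUE` so
the two readings can be compared. Note the factor 2 in the ratio: at the
default threshold of $-1$ a variant is dropped when the background model
is at least four times as likely as the cancer model.

After the cascade, the cancer-gene analysis restricts to variants of
MODERATE or HIGH impact whose consequence is none of: upstream gene
variant, downstream gene variant, 5'/3' UTR variant, synonymous variant.
We filter first and restrict second; both orders give the same kept set
because the two predicates touch disjoint fields, and the order is
exposed to callers anyway since the steps are separate functions.

# Mutational signatures

Spectra are counts over the 96 pyrimidine-centered trinucleotide
contexts; purine-reference records are reverse-complemented (flanks swap
and complement), collapsing the 192 raw strand representations onto 96
classes. Refitting solves

$$\min_w \lVert \mathrm{counts} - \mathrm{profiles}\cdot w\rVert_2,\quad w \ge 0$$

with a Lawson–Hanson active-set solver (tolerance $10^{-10}$,
deterministic), then normalises $w$ to fractions. The tests verify the
Karush–Kuhn–Tucker conditions of each solution and agreement with an
independent solver, and recovery of known mixtures from multinomial
spectra (mean absolute fraction error well under 0.05 at 5000 draws).

Per pair, the contribution delta is fraction(IBTR) − fraction(PT); both
inputs are simplex vectors, so deltas sum to zero. Signature selection
keeps the upper half of signatures ranked by mean fraction across
samples, ties at the median retained: the selection exists to drop
signatures *without* enough contribution, so "first and second
quartiles" is read as the top half. The reading is a package decision
and is confined to `select_signatures()`.

The signature matrix is an input file (COSMIC v2 tab-delimited layout,
96 labelled rows). Tests and simulations use small synthetic matrices
built by `synthetic_signature_matrix()` — block-structured, clearly
labelled synthetic stand-ins, not reconstructions of any catalogue.

# Copy number

Coverage is summarised in fixed 10-kb bins (0-based half-open) with a GC
fraction per bin. The GC model is robust locally weighted regression of
coverage on GC (`stats::lowess`, bisquare reweighting, 3 iterations,
span 0.3), and each bin is rescaled by median(fitted)/fitted(gc), which
removes the GC trend while preserving the sample's median coverage.
Log2 ratios use the matched normal as denominator when available,
otherwise the sample's own median; tracks are median-centered. Masked
bins (zero denominator, non-positive fit) are excluded downstream, never
imputed.

Segmentation is a circular binary segmentation: on each chromosome the
arc $(i, i+m]$ maximising

$$Z = \frac{|D_{i+m} - D_i|}{\hat\sigma\sqrt{m(1 - m/n)}},
\qquad D_k = \sum_{j\le k}(y_j - \bar y)$$

is tested against its permutation null (default 1000 permutations,
$\alpha = 0.01$, fixed seed, early stop once the p-value provably
exceeds $\alpha$); accepted change-points split the chromosome into up
to three pieces which are segmented recursively. Prefix arcs make plain
terminal splits a special case, while interior arcs catch focal events
that a single-breakpoint search provably misses — the property tests
include a 5-bin focal amplification and compare first-level boundaries
against brute-force arc enumeration. Defaults ($\alpha$, `min_bins = 5`,
`n_perm = 1000`) are package choices, documented as such.

Gene-level CN is the unweighted mean over all segments overlapping at
least one exon of the gene (exon intervals only, not gene bodies;
unweighted because no weighting rule is defined for the averaging).
Paired calls use DeltaCN = CN(IBTR) − CN(PT) with gain > +0.75, loss <
−0.75, and both values at least 0.5 to be evaluable.

**Scale of the 0.5 rule.** On the centered log2 scale, copy-neutral
genes sit at CN ≈ 0, so a literal "minimum CN of 0.5" would mark
essentially every gene not-evaluable and no gain could ever be called.
`gene_copy_number()` therefore defaults to the coverage-ratio scale
$2^{\text{mean log2}}$ (copy-neutral = 1), where the 0.5 floor excludes
genes in near-homozygous-deletion territory and the ±0.75 thresholds
correspond to meaningful ratio shifts; `scale = "log2"` preserves the
literal reading for comparison.

# Multi-omic drift

Per layer (CN, RNA, protein), drift between pair members is the cosine
dissimilarity

$$1 - \frac{x\cdot y}{\lVert x\rVert\,\lVert y\rVert} \in [0, 2]$$

computed on complete-case feature tables (any row with a missing value
is dropped first, making values comparable across layers with different
feature counts). Cosine is scale-invariant per column, so no cross-layer
normalisation is applied.

Pair *co-clustering* is operationalised as mutual nearest neighbours
under the full sample-by-sample dissimilarity matrix: the published
analysis shows co-clustering visually on a dendrogram without a formal
criterion, so the metric here is a package decision. The accompanying
dendrogram uses average linkage by default (configurable, since no
linkage is stated).

# Clinical associations

- 2×2 tables: two-sided Fisher exact test under the "probability at most
  that of the observed table" convention — the convention that
  reproduces the published cohort's printed p-values from its printed
  counts (ER 1.000, PgR 0.572, Ki-67 0.556, ERBB2 1.000, age 0.586).
- R×C tables: Pearson chi-square without continuity correction
  (validated by reproducing the grade 2×3 p-value 0.549, df = 2).
- Group comparisons of deltas: two-sided Wilcoxon rank-sum, exact for
  combined n ≤ 20 without ties, normal approximation with tie correction
  otherwise; one Benjamini–Hochberg family per `associate_deltas()`
  call, never inferred.
- Spearman correlation with average ranks and the t approximation.
- Histo-score: sum of cohort z-scores of the Ki-67-positive cell
  percentage and the infiltrating-leukocyte percentage; errors name the
  degenerate marker if a cohort standard deviation is zero.
- Survival: scores are median-split (ties to the low group — a package
  decision, documented because no tie rule is stated) and compared by
  the standard two-group log-rank test via the survival package.

Missing clinical categories are dropped pairwise per test and each
result records the n actually used.

# The synthetic cohort generator

The generator emulates the statistical structure of a 27-pair cohort:

- **Variants**: per patient, a clonal trunk (default 100 variants)
  present in both members with support Binomial(depth, purity/2), plus
  private variants (default 30 PT, 60 IBTR — recurrences accrue more),
  with per-variant depth Poisson(45). Trunk and PT-private contexts are
  drawn from the PT signature mixture, IBTR-private contexts from the
  IBTR mixture, applied to the supplied signature matrix; the trunk
  predates divergence, so the recurrence's realised mixture is the
  shared/private-weighted blend, which the truth set records alongside
  the configured mixtures.
- **Contaminants**: germline injections carry a population allele
  frequency drawn uniform(0.01, 0.5) and sit at VAF 1/2; true somatics
  carry frequency exactly 0, matching the filter's "0 or NA" rule.
  Recurrent artifacts are planted in at least two simulated normals so
  the panel of normals catches them.
- **Coverage**: a 2-chromosome synthetic genome (20 Mb + 10 Mb; the
  coordinates never pretend to be a reference genome) tiled in 10-kb
  bins, expected coverage depth · gc_curve(gc) · 2^(true log2 CN) with
  5% Gaussian noise by default, and configurable injected CN events.
- **Expression/protein drift**: IBTR column = PT column + N(0,
  drift_sigma) per feature, which makes the expected pair dissimilarity
  monotone in drift_sigma — the property the drift tests exploit — and
  exactly zero at drift_sigma = 0.
- **Clinical table**: patient-level biomarker categories with a 10%
  PT/IBTR discordance rate, exponential follow-up times.

Purities are drawn uniform(0.3, 0.9); depth 45 reflects a
moderate-depth whole-genome design. Each patient consumes an RNG
sub-stream at a fixed offset from the seed, so enlarging the cohort
never perturbs earlier patients, and an identical configuration always
reproduces the bundle byte-for-byte.

**What the generator does not emulate**: subclonal phylogenies, indels
and structural variants, realistic linkage or mutation hotspots,
batch effects, or biologically structured expression covariance.
Passing tests therefore demonstrate correctness of the statistical
machinery on data of known structure, not performance on real tumors.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale: cohorts
of 1–6 patients for end-to-end checks, 3000-bin genomes for copy
number, 5000-draw multinomial spectra for signature recovery, 20 seeds
for every stochastic property, 200 permutations per segmentation test.
These sizes were chosen so the whole suite exercises every stage in a
few minutes while leaving the stochastic assertions comfortable margins
(e.g. observed signature-recovery error ≈ 0.004 against the 0.05
bound).

Ties, degenerate inputs and edge semantics are pinned down explicitly:
zero-probability backgrounds in the purity filter (above), zero-norm
columns in cosine dissimilarity (an error, not NaN), all-zero spectra
(zero fractions plus a flag), degenerate GC ranges (flat model with
warning), fully tied rank tests (p = 1, flagged), zero-margin 2×2
tables (p = 1, flagged), no-event survival comparisons (p = 1,
flagged), and median-split ties (low group).

# Known limitations

- The segmentation permutation test assumes exchangeable bins within a
  chromosome; strong autocorrelation would inflate splits.
- Gene CN averaging is unweighted across segments; an exon-length
  weighted variant would differ for genes straddling many short
  segments.
- The purity filter treats purity as known; uncertainty in the estimate
  is not propagated.
- Co-clustering by mutual nearest neighbours is stricter than visual
  dendrogram adjacency; fractions are not directly comparable to
  figure-based counts.
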