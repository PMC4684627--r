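---
title: "Methods: coverage QC, deletion calling, variant prioritization and diagnostic classification for an HLH gene panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage QC, deletion calling, variant prioritization and diagnostic classification for an HLH gene panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlhpanel)
```

## The diagnostic problem

Hemophagocytic lymphohistiocytosis (HLH) is a rapid-onset hyperinflammatory
syndrome. Its familial forms are caused by biallelic loss of genes required
for lymphocyte cytotoxicity (`PRF1`, `UNC13D`, `STX11`, `STXBP2` — familial
HLH types 2–5), by biallelic defects in trafficking genes that also cause
hypopigmentation syndromes (`RAB27A`, `LYST`, `AP3B1`, `BLOC1S6`), and by
hemizygous defects of X-linked genes (`SH2D1A`, `XIAP`, `MAGT1`);
`ITK` deficiency produces a related lymphoproliferative picture. A
twelve-gene amplicon panel over these loci supports rapid molecular
diagnosis. `hlhpanel` implements the downstream computation such a panel
needs once per-amplicon depths and annotated variant calls exist: coverage
quality control, detection of large homozygous/hemizygous exonic deletions
from depth, a variant prioritization cascade, inheritance-aware diagnosis
assignment, and the cohort- and population-level statistics used to
evaluate the assay. Read mapping, primary variant calling and annotation
(VEP-style consequences, SIFT/PolyPhen-2/CADD) are upstream tools whose
outputs the package consumes.

## Coverage QC

Depth is summarized per (sample, amplicon) as mean read depth. Display
categories are `<10x` (`[0,10)`), `10-50x` (`[10,50]`) and `>50x`. An
amplicon *fails* when its mean depth across samples is **at or below** 10×.
The two boundary conventions differ deliberately: the display boundary at
10 is exclusive while the failure cut-off is inclusive, so a mean of
exactly 10 displays in the middle category yet fails QC. Whether 50 belongs
to the middle category is not fixed by any assay property; we chose
inclusive and document it here.

Effective target coverage is bp-weighted:
$100\,(designed - failed)/total$, with per-gene percentages computed over
the union of each gene's amplicon intervals (overlapping amplicons are not
double-counted; the union is computed with `IRanges`). Known-site coverage
is the fraction of user-supplied 1-based point positions falling strictly
inside a non-failed amplicon under the 0-based half-open interval
convention — a site whose 0-based coordinate equals an amplicon `end` is
outside it.

## Deletion calling from amplicon depth

Large homozygous and hemizygous exonic deletions leave an unmistakable
depth signature: a run of consecutive amplicons at essentially zero
coverage in one sample. The caller formalizes this with median-of-ratios
normalization: depths are divided by the per-sample median (library size),
then by the per-amplicon median of those values across samples (amplicon
efficiency). A diploid cell sits near ratio 1; multiplying one library's
depths by any constant leaves its ratios unchanged. Medians keep the
reference robust to failed amplicons and to the deletions themselves; at
least three samples are required, and a sample with median depth 0 is
uncallable.

A call is a maximal run of at least `min_run = 2` consecutive same-gene
amplicons with ratio below `threshold = 0.1`. Both parameters are exposed.
The threshold tolerates mispriming background (residual reads inside a
true deletion) while excluding heterozygous single-copy losses, which sit
near 0.5 and which this assay does not claim to detect. Zygosity labels
follow the inheritance model: X-linked gene in a male gives `hemizygous`,
otherwise `homozygous`. Isolated single-amplicon dips are reported in a
separate *unconfirmed* tier and never as calls — a single amplicon can dip
for reasons other than a deletion (allele-specific primer dropout, for
one), so a one-amplicon signal is a lead for orthogonal confirmation, not
a call.

## The variant prioritization cascade

Filters apply in a fixed order, and a `FilterTrace` records counts and the
per-consequence breakdown at each step:

1. **Consequence**: retain terms with a possible protein or splicing
   impact (missense, stop gained/lost, start lost, frameshift, in-frame
   indel, splice donor/acceptor/region); drop synonymous, non-splice
   intronic, UTR and regulatory-only annotations. Unrecognised terms are
   retained and flagged — a vocabulary gap must not silently discard a
   variant. Known deep-intronic regulatory mutations survive only via an
   explicit allow-list, since no consequence rule can admit them without
   admitting all regulatory noise.
2. **Frequency**: retain minor allele frequency strictly below 0.05; a
   missing frequency means the variant is absent from the reference
   population and is treated as 0 (retained).
3. **Hardy–Weinberg** (population mode only): remove sites whose genotype
   counts deviate from equilibrium at `alpha = 0.05`, using the exact
   conditional test — enumerate all heterozygote counts compatible with
   the observed allele counts and sum the probabilities of configurations
   no more probable than the observed one. The exact test (rather than a
   chi-square) is the valid choice at the rare-allele counts that dominate
   these genes. In a large outbred cohort this step is a genotyping-quality
   filter. It runs before the damaging filter so that "further analyses"
   operate on quality-filtered sites.
4. **In-silico damaging**: retain variants called deleterious by SIFT *or*
   possibly/probably damaging by PolyPhen-2. Loss-of-function consequences
   bypass this filter: the predictors score only missense changes, and
   without the bypass every nonsense and frameshift allele would be
   discarded. Missense variants with both predictions missing are dropped
   in population mode but retained-with-flag in patient mode, where a
   candidate must survive to manual review.

Patient-mode qualifying variants are deliberately labelled *qualifying*,
not *pathogenic*: final causality assessment is curation, modelled as an
explicit allow/deny list input rather than an algorithm.

## Diagnosis assignment

A patient is **diagnosed** when a single gene explains the phenotype under
its inheritance model: an autosomal-recessive gene with one homozygous
qualifying variant, a homozygous exonic-deletion call, or at least two
distinct heterozygous qualifying alleles; or an X-linked gene with a
hemizygous qualifying variant or deletion call in a male. Two heterozygous
variants are *presumed* compound heterozygous (in trans) when they lie at
different positions of one gene; parental genotypes, when supplied, can
veto a cis pair, and two hets at the same position are treated as one
allele candidate and flagged. Externally typed structural alleles (such as
a known `UNC13D` intronic inversion typed by a dedicated PCR assay) enter
as allele records, so one heterozygous SNV plus one external allele can
complete a compound-heterozygous diagnosis. A female heterozygous for an
X-linked variant is a carrier and is never diagnosed through that gene.
Patients not diagnosed but carrying at least one damaging-predicted
monoallelic variant are reported `vus_only`; the rest `undiagnosed`.

Cohort yield is stratified by age at diagnosis into the bins
`[0,1), [1,5), [5,12), [12,18), [18,∞)`. A patient of unknown age is
excluded from binned yields and from the infant/older split but retained
in the overall yield and in the pediatric subset, which is defined as
"excluding known adult cases" — the conservative reading when age is
missing, and the one consistent with reporting the overall and pediatric
denominators side by side.

## Statistics

* **Wilson score interval** for the validation sensitivity, without
  continuity correction; both bounds are reported at full precision. For
  72 successes of 74 the interval is (0.9067, 0.9926).
* **Fisher's exact test** (two-sided) uses the probability-mass rule: sum
  the hypergeometric probabilities of all tables with the observed margins
  that are no more probable than the observed table. Two-sided definitions
  differ between tools, so the rule is fixed here and cross-checked in the
  test suite against both an enumeration oracle and `stats::fisher.test`.
* **Wilcoxon rank-sum** uses midranks for ties, exact enumeration of the
  null when the smaller group has ≤ 10 observations and the pooled sample
  ≤ 20, and a tie-corrected, continuity-corrected normal approximation
  otherwise (`stats::wilcox.test` cannot produce exact p-values under
  ties, hence the in-package enumeration).
* **Carrier burden** counts individuals with at least one qualifying
  allele, homozygous carriers, and per-gene tallies, optionally restricted
  to the familial-HLH genes; cohort-versus-population comparisons are 2×2
  Fisher tests reported raw with a Bonferroni column alongside (the
  adjustment column is a convenience; raw values remain primary).

## The synthetic-data generator

Every stage is testable without restricted patient data through seeded
generators whose defaults describe the study conditions the package
targets:

* **Coverage**: negative-binomial counts with mean
  `depth_mean × amplicon_factor × sample_factor`; log-normal factors
  (amplicon efficiency SD 0.3, library-size SD 0.25 on the log scale),
  dispersion 0.15 (variance `μ + 0.15 μ²`; 0 recovers Poisson — the
  paperless choice here is the standard overdispersed-count model for
  amplicon data). Two amplicons are forced to fail (mean 3×) by default,
  and planted deletions draw a residual mean of 1 read so the caller's
  threshold is genuinely exercised rather than handed exact zeros. Random
  failure placement avoids planted deletion runs; *designating* a failed
  amplicon inside a deletion is rejected, because the ground truth would
  be confounded.
* **Cohorts**: patients receive a ground-truth class — biallelic (one
  homozygous or two heterozygous rare damaging/LoF variants in one AR
  gene), hemizygous (X-linked variant; such patients are assigned male
  sex, so the class is well-defined by construction), monoallelic VUS
  (exactly one damaging-predicted heterozygous variant), or benign-only —
  plus common background polymorphisms and synonymous variants for the
  cascade to remove. Metadata distributions default to a typical
  prospective HLH cohort: about a third of onsets in infancy, roughly even
  sex ratio, frequent consanguinity, secondary triggers concentrated among
  patients without a cytotoxicity-gene defect.
* **Populations**: per-site genotypes follow Hardy–Weinberg proportions
  distorted by an inbreeding-like coefficient `f`
  (`(1-q)² + fq(1-q)`, `2q(1-q)(1-f)`, `q² + fq(1-q)`); `f = 0` is exact
  equilibrium and `f = 1` removes heterozygotes, giving the HWE filter a
  planted positive.

What the generators do **not** emulate: read-level error profiles
(homopolymer miscalls are the leading cause of missed indels on
semiconductor sequencers), haplotype linkage structure, annotation
disagreement between tool versions, and the long tail of rare consequence
combinations in real annotation output. Passing tests therefore
demonstrate the correctness of the computation under the stated
statistical model, not the field accuracy of an assay.

## Bundled reference data

`hlh_validation_set()` encodes a 13-sample validation experiment — 18
known disease-causing mutations plus 56 exonic polymorphisms as the truth
set, two of which (a homozygous `RAB27A` indel in a homopolymer stretch
and one polymorphism) are absent from the call set — yielding sensitivity
72/74 = 97.3 % with Wilson bounds as above. The polymorphism records are
synthetic placeholders; only their count enters the computation.
`hlh_example_cohort()` encodes a 58-patient worked cohort whose genotypes,
structural alleles, ages and triggers exercise every diagnostic route
(homozygous, compound-heterozygous, hemizygous, deletion-by-coverage,
external allele, monoallelic VUS); its headline numbers — 22/58 diagnosed
(38 %), 13/20 in infants (65 %), 9/37 in older patients (24 %), 22/50
pediatric (44 %), 9/36 undiagnosed patients with a monoallelic VUS (25 %),
trigger-enrichment Fisher p = 0.002 — are recomputed, never stored, by the
test suite and by `scripts/acceptance.R`.

## Numerical and design choices

* Internal coordinates are 0-based half-open (BED); VCF positions are
  converted on ingest. X-chromosome calls in samples of unknown sex keep
  their diploid zygosity and are flagged, never auto-promoted to
  hemizygous.
* The exact HWE p-value is computed in log space (`lgamma`) and compares
  probabilities with a `1 + 1e-12` slack so ties at the observed
  configuration are included deterministically; Fisher uses the
  conventional `1 + 1e-7` slack.
* Monomorphic sites return HWE p = 1; an all-zero 2×2 table returns
  Fisher p = 1; two identical multisets return rank-sum p = 1.
* The command-line surface is the R API itself plus the reproduction
  script: the package's users drive analyses from R (or `Rscript` one-liners
  over `run_pipeline()`), so no separate subcommand binary is shipped.
* Test problem sizes are chosen to keep the default suite fast while
  leaving the statistical checks well-powered: exhaustive oracle grids up
  to 20 individuals (HWE) and a few hundred random tables (Fisher), 20
  seeded cohorts for the deletion-caller recall/false-positive guarantee,
  cohorts of 25–58 patients for classification recovery, and 10,000
  individuals for population-proportion checks.

## Known limitations

Heterozygous (single-copy) deletions are out of scope by design, as is
breakpoint estimation; a deletion confined to one amplicon surfaces only
in the unconfirmed tier. Compound-heterozygous phase is presumed, not
proven, without parental data. The consequence vocabulary maps the common
annotation dialects but cannot anticipate every tool's terms; unknown
terms are retained and flagged rather than dropped. The carrier-burden
module reports raw and Bonferroni-adjusted p-values but no calibration
against annotation-version drift, which in real reference cohorts moves
counts more than sampling noise does.
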