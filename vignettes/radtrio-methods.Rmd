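---
title: "Methods: trio DNM calling and radiation mutagenesis statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio DNM calling and radiation mutagenesis statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radtrio)
```

# Scope and model

`radtrio` quantifies germline *de novo* mutations (DNMs) in mouse
parent–offspring trios, comparing offspring conceived before and after one
parent's exposure to ionizing radiation. The analysis chain is:

1. an **effective whole-genome coverage (EWC)** mask — the positions where
   every sample in the study is reliably sequenced — whose size is the
   denominator of every rate;
2. a **trio VAF filter** calling DNM candidates, with parent-of-origin
   phasing through strain-informative polymorphisms;
3. **indel classification** by tandem-repeat context (with exclusion of
   error-prone long runs) and breakpoint microhomology in deletions;
4. **multisite clustering** of alterations sharing a haplotype within
   100 bp, counted as single mutational events;
5. **rate and aging statistics**: exact Poisson rate CIs, a linear
   parental-aging adjustment, two-tailed Monte-Carlo Poisson tests of
   before/after differences, and genome-wide extrapolation.

The statistical model treats the DNM count of a group as Poisson over
`n × G` nucleotides, `G = 2 ×` EWC size (each offspring contributes a
diploid genome). Parental aging is assumed to add mutations *linearly* with
the age of each parent at conception, as a fraction of the baseline count
per week; radiation effects are whatever excess remains after that
subtraction. Both assumptions are inherited from the trio-sequencing
literature and are the ones a before/after design can actually identify.

# Callable-region construction

A sample's **peak coverage** is the mode of its high-mapping-quality depth
histogram over depths ≥ 1. Two numerical choices make this deterministic:
depth 0 is excluded (uncovered positions say nothing about typical
coverage), and ties break toward the *lower* depth. No smoothing is applied
to the histogram before locating the mode. The peak is computed per sample
from all autosomal positions pooled across chromosomes — one bound pair per
sample, not per chromosome.

A position enters the sample mask iff

* `0.5 × peak ≤ hq_depth ≤ 3.0 × peak` (`lower_frac`, `upper_frac` in
  `ewc_params()`), and
* `hq_depth / total_depth ≥ 0.8` (`min_mq_ratio`), with total-depth-0
  positions excluded before the ratio test to avoid 0/0.

The EWC mask is the interval intersection of all sample masks. Masks are
0-based half-open (BED convention) internally; variant positions are
1-based (VCF convention); `in_mask()` converts explicitly. The interval
algebra is delegated to IRanges and is tested against a position-wise
boolean oracle, together with idempotence, commutativity, and monotonicity
in `lower_frac`.

# Trio DNM filter

A candidate passes iff VAF < 0.1 in *both* parents, VAF ≥ 0.25 in the
offspring, all three samples meet a depth floor, and the position is inside
the EWC mask. Choices worth noting:

* **VAFs use high-quality read counts** — the same reads that built the
  depth tracks — since calling is restricted to high-MQ, high-base-quality
  evidence.
* **Depth floors default to 10 reads** per sample. The EWC criteria already
  imply adequate depth at realistic coverage; the explicit floor keeps
  behaviour predictable on toy-scale inputs where the band around a low
  peak can admit thin positions.
* **Indels are assumed left-aligned** (anchored VCF style) so repeat
  annotation is well-defined; multi-allelic records must be split upstream.
* Rejected candidates are returned with machine-readable reasons
  (`outside-mask`, `low-depth`, `child-vaf`, `parent-vaf`) rather than being
  silently dropped — the replacement for manual inspection of a genome
  browser.

**Phasing.** Informative sites are variants homozygous-alternate in exactly
one parent (VAF ≥ 0.9 vs ≤ 0.1). A DNM is assigned to a parent when it
shares a read-backed haplotype tag with at least one informative site within
`max_distance` (default 500 bp, read-pair scale) and all linked sites agree;
disagreement yields `undetermined` with a conflict flag. Absence of evidence
is a valid outcome, not an error — in real data only a minority of SNVs are
phaseable.

# Indel classification

`annotate_repeat()` finds the smallest sequence unit (lengths 1–6 searched;
longer units are vanishingly rare at this indel scale) that tiles the
inserted/deleted sequence, and counts its tandem copies in the reference
spanning and flanking the locus. An indel is a *repeat indel* iff that copy
number is ≥ 2, i.e. the locus had more than one unit before the event.
Copy counting is reference-based for insertions too; `unit_count` is floored
at 1 so the non-repeat class is well-defined.

The exclusion rule drops indels in mononucleotide runs > 7 units,
dinucleotide runs > 4, and ≥ trinucleotide runs > 2 (`repeat_exclusion_params()`),
as such calls are dominated by polymerase slippage artifacts. The predicate
is property-tested against exhaustive enumeration over unit lengths 1–4 ×
counts 1–10.

`detect_microhomology()` marks a deletion as microhomologous iff it is
≥ 3 nt long and at least the first two deleted bases equal the start of the
downstream flank *or* the last two deleted bases equal the end of the
upstream flank. Both ends are tested and either qualifies:
breakpoint-junction homology is orientation-symmetric once alleles are
normalized. The reported length is the longest match, capped at
`min(4, deletion length − 1)` — a full-length match would make the locus a
tandem repeat, which is classified (and possibly excluded) as such instead.
Repeat and microhomology classes are therefore mutually exclusive, with
repeat classification taking precedence.

# Multisite mutations

Two alterations in the same offspring and chromosome are linked iff they lie
≤ 100 bp apart *and* carry compatible haplotype evidence: identical phase
tags, or identical determined parental origin when tags are absent. Clusters
are connected components of this relation (single-linkage), so a chain can
span more than 100 bp end-to-end; the window is pairwise by definition, and
in realistic data almost all members sit within 15 bp, making the
distinction inert. Each cluster counts as **one** mutation, removed from the
SNV/indel tallies. Repeat-excluded indels are removed *before* clustering.

For spectrum analysis, substitutions are collapsed to the pyrimidine strand
into seven categories (C>A, C>G, C>T at CpG, C>T at non-CpG, T>A, T>C,
T>G); a multisite contributes the substitutions of its SNV members — the
minimal set of changes describing the event, with indel members contributing
none. Spectra are compared with a global Fisher exact test on the 2 × 7
table first, then per-category 2 × 2 Fisher tests, Bonferroni-corrected by
the seven categories. Adjacent substituted dinucleotides are checked against
the GC>AA / GA>TT signatures of error-prone translesion polymerases (on
either strand), which distinguish polymerase artifacts from radiation-type
clustered damage.

# Statistics

* **Rate:** μ = m/(nG) with the exact Poisson (Garwood, chi-square
  inversion) interval rescaled by 1/(nG) — the convention behind R's
  `poisson.test`, defined at m = 0. Simulated coverage stays ≥ 93% in the
  test suite (2,000 replicates at a realistic λ).
* **Aging:** `aging_model()` defaults to 4.5%/week paternal and 2.3%/week
  maternal additions beyond an 8-week reference — the phased-count
  estimates for laboratory mice; a cross-estimate from two rate studies
  ((μ₂/μ₁ − 1)/Δweeks) gives 8.75%/week combined, supporting the same
  magnitude. The same fractions are reused for indels (their SNV-relative
  abundance is approximately age-invariant); multisite counts are never
  age-adjusted (no detectable aging effect on clustered mutations). Age
  offsets (Δweeks per parent) are explicit configuration, not inferred:
  published age-adjusted counts depend on exact mating schedules, so
  hard-coding a guess would silently disagree.
* **Before/after test:** two-tailed Monte-Carlo with pairs drawn i.i.d.
  Poisson at the pooled mean (m₁+m₂)/2 and p = P(|X−Y| ≥ |m₁−m₂|), 100,000
  replicates by default, explicit seed. The closed-form Skellam two-tail
  (`skellam_two_tail()`) is the analytic cross-check; the simulation is kept
  as the primary route because the aging-uncertainty variant has no closed
  form. With aging uncertainty, the raw post-exposure count is modelled as
  Poisson including the aging addition, and the subtracted aging estimate is
  re-drawn per replicate (per-parent Poisson components, equivalent to a
  binomially split total), which widens the null appropriately. A
  "two-fold aging" sensitivity analysis is expressed by doubling both weekly
  rates in the model.
* **Extrapolation:** counts scale genome-wide by 1/(n × `ewc_fraction`),
  default fraction 0.539. The CI is the exact Poisson interval rescaled
  identically; a simulation interval (1,000 Poisson re-draws) is available
  for cases where aging uncertainty must be folded in.
* **Regional distribution:** Pearson chi-square of observed counts against
  expectations proportional to each region class's share of the EWC region.

# The synthetic cohort generator

`simulation_config()` fixes the study conditions: six offspring per group,
spontaneous rates 4.0 × 10⁻⁹ (SNV), 3.9 × 10⁻¹⁰ (indel) and ≈ 6.5 × 10⁻¹¹
(multisite; two clusters per twelve offspring over a 2 × 1.29 × 10⁹ nt
diploid callable genome) per nt per generation, parental ages 8 weeks
(before) and 26/17 weeks paternal/maternal (after), and a post-exposure
signature of ~5 induced deletions and ~1.7 induced multisites per offspring
— the approximate age-adjusted per-offspring excesses a 4 Gy exposure
produces. Within induced deletions, 45% are single-nt deletions in
mononucleotide runs (run length 2 most common) and the rest are non-repeat
deletions of 1–35 nt, of which 60% of those ≥ 3 nt carry 2–4 nt junction
microhomology.

Design choices:

* **Chromosome length defaults to 10⁵ bp** (two chromosomes). Per-nt rates
  stay at their biological values, so spontaneous counts are tiny at desk
  scale; tests and examples inflate the rates instead of the genome, keeping
  every run in seconds. The test suite uses 2 × 10⁴ bp cohorts with rates
  of 5 × 10⁻⁶ (SNV) and 10⁻⁶ (indel), 20-seed Poisson-law checks at
  10⁴ bp, and 200-deletion signature sets.
* **Offspring VAFs** are Beta-distributed around 0.5 (concentration 40) and
  parental noise reads are Binomial at VAF 0.002, so both sides of the
  0.1/0.25 thresholds are exercised.
* **Depth** is negative-binomial (mean 40, size 8) smoothed over 100 bp
  windows, with planted low-coverage, high-coverage, and low-MQ artifact
  segments totalling a few percent per sample — enough to give the EWC mask
  real boundaries without hollowing out the intersection.
* **Signature loci are engineered, not merely sampled.** A planted
  microhomology deletion has its junction homology written into the locus;
  a planted non-signature deletion is rejection-sampled until the classifier
  finds *no* homology; both reject repeat contexts. The planted fraction is
  therefore exactly the binomial parameter the classifier should recover —
  without this, chance 2-nt matches (~1/8 of random junctions) would bias
  the recovered fraction upward of the nominal one.
* **Strain markers** are placed at 1 per 200 bp; read-backed phasing is
  emulated with block-local haplotype tags (500 bp blocks, labels randomly
  permuted per block so the tag itself carries no parental information).
  Marker density and block size control how much of the cohort is phaseable.
* **One father and one mother are shared** by the before and after groups
  (the maternal-exposure design; a paternal-exposure study may use a second
  dam, which changes nothing downstream since all rates are per-offspring).

What the generator does **not** emulate: read-level artifacts (no
FASTQ/BAM), sequencing error beyond flat parental noise, mapping ambiguity
beyond the low-MQ depth segments, real mm10 coordinates or chromatin
context, indel VAF biases, and the substitution-spectrum shift inside
induced multisites. Passing tests therefore demonstrate that the *pipeline
logic* is correct under the stated statistical model — not that the filter
thresholds are optimal for any particular sequencing platform.

# Degenerate inputs and tie-breaks

* All-zero depth histograms are an error ("no covered positions").
* Mask intersection of an empty list is an error; a single mask is returned
  unchanged.
* A variant outside the mask is a recorded rejection, not an error.
* `aging_rate_from_phased_counts()` refuses zero baseline counts and zero
  age windows; age-adjusted counts may legitimately be negative and are
  returned as-is with a warning.
* `poisson_difference_test(m, m)` returns p = 1; every stochastic routine
  takes an explicit seed and records `reps` in its result.

# Known limitations

* The per-base depth representation is dense vectors, appropriate up to a
  few 10⁷ bp; genome-scale data would need run-length or bigWig-backed
  tracks.
* Phasing uses table-level haplotype tags; the package does not itself
  phase from reads.
* Only bi-allelic records are handled; splitting multi-allelics is the
  caller's job.
* Copy number on the alternate haplotype is not consulted for insertion
  repeat annotation (reference-based counting only).
* Indels > 40 nt and CNVs are out of scope, as is variant calling itself —
  the package starts from a joint genotype table.
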