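---
title: "Models and methods behind coldmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coldmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldmap)
```

`coldmap` analyses cold-tolerance phenotypes on structured panels of inbred
rice accessions genotyped with multi-allelic SSR markers. This vignette
documents the statistical models, the tunable parameters, the design choices
made where the methodology was genuinely open, and what the package's
simulation-based tests do and do not demonstrate about real data.

## The data model

Three tibbles carry everything:

* a **genotype panel** — one row per accession, one column per marker, each
  cell a single allele label (`M003_102`: marker plus PCR fragment size) or
  missing. Accessions are fully homozygous inbreds, so one label per cell
  suffices and each accession is one known-phase haplotype;
* a **marker map** — marker, chromosome, 1-based bp position;
* a **phenotype table** — accession, subspecies, and four percent-scale
  measures: seedling survival after cold at germination (`SSvR`), and three
  booting-stage seed-setting rates (`SStR_NL` under natural low temperature,
  `SStR_CW` under cold-water irrigation, `RSStR_CW` the cold-water rate
  relative to normal conditions).

## Per-marker association: one-way GLM within subspecies

Population structure in such panels is dominated by the indica/japonica
split, and that split itself carries most of the phenotypic contrast, so all
scans run **within** subspecies; the split is the structure control. For a
marker with k genotype classes among N scored accessions of one subspecies,
the fixed-effect model is a one-way ANOVA:

* SS_model = Σ n_i (x̄_i − x̄)², SS_E = ΣΣ (x_ij − x̄_i)²,
* F = [SS_model/(k−1)] / [SS_E/(N−k)], p from F(k−1, N−k),
* CPV (contribution to phenotypic variation) = SS_model/SS_total.

Genotype classes with fewer than `min_class_size` accessions (default 5) are
**dropped, not merged**: a merged class has no allele identity, and allele
identity is the unit the breeding screens select on. The residual mean
square MS_E and the per-class means are retained because the genotypic-effect
step consumes them. An exactly constant phenotype within classes is reported
as F = 0, p = 1; a perfect between-class separation (zero residual SS at
floating-point resolution) as p = 0 with a warning.

An optional structure-covariate path (partial F-test of the marker added to
a Q matrix) was considered and deliberately omitted: within a subspecies the
residual structure of such panels is weak, and the package's scope is the
subspecies-split design.

## The sequential significance adjustment

Scans are filtered by a step-down rule applied per (subspecies, measure):
sort the p-values ascending and compare the j-th smallest with
α(1−α)^R, where R is the number of hypotheses already rejected (α = 0.05:
thresholds 0.05, 0.0475, 0.045125, ...); stop at the first failure. Ties are
broken by marker name so reruns are deterministic.

An operating characteristic worth stating plainly: the first comparison uses
the raw α, so with m null tests the probability of at least one rejection is
1 − (1 − α)^m ≈ 1 for m = 100 — the rule does **not** control family-wise
error in the strong sense. What it does control is the expected fraction of
hypotheses rejected per scan, which simulation places near 0.042 at α = 0.05
under a 100-test global null (the shrinking thresholds stop the step-down
quickly once the sorted p-values cross them). The acceptance checks assert
that property; treat individual borderline calls accordingly.

Surviving markers are named `q` + `LT` + measure tag + chromosome + ordinal
by position (e.g. `qLTSSvR6-2`), with ordinals shared across subspecies so a
QTL detected in both carries one name.

## Relative genotypic effects

For genotype class i in subspecies s:

* RGE_si = (x̄_si − x̄_s) / x̄_s — the class's effect as a fraction of the
  subspecies mean, so RGE = −0.6 is a 60% seed-setting reduction;
* MS_RGE = (MS_E / n_i) / x̄_s² — the sampling variance of RGE built from
  the marker's error mean square;
* z = RGE / √MS_RGE, two-sided normal p; positive/negative classification at
  α = 0.05 (the z-test is used throughout, never a small-sample t: MS_E is
  estimated on N − k degrees of freedom, large in practice).

RGE is computed only for markers surviving the adjustment ("for each QTL");
`all_markers = TRUE` opens it up for exploration. Two analytical notes:

* RGE is scale-free — multiplying the phenotype by any positive constant
  leaves RGE and z unchanged (tested as a property);
* MS_RGE uses Var(x̄_si) = MS_E/n_i, ignoring the negative covariance between
  the class mean and the subspecies mean it is compared against. The z-test
  is therefore conservative, increasingly so for markers with few classes:
  simulated size at nominal 0.05 is ≈ 0.008 for a biallelic marker but
  ≈ 0.04 for a 10-allele marker. The package's null simulations use
  10-class markers, the many-allele regime typical of SSR loci in diversity
  panels, where the test operates close to its nominal level.

Parameter-recovery simulations plant a shift δ on designated classes and
compare the mean estimated RGE against δ/x̄_s, within 2·√MS_RGE. The
recovery design uses 600 accessions, classes of 24 carriers, and six planted
markers per replicate: with a single class the comparison band (2σ against a
≈1σ estimator) has intrinsic coverage below 95%, while averaging over the
planted classes of a replicate makes the check sharp. A small downward bias
is expected and tolerated — the subspecies mean itself absorbs part of each
planted shift (a factor 1 − n_i/N).

## Multi-allelic linkage disequilibrium

Inbred accessions are haplotypes, so haplotype frequencies are direct counts
— no EM phasing. For markers A, B and allele pair (a, b):
D_ab = p_ab − p_a p_b, r²_ab = D_ab²/(p_a(1−p_a) p_b(1−p_b)), and the
marker-level statistic is the frequency-weighted average
r² = Σ_ab p_a p_b r²_ab — the convention of standard association-mapping
software. For biallelic markers this collapses algebraically to the
classical r² (Σ_a 1/(1−p_a) = 1/(p(1−p)) for two alleles), which the tests
assert to machine precision. Missing cells are deleted pairwise; pairs
monomorphic after deletion are skipped and counted.

Distances are binned half-open at 50/150/500/1000 kb. The prose convention
"less than 50 kb" / "between 50 and 150 kb" leaves boundary membership
open; half-open-left is used and a pair at exactly 50 000 bp falls in
[50, 150). Inter-chromosomal pairs are excluded from distance bins but
**included** in the genome-wide summary row — whether genome-wide LD should
include such pairs is a convention choice, and this one is documented rather
than hidden. Under independence the sample r² has expectation ≈ 1/(n−1);
with 174 accessions that is 0.0058, and the simulator reproduces it to well
under a percent of itself.

The Evanno ΔK helper post-processes externally supplied STRUCTURE LnP(D)
replicates: ΔK(K) = |mean L(K+1) − 2 mean L(K) + mean L(K−1)| / sd(L(K)),
with replicate means in the second difference and the n−1-denominator SD
over replicates at K. A linear LnP(D) profile gives ΔK ≈ 0; a knee yields a
sharp maximum at the true cluster count. Zero replicate SD flags ΔK as
undefined rather than dividing by zero. Bayesian clustering itself is out of
scope — subpopulation labels are an input.

## Breeding screens

The pyramiding screen counts, for every accession in the panel, how many
**positive genotype labels** from a reference subspecies' discovery set it
carries. Genotype identity is the full allele label; a different fragment
size at the same marker never counts, and a missing cell contributes zero.
Phenotype-by-count summaries merge count classes with fewer than 3
accessions into the nearest count (sparsest class first, from the tail;
distance ties toward the smaller count) so class means stay stable; plots
show both raw boxplots and class means. Accessions carrying any negative
genotype with RGE ≤ −0.5 (default) are flagged — these are the lines whose
favourable alleles elsewhere can be silently cancelled in marker-assisted
selection. Top-k tables (k = 5 by default) rank by measure value with
lexicographic accession-id tie-breaks and report genotype presence/absence
plus two booleans: carries ≥ 1 positive genotype, carries 0 strong
negatives.

## The simulator

The generator is first-class, tested code: it defines the conditions every
power and recovery claim is made under.

* **Structure.** Accessions split deterministically into two subpopulations
  (defaults 109 + 65 of 174, the indica/japonica proportions of a rice
  mini-core panel). Each marker draws an ancestral frequency vector from a
  symmetric Dirichlet; each subpopulation draws its frequencies from
  Dirichlet(divergence × k × ancestral) — a Balding–Nichols-style model
  where `divergence` → 0 fixes private alleles and large values remove
  structure. The default 1.5 produces indica/japonica-scale differentiation
  (F_ST ≈ 0.4 at k = 5, but roughly double that in realized frequency
  contrasts because both subpopulations diverge from the common ancestor).
* **LD.** Positions are uniform per chromosome (rice-like chromosome
  lengths), sorted; a marker within `ld_block_span` (default 150 kb) of its
  left neighbour copies the neighbour's allele index per accession with
  probability 1 − `ld_mutation` (default 0.1). Chained copying yields r²
  decaying roughly as (1 − mutation)^(2·steps), hence with distance. This is
  deliberately a copy-with-mutation chain, not a coalescent: simple,
  controllable decay with no mutation-model realism.
* **Phenotypes.** measure = subpopulation baseline + Σ planted allele
  effects (restricted to each effect's subspecies scope) + Gaussian noise,
  clamped to [0, 100]. Baselines and noise SDs default to the magnitudes of
  published indica/japonica screens (indica SSvR ≈ 23%, japonica ≈ 79%;
  booting-stage means below 30% with CVs near or above 100%). `RSStR_CW` is
  formed as 100·SStR_CW / SStR_N with SStR_N ≈ N(85, 10) simulated
  normal-condition seed set, which reproduces the strong observed
  correlation (r ≈ 0.9) between cold-water and relative seed set.
  Clamping (rather than truncated-normal resampling) matches the bounded
  ranges of percent data and keeps planted effects exactly additive in the
  interior; near the boundaries realized subgroup means shift slightly
  toward the interior, which the calibration tests allow for.
* **Determinism.** One integer seed drives a single RNG stream; identical
  configs give bit-identical outputs, which the pipeline's md5 manifest
  makes checkable end to end.

What the simulator does **not** emulate: SSR repeat-count mutation dynamics,
selection, admixed individuals, genotyping error, shared environments or
multi-environment G×E. Passing tests therefore demonstrate correctness of
the statistics under a clean two-population model with additive allele
effects — they do not certify behaviour under admixture or strong
within-subspecies substructure.

## Problem sizes used in the checks

The packaged checks run at deliberately modest scale, chosen as the smallest
sizes at which each property is sharply testable: 100-instance oracle
comparisons for the GLM; 2000 replicate scans of 100 tests for the null
behaviour of the sequential rule; 50 replicates of the 600-accession
recovery design and 2000 null replicates of the 200-accession, 10-class
z-test size check; 60–150-marker panels for LD (null level across three
independent panels, decay across three seeded block simulations); ten seeded
174-accession screens for the pyramiding trend contrast; and 50 replicate
120-accession scans for the planted-QTL power check (run as a single
unstructured population — allele frequencies follow the ancestral draw — so
power reflects the test, not the segregation lottery of a structured draw).
`scripts/acceptance.R` recomputes all of these from scratch under a single
`--seed`.

## Known limitations

* The sequential rule's lack of strong FWER control is inherent to its
  formula; users wanting strict control should filter the scan records with
  `p.adjust` methods instead — the records carry everything needed.
* CPV from a one-way fit is upwardly biased for small classes and many
  alleles; compare markers at similar k.
* The z classification ignores the class-vs-mean covariance (conservative,
  see above) and multiple testing across classes of called QTLs is not
  additionally corrected, matching standard practice for this screen.
* Count-class merging in the pyramiding summaries is a display stabiliser,
  not an inferential step; trend tests in the package use the unmerged
  per-accession counts.
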