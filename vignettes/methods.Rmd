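---
title: "Methods: competitive gene-set analysis for allograft rejection and downstream drug screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: competitive gene-set analysis for allograft rejection and downstream drug screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftgsa)
```

## The statistical model

`graftgsa` tests predefined gene-sets for coordinated association with a
transplant-rejection phenotype, competitively: a set is interesting only if
its members score higher *as a group* than comparable random collections of
genes, and higher than the same set under a phenotype-permutation null.

**Gene scores.** In two-class mode each gene gets the pooled-variance
two-sample t-statistic between the two phenotype groups (e.g. acute
rejection vs stable), signed positive when the upper group is higher. In
quantitative (ordinal) mode each gene gets the t-statistic of the slope
from simple linear regression of expression on the integer rank of its
sample's group in the declared severity order (D0 < STA < BL < ARIA <
ARIB, coded 0–4, equally spaced). With a binary 0/1 code the regression t
is algebraically the two-class pooled t, and the package tests that
identity to 1e-10. An optional additive offset `s0` on the denominator
(default 0) is available for variance regularisation.

*Zero-variance rule.* A gene whose denominator is exactly zero scores 0
and is logged, rather than ±Inf: a constant gene carries no ordering
information, and finite scores are an invariant of every downstream step.
This also covers the degenerate perfectly-linear gene in ordinal mode.

**Set statistic.** For member scores $z$ the raw maxmean statistic is
$s_S = \max\{\mathrm{mean}(\max(z,0)),\ \mathrm{mean}(\max(-z,0))\}$, the
larger of the mean positive and mean negative parts, with the winning side
giving the direction (ties go positive). It is sensitive to one-sided
shifts carried by a subset of members, which is the behaviour wanted for
partially activated pathways.

**Restandardization.** The signed statistic is centred and scaled by the
empirical mean and SD of the same signed statistic over `n_randomization_draws`
(default 1000) random gene subsets of the same size drawn from the scored
genes — the "unusual compared to random sets of the same size" half of the
test. Moments are estimated once per distinct set size per score-vector
context and applied identically to observed and permuted statistics, each
computed from its own score vector. When the randomization SD is zero
(constant scores, or a subset as large as the gene pool) the statistic is
centred only, and the fallback is flagged.

**Permutation null, p, FDR.** Phenotype labels (two-class) or ordinal
codes (quantitative) are permuted over samples `n_permutations` times
(default 1000, the screening configuration). When the number of distinct
arrangements is at most the budget, all are enumerated exhaustively — for
a 4 vs 4 design that is all 70 assignments — and the package's p-values
then agree *exactly* with brute-force enumeration, which the test suite
verifies against an independent oracle. Per set, the attained two-sided p
is the fraction of its permuted $|s^*|$ at or above the observed value; a
count of zero is reported numerically as 0 and labelled `< 1/B`. The
plug-in FDR at each observed threshold $t$ is the median over permutations
of the number of null statistics (all sets) at or above $t$, divided by
the number of observed statistics at or above $t$, capped at 1 and forced
monotone non-increasing in $t$. Sets are called at FDR ≤ 0.5 by default —
deliberately permissive, as appropriate for a discovery screen that is
followed by replication and wet-lab validation, not for confirmatory
claims.

## Design choices where the method was genuinely open

* **Two-sided p and FDR, direction reported separately.** Set-level
  inference is on $|s^*|$; the enrichment direction is a separate column.
* **Direction-aware replication.** Cross-dataset replication
  (`replicate_across_datasets()`) by default requires *positive*
  enrichment at the FDR threshold in both cohorts, because replication of
  a rejection signature means enrichment in rejection in both datasets.
  There is also a methodological reason: when one strong enriched set is
  present, the restandardization baseline (mean over random sets) shifts
  upward, so unrelated sets drift toward negative scores *coherently in
  both cohorts*; under a two-sided rule at a permissive cutoff these
  artifactual depletions would co-replicate. Requiring the disease
  direction removes exactly that artifact; `direction = "any"` or
  `"match"` restores the unrestricted behaviour.
* **Canonical sample order.** `run_gsa()` sorts samples by id before any
  random draw, making results bit-identical under input column
  reordering with the same seed.
* **RNG policy.** One seed per run; the observed score-vector context
  consumes the stream first, then each permutation in order; within a
  context, randomization moments are computed in increasing set-size
  order. This is documented so that external re-implementations can
  reproduce results draw for draw.
* **Minimum overlap 5.** Sets overlapping fewer than 5 scored genes are
  excluded with a reason (maxmean on 1–2 genes is degenerate); every input
  set is accounted for, scored or excluded.
* **Unpaired analysis.** Although pre/post-transplant biopsies can be
  patient-paired, the analysis treats samples as unpaired; pairing enters
  the qPCR module only (paired t-test when declared).
* **Probe collapse.** One probe per gene symbol by minimum SEM
  (sd/√n, n−1 denominator) across declared reference samples, ties broken
  lexicographically by probe id. An optional `keep_discordant` branch
  retains both probes when two reference subsets disagree on the winner;
  it is off by default because the dual-retention rule is ambiguous in
  common practice.
* **Curation thresholds.** Fold change is linear-scale and non-strict
  (≥ 2); p is strict (< 0.05); both configurable. Membership is
  deduplicated and monotone in the thresholds by construction.
* **Drug filters.** "Direct inhibition" is modelled as two independent
  record fields (`mechanism`, `direct`), both required by default. The
  target count uses only the disease input genes, and by default counts
  only interactions meeting the mechanism/direct constraint
  (`count_requires_mechanism = FALSE` gives the looser reading). The
  required-gene rule (IL17A by default) applies under the same constraint.
* **ΔΔCt.** Amplification efficiency fixed at 2; replicates are averaged
  on the Ct scale before ΔCt; fold changes are reported as magnitude ≥ 1
  plus direction; the group test is a pooled-variance unpaired t by
  default and paired when declared.

## What the synthetic data emulates — and what it does not

`simulate_expression()` generates
`baseline_g + effect_g(group_s) + N(0, noise_sd)` on the log2 scale:
per-gene baselines from N(8, 1.5), unit noise SD, cohort sizes defaulting
to the 33/16/4/7/6 ordinal design of a realistic discovery cohort, planted
sets carrying either a group shift of `delta` noise-SDs (default 0.5) in
the designated upper groups or an ordinal trend of `beta` noise-SDs per
severity step (default 0.25), each on a configurable fraction of members
(default 60%, emulating partial pathway activation), and null sets drawn
from unaffected genes. Interaction tables plant a chosen number of
compounds satisfying all repositioning filters among decoys that each
violate exactly one filter, plus background compounds that can never reach
the target count. Ct tables plant true relative-expression values that the
ΔΔCt pipeline recovers exactly at zero noise.

The generators deliberately do **not** emulate probe-level array
artifacts, batch effects, gene–gene correlation, or heavy-tailed noise.
Passing tests therefore demonstrate the correctness and calibration of the
statistical machinery under its stated model, not robustness to every
failure mode of real microarray data; in particular, inter-gene
correlation in real data widens the permutation null and the same
thresholds will be more conservative there.

## Numerical and degenerate-input behaviour

Missing values are tolerated at parse time and must be removed by
`filter_complete_genes()` (the only-complete-genes rule) before any
statistic; `run_gsa()` refuses matrices with missing entries. Negative
residual variances from floating-point cancellation are clamped at zero.
Ragged files, duplicate sample ids, duplicate set or compound ids, empty
gene-sets, constant phenotypes, and zero-norm samples under cosine
dissimilarity are hard errors that name the offender. Ties: maxmean
direction goes positive; probe collapse and candidate ranking break ties
lexicographically; clustering inherits `stats::hclust` determinism.

## Problem sizes used in the shipped checks

The packaged property checks run the screen at 2000 genes with 100
competing sets: a pure-null calibration (15/15 cohort, 100 null sets of
size 20, 500 permutations) testing p-value uniformity and the FDR call
rate; 20-replicate recovery studies for a planted two-class set (50 genes,
δ = 0.5, 60% penetrance, 15/15) and a planted ordinal set (β = 0.25, 60%,
33/16/4/7/6); and 20-replicate exact-replication runs across cohorts
shaped 16/13 and 21/10. These sizes were chosen as the smallest
configuration that exercises realistic imbalance and multiplicity while
keeping a full run on one core comfortable; 500 permutations and 1000
randomization draws reproduce the default screening resolution (p to
0.002).

## Known limitations

The competitive test assumes independent genes when drawing random sets;
correlated members inflate the randomization SD less than they inflate a
correlated set's statistic, which is a known optimism of maxmean-type
tests on real pathways. The plug-in FDR with a median numerator is coarse
near rank 1 (it can be exactly 0 or jump to 0.5). The quantitative mode's
equally spaced coding treats adjacent severity grades as equidistant. The
drug module operates on whatever open interaction table it is given — its
output quality is bounded by that table's curation, and evidence ids are
carried through for manual literature checks rather than verified
automatically.
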