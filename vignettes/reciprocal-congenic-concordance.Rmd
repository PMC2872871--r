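---
title: "Concordance analysis of reciprocal congenic expression experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concordance analysis of reciprocal congenic expression experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A quantitative trait locus (QTL) on rat chromosome 4 influences alcohol
preference. Reciprocal congenic strains make it possible to isolate the
locus: the interval from the inbred alcohol-preferring (iP) strain was
introgressed onto the nonpreferring (iNP) background (strain NP.P), and the
iNP interval onto the iP background (strain P.NP). Each congenic differs
from its background strain only inside the introgressed segment, so any
reproducible expression difference must be driven by that segment — either
*cis* (the gene itself lies inside the interval) or *trans* (a regulator
inside the interval acts on a gene outside it).

`congenicDE` implements the full analysis for such paired designs: interval
classification, detection filtering, per-region and region-averaged
two-group testing with false-discovery-rate control, cross-experiment
concordance selection, a probe-level screen for SNP hybridization
artifacts, and a ground-truth simulator used to verify every stage.

## The model and procedure

Inputs are RMA-style log2 expression matrices (probe sets × arrays) with
present/absent detection calls, one array per animal per brain region
(nucleus accumbens, amygdala, frontal cortex, hippocampus, caudate
putamen). All oriented quantities follow one convention: **iP-allele
carrier minus iNP-allele carrier**, so a positive difference means higher
expression in animals carrying the preferring allele (iP background or
NP.P congenic).

The single-experiment pipeline, per locus universe (cis = inside the
introgressed interval, both bounds inclusive; trans = placed anywhere
else; unplaced probe sets are excluded from both):

1. **Detection filter.** A probe set is analyzed in a region when called
   present on at least one third of the arrays of either group in that
   region; for the region-averaged analysis, when present on at least one
   third of arrays in at least one region in at least one group.
2. **Per-region tests.** Two-group t-tests on log2 values. Three variants
   are offered: pooled-variance Student, Welch, and a moderated t that
   shrinks each probe set's pooled variance toward a common prior value.
3. **Region-averaged ("combined") test.** Each animal's five regional
   values are averaged (arithmetic mean of log2 values, i.e. geometric
   mean of linear values) and the two groups compared on the per-animal
   means. Averaging cancels extraction- and labeling-level technical
   noise and gains power for effects shared in direction across regions.
4. **FDR control.** Benjamini–Hochberg adjustment is applied separately
   per context (each region; combined) and per universe (cis; trans).
   The cis family is two orders of magnitude smaller than the trans
   family, and mixing them would let the genome-wide family dominate the
   interval hypotheses the design was built to test. The default
   significance criterion within one experiment is FDR ≤ 0.25.

**Concordance across the reciprocal experiments.** Both experiments'
ratios are first oriented to the common allele convention (iP/P.NP and
NP.P/iNP). A probe set is selected as a reproducible candidate when, in
the *same* context (one region, or the combined analysis), it reaches raw
p ≤ 0.05 in *both* experiments with the *same* direction. Raw rather than
FDR-adjusted p-values are deliberate: with two independent experiments the
chance that a null probe set passes in the same context with the same sign
is at most α² per context, so cross-experiment consistency is itself the
false-positive filter, and relaxing the per-experiment threshold reduces
false negatives in the weaker (6 vs 6) design. Direction consistency is
evaluated within the qualifying context, not globally; a probe set can
therefore be selected through one region while its region-averaged ratios
disagree in sign (the packaged candidate table contains exactly three such
cases).

Reported ratios use the signed fold-change convention: `fc = 2^d` for a
log2 difference `d`, reported as `fc` when `fc ≥ 1` and `-1/fc` otherwise,
so magnitudes are symmetric about ±1 and a ratio of −2 means two-fold
lower in iP-allele carriers. Cross-experiment reproducibility is
summarized by the squared Pearson correlation (R²) of the two log2 ratio
vectors and by the fraction of pairs agreeing in direction.

**Moderated t.** The prior is scaled-inverse-chi-square: with per-probe-set
pooled variances `s²` on `d` degrees of freedom, the log sample variances
have closed-form mean and variance involving digamma/trigamma functions;
matching moments yields the prior degrees of freedom `d0` (by trigamma
inversion of the excess variance of `log s²`) and prior variance `s0²`.
The posterior variance `(d0·s0² + d·s²)/(d0 + d)` replaces `s²` and the
statistic is referred to a t distribution on `d0 + d` degrees of freedom.
When the observed spread of log variances does not exceed its sampling
spread, the moment equations have no finite solution and the method falls
back to the Student test — which is also the exact limit `d0 → ∞` when all
sample variances are equal. The unit tests cross-check this implementation
against limma's independent empirical-Bayes code.

**Probe-level SNP screen.** A strain-specific sequence variant under one
probe can depress hybridization in one strain and mimic expression
difference. Probe intensities are region-averaged within animal exactly
like probe sets; each probe's group difference `d_p` is centered on its
probe set's overall difference (the median of `d_p`; mean centering is
available as an option) and scaled by the set's MAD (`1.4826 ×
median|residual|`). A probe is flagged when `|robust z| > 3` **and**
`|residual| ≥ 0.5` log2. Median/MAD are used because they resist the very
outlier being sought; the absolute floor prevents flagging trivial
deviations in ultra-low-variance probe sets; probe sets with fewer than 4
probes cannot support a meaningful MAD and are skipped with a warning.
The published probe-level method is described only qualitatively; this
median-centered robust-z rule is this package's own concrete formulation,
calibrated so that an injected 2.0-log2 single-probe offset is detected
with ≥ 95% sensitivity at a ≤ 1% per-probe false-flag rate (verified by
simulation in the acceptance suite).

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `min_detection` | 1/3 | fraction of arrays | detection filter threshold |
| `fdr_threshold` | 0.25 | q | single-experiment significance |
| `alpha` | 0.05 | raw p | per-experiment concordance threshold |
| `interval` | chr4:29,413,686–128,186,835 | bp, closed | introgressed segment |
| `k` | 3 | robust z | probe screen deviation threshold |
| `min_effect` | 0.5 | log2 | probe screen absolute floor |

## The synthetic-data generator

`sim_config()` / `simulate_congenic_pair()` emulate the paired study
design: experiment A with 8 animals per group and experiment B with 6 per
group (the weaker earlier design), five regions each. The generative model
for probe set *g*, animal *i*, region *r* is

```
value = baseline_g + region_offset_r + animal_i + delta_g·[iP carrier] + noise
```

with `baseline_g ~ N(8, 1.5²)`, animal effects `N(0, 0.1²)`, residual
noise `N(0, 0.2²)` (all log2), and allele effects `delta_g ~ N(0, 0.4²)`
resampled away from zero (|δ| ≥ 0.1) — or a fixed |δ| with random sign for
calibration studies. Regulated probe sets carry the *identical* δ in both
experiments, because both congenic pairs segregate the same two alleles of
each interval gene; that premise is exactly what the concordance filter
exploits. A tenth of probe sets are placed uniformly inside the interval
and the rest elsewhere in the genome. Detection calls are Bernoulli with
present-probability logistic in the realized log2 value (midpoint 6,
slope 1.5), which yields realistic absent fractions concentrated in low
expressors. The probe-level generator adds a per-probe affinity offset
(`N(0, 0.5²)`) and probe noise, and subtracts a 2.0-log2 `snp_offset`
from designated SNP probes in iNP-allele carriers only.

What the generator does *not* emulate: array normalization artifacts,
correlated (batch) noise, heavy-tailed or intensity-dependent variance,
probe saturation, and real annotation error. Passing tests therefore
demonstrate the correctness and calibration of the *procedure* under its
stated model, not the biological validity of any particular candidate list
from real arrays.

**A note on the animal random effect.** Because every probe set of an
animal shares that animal's effect, the group difference of *all* probe
sets within one experiment is shifted by a common offset (the difference
of group-mean animal effects). Each individual t-test remains exactly
calibrated — the animal variance is part of its error term — but the
significance indicators become correlated across probe sets, so the
binomial error bound used in the null-calibration checks would not apply.
Those checks therefore run the generator with `sigma_animal = 0`, making
probe sets independent; all power and recovery checks keep the default
`sigma_animal = 0.1`. On real RMA-normalized arrays a global shift of this
kind is largely removed by quantile normalization, which is out of scope
here (inputs are post-normalization matrices).

## Numerical choices and degenerate inputs

- Coordinates are 1-based and inclusive on both interval ends; a probe set
  is represented by a single anchor position. Boundary positions classify
  as cis.
- Chromosome labels are compared case-insensitively with an optional
  `chr` prefix stripped.
- A probe set constant and equal in both groups gets `p = 1` (no
  evidence); constant but unequal is an error under Welch (undefined
  degrees of freedom) while the Student statistic is still defined.
- A signed ratio of exactly ±1 encodes a zero log2 difference; it has no
  direction and is excluded from direction-agreement counts, and
  orientation flips map it to 1.
- Missing fixture cells (`ND`) are excluded pairwise from agreement and
  correlation computations.
- In the probe screen, a zero MAD with zero residuals yields no flags;
  TSV outputs are written with six significant digits so reruns are
  byte-reproducible, and all simulation output is deterministic given the
  seed.

## Problem sizes used in verification

The test and acceptance suites run at desk scale, chosen so the whole
suite completes in well under a minute while keeping Monte-Carlo error
small relative to every asserted margin: 20,000 probe sets for null
calibration (3-binomial-SD bands at α = 0.01 and 0.05), 400 probe sets ×
(8v8 and 6v6) for recall monotonicity at |δ| ∈ {0.1, 0.3, 0.6}, and
500 + 500 eleven-probe sets for the SNP-screen operating characteristics.

## Known limitations

- The published raw-data counts (e.g. per-region significant probe-set
  totals) depend on the original array data and are not reproduced here;
  the packaged fixtures encode the published candidate and confirmation
  tables, and all other verification is property-based on synthetic data.
- The moderated-t prior estimation is this package's moment-matched
  formulation; p-values from other empirical-Bayes implementations can
  differ in distant decimals.
- The concordance selection treats the two experiments as exchangeable
  evidence; it does not model the different group sizes beyond their
  effect on the per-experiment p-values.
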