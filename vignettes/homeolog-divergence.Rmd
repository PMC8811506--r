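---
title: "Methods: homeolog expression and sequence divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homeolog expression and sequence divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeologdiv)
```

# Scope and model

After an allotetraploidization event the polyploid carries two subgenomes,
L and S; each diploid-reference gene can survive as a homeolog pair, a
singleton, or be lost. `homeologdiv` measures three things about a gene
family in such a genome:

* **retention accounting** over a catalog of gene family members
  (presence flags per genome, identity, per-copy dN/dS, expression
  categories);
* **expression divergence** between the copies of each homeolog pair,
  classified per replicate clutch and reconciled across clutches;
* **protein-coding divergence** of each copy against the diploid reference,
  summarized as the dN/dS ratio ω, with a strict ω > 1 screen for
  candidates of positive selection or relaxation.

The catalog module is pure counting and needs no statistical assumptions.
The two analysis modules and the simulators are described below, with the
decisions that were genuinely open and why they were settled as they are.

# Expression classification

## Procedure

For one homeolog pair in one clutch, with TPM profiles over an ordered
sample set, the pipeline order is fixed:

1. **Floor.** All TPM values ≤ 0.5 become exactly 0. TPM at or below this
   level is treated as irreproducible noise rather than signal. The floor is
   applied on the TPM scale *before* the log transform — flooring
   log-transformed values would retain log2(1.5) ≈ 0.585 for a 0.5-TPM
   observation and change every downstream statistic; a unit test pins this
   order with a discriminating fixture.
2. **Filter.** If either copy has no sample above the floor, the pair is
   `n/a` for that clutch and no test is run. The filter is deliberately
   pair-level (either copy failing drops the pair): a correlation or a
   paired comparison against an all-zero profile estimates nothing
   biologically meaningful. This one-sided-failure rule is a package
   decision and is recorded in the classification output metadata.
3. **Transform.** `log2(TPM + 1)`, mapping 0 to 0.
4. **Tests.** Pearson's correlation (two-sided, p from the
   `t = r·sqrt((n−2)/(1−r²))` transform on n − 2 df) decides HC
   (*p* ≤ α) vs NC; a paired Student *t* test (two-sided, n − 1 df)
   decides SE (*p* > α) vs DE (*p* ≤ α). Both tests run on the floored,
   transformed profiles. The default α = 0.05 for both axes, and the
   boundary *p* = α counts as significant on both axes (HC and DE).

No multiple-testing correction is applied: the per-pair label is the object
of interest, and the calibration property below checks the per-test level,
not a family-wise one.

## Degenerate inputs

* A constant transformed profile (common after heavy flooring) makes the
  Pearson coefficient undefined. The pair is classified **NC** — "high
  correlation" cannot be established from a flat profile — and the
  undefined statistic is preserved as `NA` in the output rather than being
  replaced by 0.
* Exactly collinear profiles give |r| = 1; the p-value is taken as the
  limit 0 instead of tripping numerical warnings.
* Paired differences that are identically zero give t = 0, p = 1 (SE);
  constant nonzero differences give an infinite t with p = 0 (DE). Both are
  exact limits of the statistic, not special-cased conventions.

## Reconciliation across clutches

Two biological replicate clutches (named T and U) are classified
independently. Equal labels pass through (including `n/a` + `n/a`); any
disagreement is `inc`, annotated with the axis the clutches share when
exactly one axis agrees (`inc:HC`, `inc:NC`, `inc:SE`, `inc:DE`), or
`inc:NA` when one clutch was filtered and the other classified. The
half-consistency annotation follows the convention used when such results
are reported alongside heat maps: the common component is named, the
disputed one is not. The operation is symmetric; the suite checks all 25
ordered label pairs exhaustively.

## Sample sets

Defaults are an 11-sample developmental series (egg through tadpole stage
40: `DEVELOPMENTAL_SAMPLES`) and a 14-organ adult set (`TISSUE_SAMPLES`),
both overridable. Oocyte stages are excluded from classification by
default because they lack a replicate clutch; they may be carried in
matrices for inspection but never enter the tests.

# dN/dS estimation

## Counting estimator

The estimator is a pairwise counting method in the Nei–Gojobori tradition,
with equal pathway weights and no transition/transversion or
codon-frequency weighting:

* **Sites.** For each codon position, the synonymous site fraction is the
  proportion of admissible single-base changes that preserve the amino
  acid, where changes creating a stop codon are excluded from the
  admissible set. Each position therefore contributes exactly one site and
  each codon exactly three; the suite asserts `S + N = 3 × codons` to
  1e−9 on every input. Site counts are averaged over the two sequences.
* **Differences.** For a codon pair differing at k positions, all k!
  orderings of the changes are enumerated as stepwise pathways; each step
  is classified synonymous or nonsynonymous; pathways passing through a
  stop codon are skipped and the average is renormalized over the
  admissible pathways. A pair with no admissible pathway is excluded whole
  (and counted as excluded). An independent brute-force enumerator —
  written separately, with a different genetic-code source and hard-coded
  orderings — reproduces the implementation on all 61 × 61 ordered sense
  codon pairs in the suite.
* **Correction.** Proportions pS = Sd/S and pN = Nd/N are corrected with
  the one-parameter Jukes–Cantor formula `d = −3/4·ln(1 − 4p/3)`.
  Saturation (p ≥ 0.75) yields an `NA` marker rather than an error, so a
  batch screen survives a saturated pair. ω = dN/dS, with dS = 0 < dN
  reported as infinite (it flags in the screen) and dN = dS = 0 as
  undefined (it never flags).
* **Alignment hygiene.** Codon columns containing a gap, an ambiguous
  base, or a stop in either sequence are excluded whole. A minimum of 10
  usable codons (configurable) guards against meaningless estimates;
  the guard is sized for short genes — chemokines run ~70–100 codons.

The ω > 1 screen uses strict inequality: a copy at exactly ω = 1.00 is
consistent with neutrality and is not flagged.

This estimator is deliberately simple: it supports a threshold screen and
ordering comparisons, not branch-specific inference. It is not a
maximum-likelihood codon model, and the catalog's stored ω values (computed
upstream with a branch model) are carried as data, not regenerated;
numerical equality between the two methods is not asserted anywhere.

## Catalog conventions

Printed percentages (retention rates, mean identity) are rounded half away
from zero, with the unrounded value always retained alongside. Missing
values in the catalog use a single `NA` sentinel. Identity and dN/dS may
only be present where the corresponding copies exist; the loader enforces
this, rejects duplicate gene symbols, negative dN/dS, out-of-range
percentages and unknown category labels, naming the offending row. The
category tally reports `inc` and `unlabeled` separately so that tallies
over columns containing rows with no call at all remain inspectable.

# Simulators

## Expression

`simulate_expression()` emulates the statistical structure the
classification assumes, not any particular real dataset:

* per pair, a latent log2-scale L profile drawn i.i.d. over samples from
  N(`base_mean_log2`, `base_sd_log2`²) — defaults 4 and 2, i.e. typical
  expressed genes around 16 TPM spanning a few orders of magnitude;
* an S profile built for target correlation `rho` (default 0.8) and mean
  L − S offset `offset_log2` (default 0) with the same marginal spread;
* independent per-clutch technical noise (`noise_sd_log2`, default 0.25);
* structural zeros with probability `zero_fraction` (default 0.15), drawn
  once per pair and sample and applied to both copies and both clutches.
  Sharing the zeros across clutches reflects biological absence (the
  replicate-clutch design treats presence/absence as reproducible, noise
  as clutch-level); sharing across copies additionally makes the exactness
  identity hold — a spec of `rho = 1, offset = 0, noise = 0` produces
  clutch T ≡ clutch U and L ≡ S bit-for-bit, whatever `zero_fraction`.

What it does **not** emulate: library-size effects, count noise
(mean–variance coupling), correlated samples along a developmental
trajectory, or realistic tissue-specific expression programs. Passing
recovery tests on simulated data therefore demonstrates that the
classifier recovers the structure it models, not that real clutch data are
this well behaved.

## Codon evolution

`simulate_codon_pair()` evolves a uniform-random stop-free ancestor along
two independent branches. Each branch gets Poisson(`branch_subs_expected`)
substitution attempts; each attempt proposes a uniform single-base change,
rejects stop-creating proposals outright, and accepts synonymous /
nonsynonymous proposals with probabilities (1, ω) for ω ≤ 1, or (1/ω, 1)
for ω > 1. This acceptance-ratio tuning makes the realized Nd/Sd ratio
increase monotonically with the target ω without claiming numerical
equality — adequate for ordering and screen-rate tests, and much simpler
than an exact codon-model sampler. Misuse warning: do not treat the target
ω as the true generating ω of a calibrated codon model.

Both simulators restore the caller's RNG state, so a fixed spec (seed
included) is bit-reproducible regardless of surrounding code.

# Verification design and problem sizes

The test suite pins every worked example above and adds property checks.
The simulation sizes are chosen to keep the full suite under a minute on a
single core while leaving the statistical gates well-powered:

* **calibration**: 2,000 independent same-mean pairs at n = 14 tissue
  samples (no structural zeros, high baseline so flooring never triggers —
  the null being calibrated is the tests', not the filter's); the HC and
  DE rates must sit within 3 binomial standard errors of α = 0.05;
* **recovery**: 500 pairs at `rho = 0.95, offset = 3` must classify ≥ 80%
  HCDE; these are implementation acceptance gates, not claims about real
  data;
* **ω recovery**: 50 replicates per generating ω in {0.1, 0.5, 1.0, 2.0}
  at 300 codons and 60 expected attempts per branch; mean estimated ω must
  increase strictly with the generating value, the 0.1 and 2.0
  distributions must be disjoint at the 5th/95th percentiles, and the
  strict ω > 1 screen must flag the ω = 2.0 pair in ≥ 90% and the ω = 0.1
  pair in ≤ 5% of replicates;
* **oracle equivalence**: the full 61 × 61 codon pair sweep against the
  independent enumerator.

`scripts/acceptance.R` recomputes the catalog overview statistics, the
null calibration rates and the ω recovery summary from scratch under a
caller-supplied seed and writes them as JSON.

# Known limitations

* The classification inherits the weaknesses of its tests: Pearson's
  correlation on 11–14 samples has modest power, and the paired *t* test
  assumes roughly symmetric differences on the log scale.
* The counting dN/dS estimator ignores transition/transversion bias and
  codon usage; ω values on very short or very diverged alignments are
  noisy, and saturated pairs return no estimate at all.
* The catalog module trusts its input table; it validates structure, not
  biology (e.g. it cannot detect a mistranscribed identity value).
* The `inc` half-consistency annotation records which axis agrees, not a
  quantitative measure of between-clutch disagreement.
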