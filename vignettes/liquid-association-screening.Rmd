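---
title: "Screening for age-associated gene co-expression with liquid association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for age-associated gene co-expression with liquid association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aagci)
```

## The model

Ordinary co-expression analysis asks whether two genes X and Y are correlated
across samples. This package asks a different question: does the *strength*
of their association change along a third, quantitative variable Z — here,
donor age? Liquid association formalises this. With X, Y, Z standardised to
mean 0 and variance 1, define g(z) = E(XY | Z = z); the liquid association of
the pair with respect to Z is E[g'(Z)], the average rate at which their
conditional co-expression changes as Z moves. When Z is standard normal,
Stein's lemma reduces this to E(XYZ), so the sample statistic is simply

    LAS(X, Y | Z) = (1/n) * sum_i  X_i * Y_i * Z_i .

A pair can have LAS far from zero while its marginal correlation is exactly
zero — for instance when the conditional correlation is negative in young
donors and positive in old ones. Such pairs are invisible to a Pearson
screen, which is precisely why the two screens are run side by side here.

### Why the inverse-normal transform

The Stein reduction requires standard-normal margins, so every gene's
expression profile and the scouting variable are mapped onto normal
quantiles of their rank fractions, `qnorm((rank - 0.5) / n)`, with average
ranks for ties. This offset keeps the output symmetric, zero-mean, and
finite at the extremes; a constant vector maps to all zeros. Ties map to
equal values, and because only ranks survive the transform, monotone
distortions of the raw data (library size, dynamic-range compression) have
no effect downstream. The untransformed ages are retained alongside, since
the young/middle/old diagnostic strata are defined in years.

## The screen

Testing every gene pair genome-wide is both computationally prohibitive and
statistically diffuse, so pairs are screened inside functional modules
(GO-term or pathway gene sets supplied as GMT). Modules are first
intersected with the measured genes; a module is usable when its intersected
size lies in [5, 500). The lower bound exists because per-module FDR control
over fewer than C(5,2) = 10 pairs is vacuous; the upper bound excludes
overly general terms. The bound is applied to the intersection rather than
the annotated size because screening can only ever use measured genes.

Within a module of k genes, all k(k-1)/2 pairs are scored. Significance is
assessed by permuting the scouting variable: one set of `n_perm = 100`
index orderings is drawn per run from the master seed and reused for every
pair, which makes runs reproducible, makes null scores comparable across
pairs, and costs |pairs|-fold less than fresh permutations per pair. With
only 100 permutations an empirical p-value has granularity 0.01, far too
coarse for FDR control over thousands of pairs, so a normal distribution
N(mu, sigma^2) is fitted to the permuted scores (mu the mean, sigma the
(n_perm - 1)-denominator standard deviation) and the two-tailed p-value is

    p = 1 - Phi((|LAS| - mu) / sigma) + Phi((-|LAS| - mu) / sigma),

clamped to [0, 1]. Benjamini–Hochberg adjustment is applied *within each
module* (each module is its own testing family), and a pair with adjusted p
not greater than 0.1 is a liquid-association pair (LAP). A gene appearing
in any LAP in any module is an *age co-expressed gene*; this union is taken
over all modules jointly.

### Numerical edge cases

* If sigma collapses below 1e-12 (all permuted scores identical, e.g. a
  constant scouting vector), the limit of the formula is used: p = 1 when
  |LAS| <= |mu| + 1e-12, else p = 0. Division by zero never propagates.
* The fitted mean mu enters the formula signed, exactly as written; with a
  centred permutation null mu is near zero and the choice is immaterial.
* The identity ordering is not excluded from the permutation draw; orderings
  are uniform over all n! possibilities.
* Pair enumeration, module processing order, and all tie-breaks are
  lexicographic on symbols, so a run is a pure function of (inputs, seed).

### Known calibration limitation

The normal fit is accurate near the centre of the null but slightly
anticonservative in the far tail: sigma is estimated from 100 draws (so the
effective reference is closer to a t-distribution) and the true permutation
null of a triple-product mean has positive excess kurtosis. At the 0.05
level the miscalibration is negligible (the test suite measures the null
rejection rate at ~0.05); at the p ~ 0.005 level relevant to the BH
runner-up threshold inside a 28-pair module it admits roughly twice the
nominal mass. The practical consequence, which the acceptance suite
measures rather than hides, is that a module containing one true LAP admits
a second, spurious pair more often than a perfectly calibrated p-value
would (about a quarter of planted-module replicates instead of ~10%).
Raising `n_perm` shrinks the sigma-estimation component at linear cost; the
default stays at 100 because that is the regime the method is defined in.

## The comparison, network and enrichment stages

**Pearson counterpart.** The same modules are screened with the Pearson
correlation, two-sided p from the exact t reference with n - 2 degrees of
freedom, BH within module at 0.1. Per module, the 2x2 table of LA-significant
by PCC-significant pairs is tested with the one-sided (greater) Fisher exact
test, BH-adjusted *across* modules (this stage's family is the module
collection), and called consistent at adjusted p <= 0.05. Zero-variance
genes yield undefined correlations and p = 1 rather than an error.

**Key drivers.** Given an undirected PPI network and a target set (a
module's age co-expressed genes), every network gene's first-layer
neighbourhood is tested for target enrichment with the one-sided Fisher
test. The background universe is all network nodes minus the candidate
itself — the candidate sits in neither its own neighbourhood nor the
complement, so every table sums to |nodes| - 1. The network (not the
measured-gene list) is the universe because candidacy itself is defined by
network membership. Candidates need not belong to the target set. BH across
all tested nodes; key drivers at adjusted p <= 0.05, ranked by adjusted p
with ties broken by raw p, hits, then symbol.

**Aging-gene overlap.** The overlap of age co-expressed genes with a curated
aging-gene list is tested with the same one-sided Fisher machinery;
`overlap_test_counts()` reconstructs published tables from printed counts
alone. Published overlap rows are sometimes computed with the reference
list intersected with the study background while the full reference size is
printed; `implied_reference_size()` solves for the integer reference size a
reported p-value actually corresponds to, which either validates such a row
(to ~3 significant figures) or exposes it as internally inconsistent. The
default construction takes the reference size as given; intersecting is the
caller's choice.

**Drug reversal.** Age co-expressed genes are split into age-elevated and
age-repressed sets by the sign of their (transformed) correlation with age,
kept at BH FDR <= 0.1 computed across the co-expressed genes only. A
perturbation signature reverses the aging signature when its up-regulated
genes overlap the age-repressed set or its down-regulated genes overlap the
age-elevated set; each direction is a one-sided Fisher test over the study
gene universe, ranked by raw p (ranking by adjusted p would not change the
order within a direction, since BH is monotone). The two directions are
reported separately rather than merged into one score, because a drug can
plausibly reverse one arm only. Purely liquid genes have no marginal age
trend, so both directional sets can legitimately come back empty — in that
case the affected ranking is empty, with a warning, not an error.

## The synthetic test-bench

Because the motivating cohort data are controlled-access, the package ships
a generator that emulates their statistical shape rather than any stored
data. A `simulation_spec()` draws n = 150 samples (inside the 83–156 range
typical of a single post-mortem tissue cohort) with ages uniform on 20–70
years; z is the inverse-normal transform of age. Planted pairs are
conditionally bivariate normal given z with correlation
clip(beta * z, -0.95, 0.95); planted drift genes get an `alpha * z` mean
component; everything else is independent standard normal. Linear-in-z
conditional correlation makes the population LAS equal beta via Stein's
identity *up to the clipping correction*: the exact value is
`beta * E[Z^2 1{|Z| <= c}] + 0.95 * E[|Z| 1{|Z| > c}]` with c = 0.95/|beta|
— 0.200 at beta = 0.2 but 0.612 at beta = 0.8, where clipping engages for
|z| > 1.19. Recovery tests therefore target this closed form, not bare
beta. The population marginal correlation of a pure planted pair is 0
(E[clip(beta Z)] integrates an odd function), which is what makes the
LA-vs-PCC divergence exactly true in simulation.

The default spec plants three beta = 0.8 pairs, one per 8-gene module; the
pair genes of the first two modules also carry marginal slopes (+0.5 and
-0.5) so that the directional-set and drug-reversal stages receive
non-empty inputs end-to-end, while the third pair is purely liquid. Four
standalone drift genes (alpha = ±0.6) live outside all modules. The
companion fixtures are deterministic given the seed: a PPI with a hub
adjacent to every planted pair gene plus five 6-node decoy cliques, an
aging-gene list containing the planted genes plus decoys, and a signature
file with one "reverser" perturbation (its up/down sets are exactly the
planted age-repressed/age-elevated co-expressed genes) among 50 random
12+12-gene decoys. The reverser's sets are kept tight so that no random
decoy can reach a smaller hypergeometric tail, making its top rank a
structural property rather than a statistical accident.

What the generator does *not* emulate: RNA-seq count noise, library-size
effects, batch structure, or correlated null genes. The pipeline consumes
rank-transformed values, which erase marginal distortions by construction,
but real co-expression backbones are denser than the independent-null
backdrop here — passing tests demonstrate correctness of the machinery and
its calibration under the stated model, not discovery rates on any real
tissue.

## Problem sizes and thresholds in the test suite

The suite and the acceptance script run at desk scale: 1,000 null triples
(n = 100, 100 permutations) for calibration; 500 pure-null 10-gene module
replicates for the BH false-module rate; 500 replicates at n = 200 for
estimator recovery at beta in {0.2, 0.4, 0.8}; 50 end-to-end replicates of
the default bundle for planted-pair recovery, key-driver detection, and
reverser ranking. Defaults throughout: `n_perm = 100`, LA and PCC FDR 0.1,
consistency and key-driver alpha 0.05, drug-direction FDR 0.1, age cut
points 35 and 55 years, module size bounds [5, 500). All thresholds are
inclusive ("not greater than").

## Limitations

* LAS averages the derivative of conditional covariance over the whole age
  range; an association that rises then falls can average to zero and be
  missed.
* Overlapping modules (the GO hierarchy) are screened independently; a pair
  significant in several nested terms is counted once per term in the
  occurrence table, by design.
* The permutation-null normal fit is anticonservative deep in the tail (see
  above); results at the FDR boundary inside small modules deserve
  scrutiny.
* Key-driver analysis is association on an undirected network; it does not
  infer regulatory direction.
* Signature reversal weighs genes equally and ignores interactions among
  them; it is a prioritisation heuristic, not an effect estimate.
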