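---
title: "Methods: simulating and analyzing genetic-diversity effects on herbivory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing genetic-diversity effects on herbivory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oakherb)
```

`oakherb` models a common-garden experiment in which maternal half-sib
families of a tree species are planted in synthetic mixtures spanning a
genetic-diversity gradient, and insect damage is related to that gradient.
This vignette documents the generative model, the two core statistics, the
numerical choices behind them, and what the synthetic cohorts can and
cannot tell you about real field data.

## The experimental design

`build_design()` constructs randomized blocks in which each block contains
one plot per non-empty subset of the `m` maternal families — `2^m - 1`
plots. With the default `m = 4` this is 15 plots per block: 4
monocultures, 6 two-family, 4 three-family and 1 four-family mixture
(the binomial coefficients `C(4, k)`), so 6 blocks hold 90 plots and 1080
saplings. Every plot is a 4 × 3 grid of 12 saplings with families at equal
density, laid out by a cyclic `(row + col) mod k` pattern so that two
saplings of the same family are never orthogonally adjacent in a mixture.
Equal density requires `12 mod k = 0` for every subset size `k`; five or
more families are therefore rejected rather than approximated.

## The synthetic cohort

The generator exists so that every downstream stage can be tested against
known ground truth. It emulates, stage by stage:

* **Markers.** 11 codominant microsatellite-like loci, allele counts
  permitted in 6–19 with a default spread whose mean is 11. Frequencies
  are either flat-Dirichlet draws (realistic unevenness) or equifrequent
  (used for estimator calibration, where exchangeability makes pedigree
  expectations exact).
* **Mating.** Mother trees are drawn from the locus frequencies. Each
  mother has a finite pollen-donor pool (default 3 donors) with
  Dirichlet(1) usage weights; offspring sharing a donor are full sibs, so
  each maternal family is a realistic full-sib/half-sib mixture. Each
  offspring receives one allele drawn uniformly from the mother's two and
  one from its donor's two, independently per locus.
* **Noise.** A per-locus genotyping error rate replaces one allele of a
  call with a random frequency-weighted allele; a per-individual failure
  rate blanks whole genotypes. Dropout defaults are calibrated to the
  design's scale: death 25/1080, amplification failure 53/1055, leaving
  about 1002 analyzable saplings in expectation.
* **Heights.** Lognormal per family, `meanlog = log(120) ± 0.05` across
  families and `sdlog = 0.25` — a small but nonzero family effect on
  height, enough for height and family to be partially confounded as in
  real gardens.
* **Ectophage damage.** Generated leaf by leaf on the logit scale:
  family baseline (monoculture mean damage, defaults spanning 5.5–8.3% of
  leaf area) plus `gd_slope` (default 0.06 per SD of plot diversity) and
  `height_slope_ecto` (default 0.05 per SD of height), plus Gaussian
  block, plot and leaf noise (defaults 0.15 / 0.15 / 1.0 logit units).
  Each of the 20 leaves is then *discretized through the visual scoring
  classes* (0, 1–5, 6–15, 16–25, 26–50, 51–75, >76 % of leaf area) and
  scored by the class midpoint (0, 3, 10.5, 20.5, 38, 63, 88); the
  sapling's damage is the mean of its 20 leaf scores. Seven class labels
  are implemented, and the open-ended top class is scored 88, the midpoint
  of 76–100; how class labels become a per-sapling percentage is a
  convention this package fixes, not a property of the field protocol.
  The logit-normal leaf model is chosen for closure under the logit
  analysis applied downstream.
* **Leaf miners.** Counts per 20 leaves are Poisson with
  `log(lambda) = miner_intercept + 0.31 * height_SD` — abundance driven
  by sapling apparency, with genetic diversity playing no direct role by
  default.

All randomness flows from one root seed through named substreams
(design, genotypes, dropout, herbivory), so regenerating one stage never
perturbs another and identical configs give byte-identical tables.

What the generator does **not** emulate: spatially explicit herbivore
movement (adjacency affects layout only), leaf chemistry, multi-year
dynamics, null alleles, or linkage between loci. Passing tests therefore
certify the *statistical machinery* — they do not certify that real oak
herbivory follows a logit-normal leaf model with these dispersions.

## Maternity verification

A locus mismatches when offspring and candidate mother share no allele
there; missing calls are skipped. Offspring are excluded when every
candidate mother mismatches at two or more loci ("multiple loci");
exactly one mismatch retains the offspring under its best mother but flags
it, because isolated single-locus incompatibilities are the signature of
genotyping error rather than wrong maternity. The per-locus share of these
single-mismatch events (relative to flagged offspring) is the error
screen; loci above 2% are flagged for removal or re-binning. Ties between
mothers at the minimum are reported `ambiguous` and treated as excluded —
a conservative choice, since a tie means the marker panel cannot decide.
Mutation and genotyping error are deliberately not distinguished, and no
automatic correction is applied: flagged offspring stay flagged.

## Dyadic maximum-likelihood relatedness

For a non-inbred dyad the IBD-mode coefficients `(k0, k1, k2)` give the
probabilities of sharing 0/1/2 alleles identical by descent;
`r = k1/2 + k2`. Per locus, the probability of an observed ordered
genotype pair given `m` IBD alleles is a polynomial in the allele
frequencies (e.g. for genotypes `ij` and `ik`: `P0 = 4 p_i^2 p_j p_k`,
`P1 = p_i p_j p_k`, `P2 = 0`); the pair likelihood is
`k0 P0 + k1 P1 + k2 P2`, multiplied over co-typed loci. Correctness of the
mode tables is pinned by an exhaustive enumeration test: for each mode the
table sums to exactly 1 over all genotype pairs.

Numerical choices:

* **Model.** The three-parameter non-inbred model only; the
  inbreeding-extended nine-coefficient model is omitted because the
  calibration expectations (0.5 / 0.25 / 0) presuppose non-inbred dyads.
* **Constraint.** The genetic feasibility constraint `k1^2 >= 4 k0 k2` is
  *not* imposed by default (`constrain_triangle = FALSE` exposes it); the
  relaxed simplex is the estimator's standard form.
* **Optimization.** A coarse grid over the simplex (step 0.05, containing
  the vertices) followed by five-fold local refinements down to a step of
  8e-5. Likelihood ties are broken toward smaller `r`. The optimizer is
  regression-tested against an independent 0.01-step grid search and
  against the simplex vertices.
* **Missing data.** Pair likelihoods use co-typed loci only; pairs with
  none are reported missing, pairs with fewer than 3 informative loci are
  flagged low-confidence. Allele frequencies are estimated by counting
  over the full genotyped sample including mothers.
* **Known bias.** Because the optimum lives on the simplex, `r >= 0`
  always; for truly unrelated pairs the sampling distribution folds at
  zero and the mean estimate sits a few hundredths above 0 at 11-locus
  information. This boundary bias is a property of constrained maximum
  likelihood, not of the implementation — the package documents it rather
  than re-centring estimates, since downstream analyses use relative
  contrasts of plot means.

Plot summaries are `GD`, the count of assigned maternal lineages, and
`GR`, the mean estimate over all distinct within-plot pairs (undefined
below two analyzable saplings). In half-sib cohorts the two anticorrelate
strongly, which is why the regression stage never puts both in one model.

## The additive partition

For an `n`-family mixture, `M_i` is the mean response of family `i` in its
*same-block* monoculture (cross-block borrowing is disallowed so block
effects cancel within comparisons), and `C_i` is the family's contribution
to the mixture plot: its mean response there divided by `n`. Under the
null of no diversity effect `E[C_i] = M_i / n`, so the observed relative
forage `RF_Oi = C_i / M_i` has null expectation `1/n` and

* `NGDE = sum(C) - mean(M)` — net effect (positive = associational
  susceptibility),
* `CE = n * mean(dRC) * mean(M)` — complementarity,
* `SE = n * cov(dRC, M)` — selection, with the *population* covariance
  (denominator `n`), which is what makes `NGDE = CE + SE` an exact
  identity rather than an approximation. The identity is enforced at
  1e-10 relative tolerance on every simulated mixture, which pins the
  algebra.

Degenerate inputs are reported, not patched: a missing or zero
monoculture reference (possible for miner counts) marks the whole
mixture's partition missing with a reason, rather than introducing a
pseudo-count. Family means are unweighted by realized survivor counts.
Because NGDE is linear in the family means, its expectation under the
null generative model is exactly zero, and the one-sided t-test of the
grand mean holds its nominal size — verified by a 500-replicate null
simulation in the acceptance suite. CE and SE are ratios' aggregates and
individually carry finite-sample Jensen bias; only their sum is
bias-free under the null, which is why calibration is asserted for NGDE.
Test directions default to the associational-susceptibility alternative
(NGDE, CE upward; SE downward) and are configuration, not hard-coded.

## Herbivory regressions

The regression stage owns transforms, model structure and the
simplification loop; estimation itself is delegated to `lme4`/`lmerTest`.
Damage proportions are logit-transformed with a data-driven boundary
adjustment (`eps` = half the smallest nonzero proportion — exact zeros are
routine in scored damage). Continuous covariates are centred and scaled so
coefficients are per-SD effects comparable across terms and models. Models
follow the design's correlation structure with random intercepts for plot
nested in block; diversity enters as GD or GR, never both. Backward
simplification refits after dropping the least-significant non-significant
interaction of highest order, never touches main effects, and keeps (and
flags) any term whose reduced fit fails. Per-term evidence uses
Satterthwaite F (LMM) or likelihood-ratio chi-square (GLMM), and a
likelihood-ratio `R^2 = 1 - exp(-LRT/n)` against the model without the
term.

For *parameter recovery* checks the package does not regress the logit of
the discretized damage directly: midpoint scoring compresses the scale and
attenuates slopes by roughly a third at the default noise levels. Instead,
the scoring process has a known observation link — the expected midpoint
score given the sapling's linear predictor is a sum of class midpoints
weighted by normal CDF differences at the class boundaries
(`damage_link()`), strictly increasing and available in closed form. The
recovery procedure inverts it (`invert_damage_link()`) and regresses the
inverted scores, which restores the generative scale; the acceptance suite
recovers the default slopes within three standard errors at
10,000 saplings. The paper-style logit regressions remain available and
are checked for sign and significance, not for slope equality.

## Problem sizes and reproducibility

The test suite runs on a small fixture (2 blocks × 2 families,
72 saplings) wherever the full design adds nothing, and scales up only
where the quantity demands it: 500 dyads per pedigree class for estimator
calibration, 500 replicates of the small fixture for test-size
calibration, 56 blocks (10,080 saplings) for slope recovery. These sizes
were chosen so each stochastic check has a 3-standard-error margin
around its target while the whole suite stays quick to run.

## Known limitations

* The relatedness estimator's positive boundary bias for unrelated dyads
  (above) is inherent; comparisons of GR across plots are unaffected by a
  shared offset, but absolute GR values near zero should be read with it
  in mind.
* Null alleles are not modelled and not detected; a locus with a strong
  null allele would surface in the error screen only as an elevated
  mismatch rate.
* The partition is the two-way CE/SE split; no tripartite extension.
* Mixed-model internals (REML, Laplace) are used as provided by `lme4`;
  singular random-effect fits at small scales are possible and surface as
  warnings from the delegated machinery.
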