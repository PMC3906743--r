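---
title: "Methods: from transfection arrays to regulator prioritisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from transfection arrays to regulator prioritisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexreg)
```

`coexreg` packages the computational workflow of a small transfection
microarray study into tested, reusable pieces: normalize the arrays, score
differential expression and phenotypic impact per contrast, call significant
probes with a mixture model at a fixed false discovery rate, prioritise
candidate regulators with co-expression machinery (PCIT, module-to-regulator
ranking, RIF), analyse the confirming qPCR with a fixed-effects ANOVA and
delta-delta-Ct contrasts, and test called gene lists for gene-set
over-representation. This vignette explains each model, its assumptions and
the numerical choices, in the package's own terms.

## Normalization chain

Raw bead-array signals are positive and heteroskedastic, so the chain is:

1. **Detection filter** — keep probes with a detection p-value below
   `alpha` (default 0.01) in *at least one* array. A probe indistinguishable
   from background everywhere carries no usable signal; the at-least-one rule
   deliberately errs on the permissive side because downstream DE uses group
   means, not single arrays.
2. **log2 transform** — stabilizes variance. Requires strictly positive raw
   values; a non-positive value is an error naming probe and sample, never a
   silent offset.
3. **Within-chip standardization** — each sample column is centred and
   scaled to mean 0, sd 1, so arrays of different overall brightness combine
   into linear contrasts without chip effects. The standard deviation uses
   the **population (divide-by-n) convention**; nothing downstream depends
   on which convention is used as long as it is applied consistently, and
   the test suite asserts the contract in the same convention.

The `expr_matrix` container carries a scale flag (`raw -> log2 ->
standardized`) that each step checks, so running steps out of order is an
error rather than a silently wrong analysis. Missing values are rejected at
construction: the platform yields complete matrices, and explicit failure
beats silent imputation.

Outlier arrays are *flagged*, not dropped: `flag_outlier_samples()` computes
each array's mean correlation to the others and flags arrays more than
`z_cut` (default 3.0, our convention) standard deviations below the mean of
that statistic. The analyst then passes an explicit drop list to
`pool_controls()`, which also merges control groups that cannot be
discriminated into a single `control` label. Keeping removal explicit makes
the decision reproducible — a drop list in a script instead of an eyeballed
dendrogram. Note that with very few arrays (e.g. 6) the z-score of even a
blatant outlier is bounded (~2), so small designs need a lower `z_cut`.

## DE, PIF and fold changes

For a contrast of groups A and B, per probe on the analysis scale:

- `de = mean_A - mean_B`, with standard errors `sd / sqrt(n)` per group;
- `avg_abund = (mean_A + mean_B) / 2` — the symmetric choice of "average
  abundance", taken on the same normalized scale as DE;
- `pif = avg_abund * de` — the Phenotypic Impact Factor. Rare transcripts
  are noisy in proportion to their signal, so weighting DE by abundance
  raises the sensitivity for abundant transcripts with modest fold changes
  (an abundant 1.3-fold shift can matter more, and be measured better, than
  a rare 3-fold one);
- `fold = 2^de`, reported to 2 significant figures in summaries with full
  precision retained internally.

In a transient transfection only a fraction `e` of cells receive the
construct, so a bulk fold change `f` over the culture understates the
per-transfected-cell effect; `efficiency_correct(f, e) = f / e` recovers it
(e.g. a bulk 3.4-fold at 10% efficiency implies ~34-fold per transfected
cell). `panel_summary()` applies the same arithmetic to a flagged probe
panel (such as the mitochondrially encoded protein genes) and reports the
number of distinct genes, how many trend up in at least one probe, and the
maximum per-probe fold.

## Two-component mixture and FDR calling

Genome-wide DE or PIF scores are modelled as
`pi0 N(mu0, sigma0^2) + (1 - pi0) N(mu1, sigma1^2)`, fitted by EM. Choices:

- **Initialization**: split at the 90th percentile of |score| to seed the
  alternative component, plus 5 jittered restarts (seeded, so fits are
  bit-reproducible); the best restart by final log-likelihood wins.
- **Null label**: the larger-weight component, ties broken by the mean
  closer to 0 — DE scores are majority-null by design, so the label does not
  depend on component ordering.
- **Numerics**: convergence at relative log-likelihood change < 1e-8, at
  most 2000 iterations, and a variance floor of `1e-6 * var(scores)` that
  prevents a component collapsing onto a point (if it engages the fit says
  so). On pure-null data the alternative component is weakly identified and
  EM can hit the iteration cap while creeping along a flat likelihood
  ridge; such fits are still usable mixtures and classification proceeds
  with a warning.

Calling uses **tail-area ("experiment-wise") FDR** rather than local fdr:
for a threshold `t` above the null mean, `FDR(t) = pi0 * P0(X >= t) /
(fraction of scores >= t)`, and the chosen threshold is the least extreme
observed score with `FDR(t) <= target` (default 1%). Up and down thresholds
are chosen independently, since up- and down-regulated lists are reported
separately. This construction makes call sets monotone in the target. DE
and PIF columns are exposed separately and each can be called on its own;
whether to threshold them jointly is left to the analyst.

A note on operating characteristics: at 10% alternatives shifted 3 sd, a 1%
tail-area FDR forces an up-threshold near 3.3 even with the true parameters
known, so power is ~0.35 — that is a property of the target, not of the
fitting. At a 5% target, power clears 0.5 with realized FDR near target;
the suite measures both.

## Co-expression machinery

**PCIT.** For every gene trio (x, y, z) the three first-order partial
correlations are computed, e.g. `r_xy.z = (r_xy - r_xz r_yz) /
sqrt((1 - r_xz^2)(1 - r_yz^2))`; the trio tolerance is the mean of the
three |partial/direct| ratios, and the edge (x, y) is eliminated if some z
satisfies `|r_xy| <= eps |r_xz|` and `|r_xy| <= eps |r_yz|`. The exact
inequality (non-strict, AND over both comparisons, existential over z) is
locked by a literal triple-loop oracle the vectorized implementation must
match exactly on randomized instances. Off-diagonal correlations at ±1 are
clipped to `1 - 1e-12` (reported) so partials stay defined; ratio
denominators are floored at the smallest positive double. The O(n³) scan is
capped at 2,000 genes by default with an explicit error beyond — this
implementation targets module-scale networks, not whole transcriptomes.

**Module-to-regulator.** Candidate regulators are ranked by their mean
|r| to the module members ("which regulator has the highest absolute
average correlation to all genes in the module?"). A regulator inside the
module is excluded from its own average; the absolute value makes the score
invariant to sign flips of member profiles; ties break lexicographically by
gene id so rankings are deterministic.

**RIF.** Across two conditions A and B with regulator-to-DE-gene
correlations `r^A`, `r^B`, DE-gene impact weights `pif_j` and per-condition
mean abundances `e_j`:

$$rif1_i = \frac{1}{n_{DE}} \sum_j pif_j\,(r^A_{ij} - r^B_{ij})^2
\qquad
rif2_i = \frac{1}{n_{DE}} \sum_j \left[(e^A_j r^A_{ij})^2 -
(e^B_j r^B_{ij})^2\right]$$

both z-standardized across regulators. `rif1` is symmetric under condition
swap; `rif2` (a signed change) negates. When all raw scores coincide
(identical conditions give `rif1 = 0` everywhere) the z-scores are defined
as 0. Regulators with zero variance in either condition are excluded with a
report. These formulas are a declared design decision of this package,
validated against planted synthetic truth rather than against any external
dataset.

Correlations throughout are Pearson on standardized log2 values, consistent
with the normalization chain.

## qPCR model

Ct values are analysed with the fixed-effects ANOVA
`Ct ~ primer + treatment + primer:treatment` (fit by `lm`, cell LSMs via
`emmeans`). In the balanced designs this targets, the least-square mean of
a cell equals its arithmetic mean; the model also yields the fraction of
total Ct variation explained (R²) and F-tests for both main effects and the
interaction. Wells annotated as no-amplification are treated as censored
and excluded (they are annotations, not measurements); an additional Ct
ceiling (default 34 cycles) censors late amplifications, which are noise
under SYBR chemistry. A cell emptied by censoring is reported as missing,
and contrasts touching it fail by name. With all Cts identical, R² is 0/0
and is returned as `NA` by convention (all contrasts are 0 regardless).

The reference-gene-normalized fold change is computed **from LSMs, not per
replicate**:
`fold = 2^[(Ct_tgt,ctl - Ct_ref,ctl) - (Ct_tgt,trt - Ct_ref,trt)]`,
assuming perfect doubling per cycle (primer-specific efficiencies are out
of scope). Per-sample additive Ct offsets — pipetting and cDNA input
variation — cancel exactly in this double difference, which the suite
asserts. Error bars elsewhere in the package are standard errors of the
mean; where published figures used a standard-curve-based error, SEM is
used here instead and the divergence is accepted.

## Gene-set enrichment

`hypergeom_enrich()` is a plain upper-tail hypergeometric
over-representation test, inclusive at the observed overlap, against a
user-supplied background (all genes on the array). Sets are intersected
with the background first; a hit absent from the background is an error, not
a silent drop. Benjamini–Hochberg adjustment across sets is provided but
optional, since raw hypergeometric p-values are the convention of the web
tools this replaces. There is no ontology traversal, ranked-list (mHG) mode
or motif scanning; published enrichment p-values depend on annotation
snapshots and are not reproduction targets.

## What the synthetic data emulate — and what they do not

`sim_config()` defaults encode the study design this pipeline was built
for: 4 treatment groups (two controls, two transfected variants) × 3 pooled
arrays, ~20k probes of which ~10% are background-only noise (so ~18k are
detectable), log2-Gaussian signals around three abundance tiers, a 5%
planted DE fraction at 1.0 log2, and a 12-probe abundant panel shifted
uniformly in [log2 1.1, log2 1.4]. Detection p-values are drawn directly —
Beta(0.1, 10) for expressed probes, Uniform(0, 1) for noise probes — rather
than simulated from negative-control beads, because the pipeline consumes
vendor detection p-values, not bead-level data. Co-expression modules use
one latent factor per module with members at ~0.97 correlation to it and a
designated regulator loaded so its expected correlation to members equals
`regulator_r`; the two-condition generator rewires exactly one regulator's
loading by `delta_r`. qPCR tables are triplicates with a flat reference
primer, per-sample offsets, and `-log2(fold)` shifts on target primers.

All randomness flows through one seed per generator call; identical
configurations are byte-identical. Every planted quantity is recoverable
from the returned truth table without re-running the generator.

Deliberately **not** emulated: bead-level summarisation, spatial artefacts,
batch effects, probe cross-hybridisation, mixture distributions with heavy
tails, or primer efficiency differences. Passing tests on this synthetic
world therefore demonstrate the correctness of the arithmetic and the
statistical behaviour under the stated generative model — they do not
certify performance on arrays with structured technical artefacts.

## Problem sizes and test design

The suite runs everything at desk scale, chosen so the whole suite
completes in a few minutes: planted-effect recovery at 200 samples/group,
module recovery at 16 genes × 60 samples with 20 decoys (100 seeded
replicates), RIF recovery at 30 + 30 samples (100 replicates), EM recovery
at 10,000 scores, FDR control at 2,000 scores × 100 replicates, PCIT oracle
equivalence on 50 random instances of at most 25 genes, and hypergeometric
enumeration over every admissible (N, K, n, k) with N ≤ 30. Monte-Carlo
acceptance bands (e.g. "≥ 95 of 100 runs") are properties of these stated
conditions; the conditions are fixed in the tests, not tuned.

## Known limitations

- No moderated-variance (empirical-Bayes) DE statistics; group means and
  plain SEs only, as appropriate for the 2–6 arrays/group designs this
  targets.
- PCIT is O(n³) and intended for candidate sets, not 20k-probe networks.
- The mixture model is strictly two-component Gaussian; heavy-tailed or
  multi-modal alternatives will push `pi0` down and widen `sigma1` rather
  than fit well.
- ΔΔCt assumes perfect doubling; folds from primers with poor efficiency
  will be biased.
- Gene-level aggregation across probes is limited to the panel summary
  counts; everything else is per-probe.
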