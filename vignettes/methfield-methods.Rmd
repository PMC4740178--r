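---
title: "Detecting stochastic DNA-methylation field defects: models and methods"
author: "methfield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stochastic DNA-methylation field defects: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methfield)
```

## The problem

Histologically normal tissue adjacent to a tumour often carries molecular
alterations — *field defects* — thought to mark pre-neoplastic clones.
In DNA methylation data these alterations are heterogeneous: a given CpG
is typically altered in only a handful of the normal-adjacent samples,
each as an outlier "jump" of 0.2–0.3 on the beta-value scale away from
the tight normal baseline. A conventional differential-methylation
analysis (compare group means) has almost no power against this signal,
because a few outliers barely move a group mean. A pure
differential-variability analysis has the opposite problem: variance
tests such as Bartlett's are so sensitive that a single aberrant
measurement produces an extreme p-value. `methfield` implements the
statistical toolkit built around this tension.

## The iEVORA selection model

`runIEVORA()` performs a two-stage selection between a control group
(e.g. normal tissue from cancer-free women, `N`) and a case group (e.g.
normal tissue adjacent to tumours, `NADJ`):

1. **Differential-variability screen.** Each CpG is tested with the
   two-group Bartlett statistic
   \[
   T = \frac{(N-2)\ln s_p^2 - \sum_i (n_i-1)\ln s_i^2}{C},
   \qquad
   C = 1 + \frac{\sum_i \frac{1}{n_i-1} - \frac{1}{N-2}}{3},
   \]
   referred to \(\chi^2_1\). CpGs with FDR q-value below `dvFdr`
   (default 0.001, deliberately stringent) are differentially variable
   CpGs (DVCs).
2. **Regularization and re-ranking.** Because the variance screen is
   overly sensitive to single outliers, DVCs are retained only when the
   two-sided t-test of mean methylation has unadjusted p below `dmP`
   (default 0.05), and survivors are re-ranked by \(|t|\) descending.
   A DVC driven by one aberrant sample has a large Bartlett statistic
   but a negligible mean shift, so it fails this filter; a DVC altered
   in a consistent direction across several outlier samples passes.

Each selected DVMC is labelled `dvUP`/`dvDN` (variance up/down in the
case group, the sign of \(\log_2 s^2_{case}/s^2_{ctrl}\)) crossed with
`dmUP`/`dmDN` (the sign of the t-statistic, case minus control).

Design choices we made where the procedure was genuinely open:

* **t-test flavour.** The Welch unequal-variance t is the default
  (`tVariant = "welch"`), matching the default two-sample t-test of the
  R environment the original screen ran in; a pooled-variance variant is
  available (`tVariant = "pooled"`). The choice matters: under outlier
  contamination the case-group variance is inflated by the jumps
  themselves, so the Welch denominator is dominated by the very signal
  being tested. With a fraction \(f\) of jumping case samples the
  expected Welch t is approximately \(\sqrt{n_{case} f/(1-f)}\)
  *independent of the jump size*; at \(f = 0.1\) and 42 case samples
  this is ≈ 2.08, right at the p = 0.05 critical value, so roughly half
  of genuinely contaminated sites sit on either side of the `dmP`
  filter. This is an intrinsic property of the regularized design — the
  filter exists to discard outlier-driven sites, and it prices that
  robustness as reduced sensitivity at low contamination fractions. The
  pooled variant is noticeably more sensitive here (the clean control
  variance shrinks the pooled denominator) but less robust when group
  variances genuinely differ, which is the very phenomenon under study;
  we therefore kept Welch as the default.
* **FDR estimator.** `estimateFdr()` defaults to Benjamini–Hochberg.
  A Storey-type estimator is available (`method = "storey"`), with
  \(\hat\pi_0\) the median of \(\#\{p>\lambda\}/(m(1-\lambda))\) over
  \(\lambda = 0.05, \ldots, 0.95\); the exact spline smoother of the
  q-value package is version-dependent, so the simpler median estimator
  is used and BH remains the default.
* **Ties** in \(|t|\) are broken by smaller Bartlett q-value, then probe
  id, for deterministic output.
* **Degenerate probes** (fewer than `minGroupSize = 3` usable values in
  a group, or zero variance) are never tested and never silently
  dropped: they are reported in the `excluded` side table.
* Tests operate on beta values directly; no M-value transform is
  applied, and no imputation is performed (probes failing the
  missingness rule are excluded instead).

## Deviation calling, hit matrices and permutation nulls

`deviationZ()` scores each target sample against the reference group per
probe, \(z = (\beta - \mu_{ref})/s_{ref}\) with the n−1 standard
deviation, and converts to two-sided normal p-values; `p < 0.001`
(strict) defines a *hit*. The 0.001 default corresponded roughly to an
FDR of 0.05 in the cohort that motivated it, but that equivalence is
data-dependent, so the threshold is exposed as a parameter. Two-sided
p-values were chosen (the sidedness was genuinely open) and the sign of
z is retained so hyper- and hypomethylation remain distinguishable.

Three Monte-Carlo analyses operate on the binary hit matrix, each
conserving exactly the margins its question requires (asserted on every
permutation):

* `stochasticityTest()` scrambles all entries jointly (total hit count
  conserved) and compares the maximal per-probe alteration frequency
  with its null — are any loci altered more often than chance, given the
  overall alteration burden?
* `heterogeneityTest()` permutes each sample's hit vector over probes
  (per-sample counts conserved) and compares mean pairwise Manhattan
  distances and fractional overlaps — do samples share altered loci more
  than chance, after adjusting for per-sample burden? Fractional overlap
  is reported as intersection over union of the two hit sets.
* `coordinationTest()` permutes each gene/probe row across samples
  (per-row counts conserved), over rows with at least
  `floor(minHitFrac × n_samples)` hits (4 at the default 0.1 with 42
  samples); a mean pairwise distance below the null indicates
  coordination, above it mutual exclusivity.

Empirical p-values always use the +1 correction,
\((1 + \#\{null \ge obs\})/(n_{perm}+1)\), so they are never zero.
Per-permutation RNG streams are keyed by (seed, permutation index), so
the null distributions are bit-reproducible for a given seed.

## Cell-fraction deconvolution

Breast tissue is a mixture of epithelial and adipose compartments, and
fat content dominates the correlative variation of whole-tissue
methylomes. `buildReference()` selects marker CpGs with
\(|\beta_{HMEC} - \beta_{FAT}| > 0.7\) (strict) that fall in DNase
hypersensitive sites, and `estimateFractions()` solves, per sample,

\[
\min_w \sum_j \Big(\beta_j - \sum_k w_k c_{jk}\Big)^2
\quad \text{s.t.}\quad w_k \ge 0,\ \textstyle\sum_k w_k = 1 .
\]

Stromal cells are absorbed into the epithelial weight, so for two cell
types \(w_{HMEC} + w_{FAT} = 1\). The solver enumerates support sets and
solves each equality-constrained KKT system exactly (tolerance 1e-9);
with the handful of cell types this problem ever has, this is exact,
dependency-free and fast, and the two-type path is cross-checked against
a grid search in the test suite. `adjustForFractions()` then removes the
linear effect of the fat fraction per probe, returning residuals
recentred at the fitted value for the mean fat fraction — rather than
raw residuals — so adjusted values stay on the beta scale; values are
clipped to [0,1] afterwards and clipping events are counted. The
adjustment model (simple per-probe OLS) was an open design point and is
deliberately the most transparent choice.

## Scores

Over a DVMC category, `progressionZ()` averages a sample's z-deviations
(hypermethylated categories: more positive = further from the normal
state), `fracHitsScore()` counts the fraction of category probes hit,
and `personalizedDeviation()` averages \(\beta_{tumour} -
\beta_{matched\ adjacent}\) within matched pairs. `discriminateAUC()`
turns any of these into a two-group AUC via the Mann–Whitney identity
(ties ½) with a Hanley–McNeil 95% CI. Missing values are dropped
pairwise within every mean and the number of contributing probes is
reported alongside each score.

## Enrichment arithmetic

`fisherEnrichment()` tests over-representation of a selection in named
sets by the one-tailed hypergeometric tail, reporting the sample odds
ratio ad/bc (Haldane 0.5 correction only when a zero cell occurs) and BH
adjustment across the sets of the call. The default universe should be
the set of probes actually tested by the screen, not the whole array, to
avoid selection bias; the array-wide universe can of course be passed
explicitly, and the printed-arithmetic audits (`expectedOverlap()`) use
it because their published inputs do. Gene-level analyses should map
probes to genes through the TSS-proximal region classes (TSS1500,
TSS200, 1stExon), the regions most informative of expression.

## What the synthetic cohorts emulate — and what they do not

`simulateNullCohort()` draws both groups per probe from one
normal-on-the-beta-scale distribution with three baseline strata (means
0.10 / 0.50 / 0.85 in proportions 0.35 / 0.25 / 0.40), a per-probe mean
jitter of sd 0.02, and per-probe dispersions uniform on [0.01, 0.03] —
values chosen once as representative of the bimodal 450k landscape and
of inter-individual variability of normal tissue. Values are clipped to
[0,1]; with these parameters clipping affects a negligible fraction of
cells, so Bartlett's test stays calibrated (verified in the acceptance
suite at α = 0.05 and 0.01 on 10,000 probes).

`simulateFieldDefect()` plants hypervariable probes by adding jumps
drawn from U[0.2, 0.3] in `round(outlierFrac × n_case)` randomly chosen
case samples per planted probe, directed away from the baseline (up
below 0.2, down above 0.6, random per probe otherwise) — with the
default 0.1 and 42 case samples that is 4 outlier samples per probe,
matching the observation that most field-defect loci are altered in only
four to five of 42 normal-adjacent samples.
`simulateProgressionCohort()` adds matched tumours that inherit their
adjacent-normal profile plus a further directed shift at *every* planted
probe, emulating the convergence of tumours onto the full field-defect
repertoire. `simulateMixtureCohort()` produces convex combinations of
reference centroids plus truncated noise for the deconvolution harness.

These generators reproduce the statistical structure the methods assume
— outlier contamination on a tight baseline, burden differences between
groups, mixtures on the simplex — but deliberately **not** array
technical artefacts: probe-type bias, batch/chip effects, detection
failures, spatially correlated probes, or cell-type heterogeneity beyond
the two-component mixture. Passing tests on these cohorts therefore
validate the algorithms' contracts, not their end-to-end behaviour on
raw array data, which additionally requires the usual normalization
pipeline (out of scope here, as is IDAT parsing, BMIQ and imputation).

A consequence of the generator's faithful conditions is worth stating
plainly: at a 10% outlier fraction among 42 case samples, the Welch-t
regularization filter caps recovery of planted probes near 50% (see the
selection-model section above); recovery climbs steeply with the outlier
fraction (it is essentially complete at 25%), and the two-stage
selection recovers strictly more planted probes than a Welch-t + BH
differential-methylation analysis at every contamination level we
simulate — the property the design exists for.

## Numerical conventions

* Coordinates are 1-based inclusive; the RRBS mapping window
  (`mapArrayToRrbs()`) is |Δ| ≤ 100 bp, closed at both ends, after
  filtering loci to ≥ 20× coverage; BED inputs (0-based half-open) are
  converted on import. Strand is ignored throughout (CpG methylation is
  treated as strand-symmetric).
* Missing-value tokens on input are `NA`, `NaN` and the empty string;
  out-of-range beta values are an error naming the offending
  probe/sample, never clipped.
* Beta matrices are serialized with 17 significant digits so write/read
  round-trips are bitwise exact.
* The problem sizes used by the test and acceptance harnesses (10,000
  probes for calibration, 2,000 for recovery, 1,000 permutations,
  10–20 seeds) were chosen as the smallest sizes at which the
  Monte-Carlo standard errors are well below the tolerances being
  checked.

## A small worked example

```{r example}
sim <- simulateFieldDefect(nProbes = 500, nControl = 50, nCase = 42,
                           fracDvProbes = 0.02, outlierFrac = 0.25,
                           seed = 7)
res <- runIEVORA(sim$beta)
res
head(as.data.frame(dvmcTable(res))[, c("probe_id", "t_stat",
                                       "log2_var_ratio",
                                       "bartlett_qvalue", "category")])
mean(sim$truth$plantedDvProbes %in% dvmcTable(res)$probe_id)
```

## Known limitations

* The normal approximation behind the deviation p-values ignores the
  boundedness and skew of beta values near 0 and 1; in practice the
  reference sd is small enough that this matters little, but extreme
  baseline probes (μ very close to 0 or 1) deviate.
* The Storey π₀ estimator is the simple median-of-grid version, not the
  smoother of the q-value package.
* `estimateFractions()` assumes the reference centroids span the
  sample's composition; an unmodelled cell type biases the weights
  toward whichever centroid it resembles.
* Permutation nulls treat probes as exchangeable; correlated probe
  blocks (CpG islands) make the stochasticity null mildly liberal.
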