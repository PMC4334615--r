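---
title: "Pooled-sample GWAS: model, calibration and design choices"
author: "poolGWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled-sample GWAS: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolGWAS)
```

## The problem and the model

Genotyping arrays are expensive at cohort scale. A pooled design
hybridizes the combined DNA of many patients to a single array and reads
off *group* allele frequencies rather than individual genotypes. This
package implements the two-stage version of that design for case groups
that are clinically distinct disease subtypes: a discovery screen on
duplicate 10-patient DNA pools per condition, followed by individual
genotyping of a replication cohort for the candidates that survive.

The fluorescence model is deliberately minimal. Each SNP has allele-A and
allele-B probe quartets; the background-corrected signal of a quartet is
$f = \max(PM - MM, 0)$, quartets are summed per allele, and the pool
frequency estimate is $F_A = f_A / (f_A + f_B)$. Because only this ratio is
consumed downstream, any common gain or additive offset cancels; what
matters is that the per-allele signal is approximately linear in the
allele's frequency in the pool.

With duplicate pools, each case subtype vs control contrast yields four
frequency ratios $R_1 \dots R_4$ (both case pools over both control
pools). Their mean measures the size of the frequency shift; their
coefficient of variation measures its consistency across the biological
duplicates. A large, consistent shift — large mean (or, symmetrically,
mean below the reciprocal threshold), small CV — is the signature the
screen looks for.

## What the screen can and cannot detect

A 20-fold threshold on a ratio of allele frequencies is only reachable
when the denominator is nearly zero: in practice, when both control pools
contain zero copies of an allele that is common in the case pools. With
pools of 10 individuals the estimated pool frequency lives on the grid
$k/20$, so "nearly zero" means *exactly* zero, and the clamp
$\varepsilon = 10^{-4}$ turns those zeros into ratios of order $10^3$.
Consequently:

* a planted allelic odds ratio of 4 at a typical MAF shifts the mean ratio
  to about 3–4 and essentially never passes the 20-fold pre-selection (we
  measured a per-cohort success probability near zero at threshold 20 and
  only ~0.27 even at a lowered threshold of 2);
* the detectable regime is a near-private allele in controls (population
  frequency ≲ 0.01) that is strongly enriched in cases — which is also why
  ranked discovery lists from this design show mean ratios of either
  hundreds or hundredths, never single digits.

The packaged power demonstration therefore plants a control frequency of
0.005 with a case frequency of ~0.5 (allelic OR 200 for the rare allele),
the weakest effect that survives the whole funnel in ≥ 18 of 20 seeds.
The power-monotonicity property (smaller empirical probability for larger
planted OR) is tested at OR 1.5/2.5/4 directly on the empirical
probability, without the pre-selection gate, using common random numbers
across OR levels: genotypes are drawn by quantile inversion from shared
uniforms, which removes most of the replicate-to-replicate noise from the
paired comparison.

## The Monte Carlo null and its calibration

The null is built exactly like the analysis: for each simulated SNP, four
frequencies are drawn, clamped with the same $\varepsilon$, and pushed
through the same ratio/mean/CV code. Three frequency models are provided:

* **uniform** (default): independent Uniform(0, 1) draws — the simplest
  "random allele frequencies" null, applied per chromosome with the chip's
  SNP count;
* **empirical**: resampling of the observed pool frequencies;
* **matched**: a parametric null that redraws the synthetic-cohort
  generative process itself (MAF spectrum → binomial pool allele counts →
  probe noise → allelotyping), preserving the fact that the four pool
  frequencies of one SNP share a population frequency.

Joint extremeness of an observed pair is defined as *mean at least as
extreme and CV no larger*, which rewards large consistent shifts and
penalizes noisy ones. The raw joint-tail mass, however, is **not** a
p-value: quadrant probabilities are not probability-integral transforms,
and we measured a Kolmogorov–Smirnov distance of 0.65 from uniformity for
null draws. The package therefore reports, by default, the
*rank-calibrated* probability: the add-one-corrected fraction of null
pairs whose own joint-tail count is at most the observed count. This is a
strictly monotone transform of the raw count — the SNP ranking is
identical — but uniform under the null by construction (measured KS
p ≈ 0.3–0.99 across seeds), so the 0.05 cut used for "FDR 5%" selection
actually has a 5% null exceedance rate. The raw definition remains
available (`empiricalP(..., method = "raw")`) for comparison. Both share
the floor $1/(1 + n_{\mathrm{SNPs}} \times n_{\mathrm{reps}})$.

Two caveats the user should know:

* the **uniform** null badly mis-states the tail for realistic spectra:
  real low-MAF SNPs produce exact-zero control pools at percent-level
  rates, while Uniform(0, 1) draws do so with probability $10^{-4}$, so
  uniform-null probabilities for clamp-driven signals are optimistic. The
  type-I calibration property is therefore stated — and tested — against
  the **matched** null, where the full discovery chain's rate of
  {pre-selected and p < 0.05} agrees with the null's own tail rate (we
  measure ~0.010 vs ~0.010 on 5,000 null SNPs);
* exchanging case and control pools maps each ratio to its reciprocal, but
  the *mean* of reciprocals is not the reciprocal of the mean: a SNP
  selected through a single discordant control pool need not remain
  selected after the exchange. The guaranteed symmetric mapping holds for
  consistent quadruples (all four ratios past the threshold).

## The synthetic cohort generator

The generator's defaults encode the study design it emulates: four groups
(CTR control plus SUP/OMA/DIE subtypes), two 10-individual DNA pools per
group in biological duplicate, a uniform minor-allele-frequency spectrum
on [0.05, 0.5], 120 individuals per group (pooled arm plus an
individually genotyped arm of replication-cohort magnitude), and a 2.5%
genotype missingness rate matching a ~97.5% genotyping call rate.
Choices worth spelling out:

* **Allele designation.** The array's A/B labelling is arbitrary with
  respect to minor/major, so half the SNPs carry the minor allele as B
  (planted-effect SNPs excepted, so a configured base frequency refers to
  allele B directly). Without this, ratios formed on the designated A
  allele could never reach the selection threshold.
* **Effects.** A planted effect shifts the population frequency by an
  allelic odds ratio, $p_{case} = OR\,p/(1 - p + OR\,p)$, then genotypes
  are drawn under Hardy–Weinberg *within* group. This is the simplest
  model consistent with reporting allele-level odds ratios.
* **Missingness** applies only to individuals outside the pools: pools are
  made of DNA, not of genotype calls, and pool frequencies must remain
  exact allele counts over $2 \times$ pool size.
* **Noise.** Probe-level intensities are linear in allele frequency with
  log-normal multiplicative noise (CV 0.1 per probe, 5 probes per allele),
  a 20% mismatch leakage of the noise-free signal, and an additive floor
  common to PM and MM. The floor cancels in PM − MM; a frequency of
  exactly zero yields a corrected fluorescence of exactly zero. Under
  these defaults the true-vs-estimated pool-frequency correlation is
  ~0.9986 and the mean absolute error ~0.011; with noise switched off the
  round trip is exact to machine precision (~$10^{-16}$).
* **What is not emulated:** linkage disequilibrium, population
  stratification, batch effects, probe-sequence-specific affinity, and
  unequal DNA contributions of pool members (an equal-contribution pool is
  assumed; the original protocol quantified pools repeatedly to approach
  this). Passing tests on these cohorts therefore validate the
  *statistics*, not robustness to those real-data artifacts.

## Replication-stage statistics

The association test is the genotypic Pearson chi-square on the 3×2 table
(no continuity correction; all-zero genotype rows dropped before
df = (r−1)(c−1)). The odds ratio is allelic, from the 2×2 table in which
every genotyped individual contributes two alleles, *oriented to the
case-enriched allele* so OR ≥ 1 — the only convention that reproduces all
published values we checked — with Woolf's log-normal 95% interval; a zero
allele cell triggers the Haldane–Anscombe +0.5 with a flag.
Hardy–Weinberg equilibrium in controls uses the 1-df goodness of fit
against proportions implied by the observed allele frequency (an exact
test is available). Breslow–Day heterogeneity across stages solves the
Mantel–Haenszel common-OR quadratic for the expected counts, with
Tarone's correction on by default; the discovery stratum is an
*approximate* 2×2 built by rounding mean pool frequencies times twice the
pooled sample size, and is flagged as such. Missing genotypes are excluded
listwise per SNP and tracked as a call rate.

On the published genotype counts bundled with the package, this battery
reproduces all five odds ratios, all ten Woolf bounds and all printed
allele-frequency percentages; four of the five printed chi-square
p-values round to the published values, while one published p-value
(0.005 for the rarest variant) is not reproducible from its printed
genotype counts under any standard test we tried (genotypic Pearson gives
0.056, allelic Pearson 0.009, allelic Fisher 0.007) — the package reports
the computed value.

## Numerical and interface choices

* PM − MM can be negative on real arrays; it is clamped at 0 to keep
  $F_A \in [0, 1]$. Probe quartets are combined as a ratio of sums, more
  robust to one dim probe than a mean of per-probe ratios.
* Frequencies are clamped to $[\varepsilon, 1-\varepsilon]$,
  $\varepsilon = 10^{-4}$, before ratios; $\varepsilon$ is a config knob.
* The CV of the four ratios uses the sample (n−1) standard deviation by
  default; the population convention is a switch.
* The joint-tail machinery uses an $O(N \log N)$ Fenwick-tree dominance
  count (C++) so nulls of $10^5$–$10^7$ pairs stay cheap.
* One global seed drives every stage; sub-streams are derived with fixed
  offsets, and all tabular writers are deterministic, so a run manifest
  (config + seed) reproduces every output byte.
* Tests and the acceptance script run the discovery pipeline at desk
  scale — a few hundred to 2,000 SNPs and 100–200 Monte Carlo replicates,
  against the chip-scale 262,000 SNPs × 1,000 replicates — sizes chosen so
  the statistical properties (calibration, type-I, power ordering) are
  measurable with tight binomial error while the whole suite runs in
  about a minute.

## Limitations

The screen's operating characteristics are dominated by the pool-size
grid and the clamp: it is a detector of near-fixation frequency
differences, stringent but insensitive, and nothing in this package
changes that — it makes it measurable. Empirical probabilities are only
as honest as the null's frequency model; prefer `mode = "matched"` (or
"empirical") when judging significance of real selections, and treat
uniform-null probabilities as a ranking device. The Breslow–Day
discovery stratum is a rounded reconstruction from pool estimates and
should be read as descriptive, not inferential.
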