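---
title: "Methods: multimodal cfDNA cancer-signal detection and tissue-of-origin prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal cfDNA cancer-signal detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements: the
models and their assumptions, the tunable parameters with their defaults and
rationale, what the synthetic cohort generator does and does not emulate, the
numerical choices made where the design was genuinely open, and the known
limitations. It states no empirical result that the test suite does not
itself compute.

## The measurement model

Plasma cell-free DNA (cfDNA) from a cancer patient is an admixture: a
fraction TF (tumor fraction) of fragments derive from tumor cells, the rest
from normal turnover (mostly hematopoietic). Every modality in the package is
a different projection of that admixture.

**Methylation.** The observable at CpG site $j$ is a pair of counts
$(C_j, T_j)$ (cytosine = methylated, thymine = converted/unmethylated), with
level $\beta_j = C_j/(C_j+T_j)$. The expected plasma level is the linear
mixture $(1-\mathrm{TF})\,\beta^{\mathrm{healthy}}_j +
\mathrm{TF}\,\beta^{\mathrm{tumor}}_j$. Because single-CpG signals are noisy
at realistic depth, levels are aggregated over regions $R_i$ of contiguous
CpGs sharing a methylation status, by the average methylation fraction
$\mathrm{AMF}_i = \frac{1}{|R_i|}\sum_{j \in R_i} \frac{C_j}{C_j+T_j}$,
an unweighted mean over the member sites covered in that sample.

**Copy number.** Read counts in fixed genomic bins, depth-normalized and
divided by a healthy-reference median, have log2 ratio near 0 in healthy
samples; a segment gained in the tumor shifts the ratio by roughly
$\log_2(1 + \mathrm{TF}\cdot g/2)$ for a $g$-copy gain — small at screening
TFs, which is why bin-level calls are thresholded at 2 standard deviations of
the healthy reference and summarized as marker detection *frequencies* rather
than segmented profiles.

**Fragmentation.** Tumor-derived fragments run shorter than the ~166 bp
mono-nucleosomal mode of healthy cfDNA. The fragment size ratio (FSR) is the
per-window count ratio of short (strictly 80–150 bp exclusive) to long
(strictly 150–220 bp exclusive) fragments; the fragment size distribution
(FSD) is the genome-wide proportion vector over 5-bp bins on [80, 220).
The interval bounds are strict on both ends, so lengths 80, 150 and 220
belong to neither class; this mirrors the assay definition literally and is
covered by tests.

## Marker discovery

CpG sites are first filtered: mean coverage across healthy samples at least
3× (the aggregator is a package choice — the assay rule names "3× coverage in
healthy individuals" without one; a stricter every-sample variant is exposed
via `aggregate = "all"`), outside blacklist intervals, and off the sex
chromosomes (which would otherwise encode sex, and several cancer types here
are sex-specific). Methylation status uses the healthy-sample mean $\beta$
per site: unmethylated = strictly below the 10th percentile of site means
*and* below 0.5; methylated = strictly above the 90th percentile *and* above
0.5; else neutral. The percentile reference distribution is "across sites",
ties lose (strict inequalities), and the decile/0.5 conditions are read as a
conjunction; all three conventions are documented package decisions where the
assay description is ambiguous. Regions are maximal same-status runs, split
at chromosome boundaries, with at least 3 CpGs.

Differential methylation uses Welch (unequal-variance) two-sample t-tests on
AMF — the unequal-variance form matters because cancer-group variance is
inflated by TF heterogeneity — with Benjamini–Hochberg adjustment within each
comparison family and retention at q < 0.05. Direction is hyper when the
cancer-side mean is larger. Three comparison settings exist: tumor tissue vs
adjacent normal, one cancer type vs the other cancers (used for
tissue-of-origin markers), and cancer cfDNA vs healthy cfDNA (used for
cancer-signal markers). Where matched tissue exists, cfDNA markers must agree
in direction with tissue markers (the concordance filter); types without
tissue keep their cfDNA markers, flagged. The cancer-signal marker set is the
union over types.

## Copy-number markers and the exclusion rule

Alterations are strict exceedances of mean ± 2σ per bin, with the reference
mean/σ from training healthy samples only. Two hardening choices proved
necessary and are deliberate deviations from a naive reading:

* **Moderated variance.** With a small reference panel the per-bin σ̂ is
  noisy, and marker selection couples to that noise: bins with
  underestimated σ over-call in *every* cohort, pass the cancer-prevalence
  test, and then inflate healthy false calls at test time. Per-bin variance
  is therefore shrunk toward the median bin variance with prior degrees of
  freedom equal to the panel size (the moderation idea familiar from
  empirical-Bayes differential expression).
* **Leave-one-out reference scoring.** A panel member compared against
  statistics that include itself is optimistically deflated; panel members
  are scored against leave-one-out mean/variance so their call rates are
  exchangeable with non-panel samples.

Marker selection then excludes bins altered (either direction) in more than
α% of healthy controls — the clonal-hematopoiesis guard — and retains
(bin, direction) pairs with healthy frequency strictly below α% and
prevalence strictly above β% in at least one cancer type. Defaults α = 5
(the assay names 5% or 10% as examples) and β = 20 (unstated in the source;
chosen once as a prevalence at which a recurrent arm-level event is
credible). Loss markers are included symmetrically with gains (toggleable via
`directions =`). β = 100 is allowed and yields an empty set (an impossible
prevalence), reconciling the assay's boundary example with its error
contract. The CNV cancer-signal score is the fraction of markers detected in
a sample; the open question of whether the CNV modality enters the ensemble
as this marker-frequency score or as a classifier probability is resolved in
favor of the marker-frequency score (the assay describes its single-feature
scores "excluding CNV"), with the CNV nine-class classifier used only for
tissue-of-origin conditional probabilities.

## Classifiers

Each feature (AMF over selected marker regions, CNV marker-detection
indicators, standardized FSR windows, standardized FSD bins) trains a
nine-class model — healthy plus eight cancer types in fixed alphabetical
order — selected by stratified fourfold cross-validation on macro
one-vs-rest AUC, ties broken by candidate order, winner refit on all
training data. The candidate pool is ridge multinomial regression, lasso
multinomial regression (each with a small lambda grid evaluated inside the
CV loop) and linear discriminant analysis; the AutoML-style pool of the
original assay (random forest, boosting, SVM) is not available in the target
environment, and regularized linear models are well matched to the
p ≈ n, strongly collinear feature blocks involved. Out-of-fold probabilities
of the winning candidate are retained: all downstream ensemble fitting uses
them, never in-sample predictions.

The cancer-signal score of a nine-class probability vector is the cancer
mass $1 - P(\mathrm{healthy})$; tissue-of-origin conditioning renormalizes
the eight cancer probabilities (uniform fallback, flagged, if all are zero).

## The CSE ensemble

Per-feature scores are logit-transformed with clipping constant
$\varepsilon = 10^{-6}$ (so boundary probabilities stay finite), joined with
age (years, unscaled) and sex (0 = F, 1 = M), and fed to logistic
regression. The fit carries a light ridge penalty (λ = 0.01): on
well-powered synthetic cohorts the logit scores are completely separable, the
unpenalized maximum-likelihood estimate diverges, fitted probabilities
collapse to exactly 0/1, and a specificity threshold loses meaning. The
penalty is a numerical stabilization, not a model change.

**Threshold calibration.** The decision threshold is the smallest observed
healthy ensemble score whose strict exceedance fraction is at most
1 − target specificity (default 0.95); calls are strict (`score >
threshold`), so a sample exactly at threshold is negative. Calibration uses
a held-out third of the ensemble-eligible training healthy samples that no
fitting stage touches (not markers, not the CNV reference, not the
classifiers, not the meta-model): scores that have passed through any
selection step are systematically left-shifted relative to test-sample
scores (selection optimism), and in-sample calibration measurably misses the
specificity target. When fewer than 10 eligible healthy samples exist, the
package falls back to calibrating on out-of-fold training scores
(`calibrate = "oof"`).

Ensemble training restricts healthy controls to age ≥ 50 — the screening
population — while marker discovery uses all healthy samples; with an
old-only healthy arm the age coefficient does not extrapolate meaningfully
below 50, a documented limitation. Tissue-of-origin prediction averages the
four features' conditional probability vectors with weights proportional to
each feature's out-of-fold top-1 accuracy on training cancer samples (the
assay says "weighted ensemble" without a rule; accuracy-proportional weights
are the simplest data-driven choice, with uniform weights available).
The two largest aggregated probabilities give top-1/top-2 calls; a gap
strictly below δ = 0.07 flags the sample "in between". Ties break by class
label order, deterministically.

## The synthetic cohort: a stated world

The generator emulates: healthy plus eight cancer types at stages I–IV with
per-stage truncated-normal TF (means 3/5/8/12%, matching the observation
that early-stage samples mostly sit below 5% while advanced stages shed
more); beta-binomial methylation counts (concentration 50, coverage
Poisson around 30×) over a block-structured methylome with planted
type-specific DMR blocks whose baselines sit strictly inside the decile
extremes (so the assay's own status classification can find them — DMRs in
mid-methylated territory would be invisible to this assay by construction,
which is a property of the assay, not the simulator); negative-binomial bin
counts with TF-scaled multiplicative segment effects (log2 effect 0.8 at
TF = 1, between a one- and two-copy gain) and CHIP-like recurrent gains in
10% of individuals; and per-window fragment counts from a two-component
length mixture (healthy mode 166 bp, tumor mode 145 bp, σ = 10) with tumor
weight TF. Matched tumor/adjacent tissue pairs (purity 0.5–0.9) exist for
colorectal, liver and lung, exercising the concordance filter. Ages and sex
follow the screening-cohort demographics (breast/ovarian female, prostate
male and oldest, healthy split into <50 and ≥50 arms); a 2% low-coverage
site fraction and a small blacklist exercise the filters.

What it does **not** emulate — so a green test does not establish robustness
to: GC and mappability bias, spatial autocorrelation of fragmentation or
copy number, realistic chromosome coordinates, bisulfite conversion error,
batch effects, non-CHIP benign lesions, or inter-patient heterogeneity of
marker direction. Effect sizes (DMR Δβ = 0.6, one-to-two-copy gains,
21-bp fragment mode shift) were fixed once at values a reviewer of this
literature would call typical for *selected markers* and are not tuned to
reproduce any published performance number; the tests assert qualitative
properties (recovery, calibration, monotonicity, ranking), not headline
sensitivities.

## Numerical choices and degenerate inputs

* Logit clipping ε = 10⁻⁶; probabilities tolerate ±10⁻⁸ float overshoot.
* Zero-sd features standardize to 0; AMF values missing for a sample
  (uncovered region) enter models at the training mean.
* Zero-σ copy-number bins call on strict inequality against the mean.
* A region identical across groups gets p = 1 (never selected); zero
  pooled variance with a nonzero mean difference gets p = 0.
* FSR windows with zero long-fragment count are missing and recorded;
  FSD with zero in-range fragments is an error naming the sample.
* Stratified split: `round(ratio × n)` per stratum, singleton strata to
  train, seeded and deterministic.
* glmnet fits always run along a decreasing lambda path (a lone small
  lambda can fail to converge in coordinate descent).
* All coordinates are 0-based half-open; BED files are native.

## Known limitations

Per-window fragment counts are independent across windows; the FSD "30 bins"
figure sometimes quoted for this feature family disagrees with the 28 bins
implied by 5-bp binning of [80, 220) — 28 is implemented. The CNV path does
not segment (no CBS) and does not estimate TF; the simulator supplies ground
truth TF instead of an ichorCNA-style estimator. Single-feature models are
trained on all training samples (including healthy < 50); only the ensemble
applies the age restriction. Threshold calibration quality is bounded by the
calibration-arm size — with tens of healthy samples the realized specificity
has binomial noise of several points, which is why the calibration
acceptance test runs at n ≥ 300. No missing-feature imputation exists:
samples failing a feature stage are reported, not silently dropped.
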