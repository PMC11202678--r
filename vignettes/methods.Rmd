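---
title: "Genomic prediction of pre-harvest sprouting resistance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction of pre-harvest sprouting resistance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phsgp)
```

## The problem

Pre-harvest sprouting (PHS) — germination of mature grain on the ear before
harvest — degrades winter-wheat quality through α-amylase-driven starch
breakdown, visible as a drop in the falling number (FN, in seconds). Because
sprouting is only expressed under wet pre-harvest weather, the traits used to
select against it (sprouting scores, germination index, falling number after
rain) vary strongly across years and locations, which limits heritability
and therefore genomic prediction across seasons. `phsgp` implements the full
quantitative-genetic analysis chain for this problem in breeding
populations: trial-level variance-component estimation from unreplicated
augmented designs, GBLUP prediction of breeding values with optional
fixed-effect weighting of known PHS resistance QTL — above all the major
dormancy locus on chromosome 4A (*Phs-A1*, candidate gene *TaMKK3-A*) — and
the cross-validation and across-season machinery needed to compare models.
Because breeding data of this kind are proprietary, the package ships a
synthetic cohort generator that reproduces the statistical structure of such
a program, so every stage is testable end to end.

## Trait statistics from augmented trials

Plot-level records come from unreplicated augmented designs: each location
has `n_blocks` (default 10) blocks, three replicated check varieties appear
once per block, and each breeding line appears once per location. Three
estimators operate on these records.

**Germination index.** For daily germination counts $n_1,\dots,n_D$ out of
$n_{total}$ seeds over a $D$-day window (default 6),
$$GI = \frac{\sum_{d=1}^{D}(D-d+1)\,n_d}{D\,n_{total}} \in [0,1],$$
so a seed germinating on day 1 carries weight $D$ and one on day $D$ weight
1. This is the standard weighted form; the window divisor can be changed via
`n_days`. GI is exactly 1 if all seeds germinate on day 1 and 0 if none
germinate, and moving any germination one day earlier can never decrease it
(verified exhaustively in the tests).

**Repeatability** (per environment): REML fit of
`value ~ (1|line) + (1|block)`; $rep^2=\sigma^2_g/(\sigma^2_g+\sigma^2_e)$.
The replicated checks supply the error degrees of freedom. Within a single
environment the genotype-by-location interaction is confounded with the
genetic variance, so the "genetic" component here is their sum.

**Heritability and adjusted means** (per season, across locations): the
all-random model
`value ~ (1|line) + (1|location) + (1|location:block) + (1|line:location)`
gives the entry-mean heritability with one unreplicated plot in each of $L$
locations,
$$h^2=\frac{\sigma^2_g}{\sigma^2_g+\sigma^2_{g\times loc}/L+\sigma^2_e/L}.$$
Misallocation between $\sigma^2_{g\times loc}$ and $\sigma^2_e$ (they are
poorly separated when only checks are replicated) is harmless here because
both enter divided by $L$. Adjusted means (the observed breeding values fed
to GBLUP) use the same structure with genotype *fixed* and location fixed
under sum-to-zero contrasts, so each line coefficient is its mean at the
average location. Genotype is deliberately fixed for the means: random
genotype would shrink them and the GBLUP step would then shrink twice.

These small crossed/nested models are fitted with `lme4` (the standard tool
for exactly these models) under a tightened BOBYQA optimizer
(`rhoend = 1e-10`), which makes REML agree with closed-form ANOVA
method-of-moments estimators to ~1e-7 on balanced designs. Records are
sorted into a canonical order before fitting so results cannot depend on row
order. If a fit is degenerate (e.g. noise-free data, where lme4's solver
fails), the estimators fall back to the fixed-effects least-squares fit and
flag the result. Variance components are bounded at zero by REML itself;
ratios are clamped to $[0,1]$ and the clamping is recorded.

## Genotypes and kinship

Genotypes are biallelic SNP dosages. `recode_minor_allele()` orients every
marker to count minor-allele copies (0/1/2); `qc_filter()` applies the
panel's rules — drop lines with more than 20% missing calls or heterozygote
excess (heterogeneity in F6 material; threshold 12.5%, far above the ~3%
F6 expectation), keep markers with MAF strictly above 0.01 and missingness
strictly below 5%, and collapse exactly duplicated marker columns. The
duplicate representative is the smallest marker id, which makes the retained
set independent of column order. Remaining missing calls are filled by
Binomial(2, $\hat p$) draws under a fixed seed.

The kinship is the first VanRaden genomic relationship matrix
$$A=\frac{ZZ'}{2\sum_j p_j(1-p_j)},\qquad Z_{ij}=d_{ij}-2p_j,$$
with centering frequencies estimated once on the full genotyped panel and
reused everywhere, so cross-validation folds share a single precomputed
kinship. Column centering forces $A\mathbf 1=0$; in inbred material the
diagonal averages close to 2 rather than 1 (dosage variance is
$2p(1-p)(1+F)$), which matters when interpreting $\sigma^2_t$.

## The prediction core

The central model, fitted by `gblup()`, is
$$y = X\beta + t + e,\qquad t\sim N(0, A\,\sigma^2_t),\qquad
e\sim N(0, I\,\sigma^2_e),$$
with $y$ the per-line adjusted means. In model 1, $X$ is the intercept; the
model-2 variants add minor-allele dosage columns for covariate markers: the
full 17-marker PHS QTL panel (`model2_qtl17`), the three *Phs-A1*-region
markers (`model2_phs`), or the three markers tagging the T1RS.1BL
translocation and the dwarfing genes *Rht-B1*/*Rht-D1*, which affect falling
number per se (`model2_rht`). Aliased columns are removed by pivoted QR at
tolerance 1e-8 and recorded.

REML is computed in the eigenbasis of $A$: with $A=UDU'$, rotating by $U'$
makes the covariance diagonal, $\sigma^2_e(\lambda d_i+1)$ with
$\lambda=\sigma^2_t/\sigma^2_e$. $\beta$ and $\sigma^2_e$ profile out
analytically, leaving a one-dimensional restricted likelihood in
$\log_{10}\lambda$ that is maximized over $[10^{-6},10^6]$ by a 41-point
grid bracket followed by Brent search (tolerance 1e-10). The grid bracket
guarantees the optimizer cannot be beaten by any point of a dense grid
oracle (a property the tests assert against an independent dense-matrix
likelihood implementation). Negative eigenvalues beyond $-10^{-8}$ (a
non-PSD input) trigger a logged ridge of $10^{-6}$ on the diagonal; the
routine zero-clipping of numerically tiny negative eigenvalues needs no
ridge, which keeps identities such as "a duplicated line gets exactly its
twin's breeding value" exact. Breeding values are
$\hat t = \sigma^2_t A V^{-1}(y-X\hat\beta)$, and predictions for
unphenotyped lines use the conditional expectation
$\hat t_{new}=\sigma^2_t A_{new,train}V^{-1}(y-X\hat\beta)$ — algebraically
identical to $A_{cross}A_{train}^{-1}\hat t_{train}$ but defined even when
$A_{train}$ is singular. GEBVs are $X\hat\beta+\hat t$. The tests verify the
classic GBLUP–RRBLUP identity: with $A=ZZ'/d$, these breeding values equal
ridge-regression marker-effect predictions at the matched ridge
$d\,\sigma^2_e/\sigma^2_t$ to 1e-6.

## Evaluation machinery

`make_folds()` builds the within-season scheme: 10 replicates of 5-fold CV,
stratified so every breeding program is split into five nearly equal sets —
both estimation and test sets always contain lines from each program, and
fold sizes within a program differ by at most one (programs smaller than
$k$ simply contribute nothing to some folds, with a message).
`cross_validate()` refits the model in every one of the 50 runs (variance
components re-estimated per training fold, the standard behaviour of
kinship-based prediction pipelines) and records the predictive ability
$r(y_{TS},\hat g_{TS})$ as a Pearson correlation; undefined correlations
(constant predictions or phenotypes) become `NA`, are excluded from means
and logged. Reusing one fold plan across model variants pairs the 50 runs,
and `compare_models()` applies the Student's paired *t*-test over per-run
differences with the usual significance stars. Runs within a replicate are
dependent, which the paired *t*-test ignores (as is conventional); the test
suite calibrates directional claims over independent simulation seeds
instead of trusting the nominal type-I rate.

`cross_season_predict()` implements the across-season scenarios: calibrate
on all lines of one season ($N_{ES}=298$ in the default cohort), predict
either the calibration-set lines' other-season means ($N_{TS}=199$) or the
other season's independent validation set ($N_{TS}=99$), and additionally
correlate the CS lines' raw means across seasons (OBV–OBV) against the
correlation of their per-season GEBVs (GEBV–GEBV). `haplotype_analysis()`
groups lines by the two-locus homozygous haplotype at the major-locus
marker pair (missing or heterozygous calls excluded and counted) and runs
pairwise Welch *t*-tests under Bonferroni correction at $\alpha=0.05$ —
the paper-style check that one haplotype class carries significantly lower
falling-number stability.

## The synthetic cohort

`population_spec()` defaults describe the study conditions: 400 F6 lines
from six breeding programs (80/80/80/94/20/46), split into a 200-line
calibration set phenotyped in both seasons and two 100-line single-season
validation sets, with set membership spread across programs. Genotypes are
6,250 independent biallelic loci: each marker's ancestral minor-allele
frequency is uniform on (0.01, 0.455) — chosen so the realized panel mean
MAF is ≈0.233 — program frequencies diverge by a Balding–Nichols Beta model
with $F_{ST}$-like parameter 0.02 (weak structure, as the cohort's PCA
showed), and genotypes are drawn at an inbreeding level giving 1% residual
heterozygosity. Markers whose realized MAF leaves the bounds are redrawn, so
the generated panel passes MAF QC untouched. Three lines receive 25%
missingness so that QC reproduces the 400 → 397 line bookkeeping (one line
lost per set).

The QTL architecture mirrors the tracked marker panel: 17 sprouting-QTL
markers in 11 groups, including a three-marker major locus on the 4A block
whose first two markers are adjacent and define the haplotype pair, plus
three falling-number loci (T1RS.1BL/*Rht* analogues) on their own
chromosomes. Effects are scaled on the realized genotypes so the major
locus carries exactly its target share (default 30%) of a unit genetic
variance for sprouting traits, with a polygenic background of 300 markers;
falling-number-per-se traits instead give 25% to the three fn loci and
nothing to *Phs-A1*, reproducing the paper's contrast between the two trait
classes. The two major-locus markers are simulated as independent loci
(there is no LD model), so up to four haplotype classes can be observed
rather than exactly three; class frequencies still make the analysis
exercisable.

Phenotypes follow the generating model the estimators assume,
$y=\mu+loc+block(loc)+g+g\times loc+e$, with the residual variance
back-solved from a per-trait target heritability:
$\sigma^2_e=L\,\sigma^2_g(1/h^2-1)-\sigma^2_{g\times loc}$. The default
trait set matches the study's five traits at their reported heritability
levels (LS 0.66 on an ordinal 1–9 scale, GI 0.75 in [0,1], FN1 0.62,
FN2 0.77, FNS 0.86, FN traits in seconds around 250–300 s). The paper
reports no variance components, so the location/block/interaction
magnitudes (0.5/0.2/0.2 × $\sigma^2_g$) are the package's own choice of a
realistic multi-environment regime; they were fixed once against the
reported heritability and repeatability ranges. Germination is simulated
per seed with a geometric daily hazard, so a propensity of 0 yields no
germination, 1 yields full day-1 germination, and GI is stochastically
increasing in propensity.

**What the generator does not emulate.** There is no linkage disequilibrium,
no genetic map or recombination, no weather or dormancy process, and no
spatial field trend. The most visible consequence: with 6,250 *independent*
markers the effective number of genome segments is the marker count itself,
so purely genome-wide (model 1) predictive abilities on the synthetic
cohort are substantially lower than the 0.48–0.65 a real LD-rich panel
attains, while models that weight the causal QTL recover most of the
signal. Tests that check predictive-ability *levels* therefore tune the
marker count (600–2,000) so the effective dimensionality matches what dense
LD-rich panels realize; directional claims (model 2 beats model 1 under a
major QTL; independent validation sets predict worse than re-evaluated
calibration lines; GEBV–GEBV correlations exceed OBV–OBV) are asserted at
the study scale. Passing tests show the estimators and machinery are
correct under the stated generating model, not that real data would give
the same numbers.

## Numerical choices and degenerate inputs

* $\lambda$ search bounds $[10^{-6},10^6]$; grid bracket + Brent, tolerance
  1e-10 on $\log_{10}\lambda$; profile likelihood unimodality is not
  assumed beyond the bracket.
* Zero residual variation (e.g. a constant phenotype vector) cannot be
  profiled; `gblup()` returns an OLS fallback flagged `converged = FALSE`
  with zero genetic variance, which downstream CV records as an undefined
  predictive ability rather than failing.
* The noiseless limit $\lambda\to$ upper bound is only identifiable when
  $\mathrm{rank}(A) < n - p$; with more markers than lines REML legitimately
  settles at a finite ratio.
* MAF thresholds are strict inequalities; MAF is computed on non-missing
  calls.
* Ties in fold allocation are resolved by randomized balanced labels, so
  remainders do not systematically favour low-numbered folds.
* All randomness flows through explicit integer seeds; reruns of
  `run_pipeline()` with the same configuration are bit-identical
  (md5-verified in the manifest).

## Pipeline problem sizes

The default configuration runs the full cohort (400 lines, 6,250 markers,
two seasons, five traits, four model variants, 10×5-fold CV). The package's
own test suite and the bundled acceptance script run reduced but
structurally identical configurations (two traits, two to three model
variants, or fewer markers) — the statistical structure, not the volume, is
what the checks depend on.
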