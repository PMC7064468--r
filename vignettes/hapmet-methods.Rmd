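---
title: "HapMET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HapMET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

HapMET analyses grain yield (GY) and yield stability in multi-environment
trials (METs) of fully inbred crop lines, the setting typical of spring
bread wheat breeding programmes: cohorts of advanced lines (an "EYT", one
elite yield trial cohort per year) are grown in several contrasting
environments — irrigated, drought-stressed, heat-stressed — in small
alpha-lattice experiments with repeated check varieties, and genotyped with
sparse, partially missing genotyping-by-sequencing (GBS) markers. The
package covers the full path from plot data and raw SNPs to haplotype-based
association results and genomic prediction. This vignette documents the
models, the tunable parameters, and the design decisions taken where the
method family genuinely leaves choices open.

## Phenotype adjustment

Each combination of cohort and environment is one *trial*. Within a trial,
GY plot values are adjusted for incomplete-block effects with a
moving-check correction: for every block $k$ inside replicate $r$, the
deviation of the block's check mean from the trial-wide check mean is
subtracted from all entry plots in that block, and entry means are taken
over replicates. Only the check plots drive the correction, so with
constant checks the operator is the identity; a block without a check is a
hard error naming the block. The correction is additive; a GLM-covariate
variant would need plot covariates the record format does not carry.

Covariate traits measured on different trial scales (days to heading DH,
plant height PH) are put on a common scale with the check-mean formula
$Y = (Y_{ij} - Y_i) + Y_{\mathrm{all}}$, where $Y_i$ is the mean of the
trial's checks and $Y_{\mathrm{all}}$ the check mean over all trials.

The factorial ANOVA fits `value ~ Rep + Geno + Env + Geno:Env` by least
squares with all factors fixed, each term tested against the single
residual mean square. Broad-sense heritability on an entry-mean basis is
derived from the expected mean squares of the same fit,

$$H^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{GE}/e +
\sigma^2_\epsilon/(er)}, \qquad
\sigma^2_G = \frac{MS_G - MS_{GE}}{re}, \quad
\sigma^2_{GE} = \frac{MS_{GE} - MS_\epsilon}{r},$$

with $e$ environments and $r$ replicates. Negative component estimates are
clipped at zero with a warning and $H^2$ is clipped to $[0, 1]$. The
clipping gives the estimator a small positive bias near $H^2 = 0$ on small
designs; the null-case test therefore uses several hundred lines, where the
bias is a few percent.

## Stability indices

Two per-line stability measures are computed from adjusted means across
the environments of one cohort:

* **Lin–Binns superiority index** $P_i = \sum_j (X_{ij} - M_j)^2 / (2E)$,
  with $M_j$ the best line in environment $j$. The denominator $2E$
  follows Lin & Binns (1988); variants with $2(E-1)$ exist, so the choice
  is stated prominently here and in the help page. $P_i = 0$ exactly when
  a line is best everywhere; low $P_i$ identifies lines that are both
  high-yielding and stable.
* **Eberhart–Russell regression**: each line's means are regressed on the
  environmental index $I_j$ (environment mean minus grand mean). The
  slope $b_i$ ($b_i = 1$ is average stability) is reported as "the ER
  coefficient", with the mean squared deviation from the regression as an
  auxiliary column — the literature uses both parameters and rarely says
  which; the slope is the conventional reading of "coefficient".

`stabilityVsMean()` reports the Pearson correlation of mean GY with $-P_i$
(sign flipped so "positive = high-yielders are also superior/stable") and
with $b_i$.

## Haplotype blocks from D′ confidence intervals

SNPs are first filtered to at most 40% missing data and minor allele
frequency ≥ 0.15 — the MAF floor is deliberately high because blocks are
built on all cohorts pooled, and a pooled MAF of 0.15 keeps per-cohort MAF
above about 0.05. Heterozygous calls in these fully inbred lines are
treated as missing for LD and haplotype calling: residual GBS
heterozygosity is noise, and no imputation is done anywhere.

For each SNP pair, phased haplotype counts (phase is known in inbreds)
give $D' = |D|/D_{\max}$, and a 95% confidence interval is obtained by
evaluating the multinomial likelihood of $|D'|$ on a grid of 101 points in
$[0,1]$ with allele frequencies fixed at their sample estimates; the
bounds are the 5th and 95th cumulative-likelihood percentiles. This is the
Haploview/Gabriel-style estimator; grid resolution is configurable. Pairs
are classified as **strong LD** (CI lower bound ≥ 0.6 *and* upper bound ≥
0.95), **strong recombination** (upper bound < 0.9, the Gabriel
convention; only the strong-LD thresholds are fixed by the method, so the
0.9 is configurable), or **inconclusive** otherwise.

A contiguous span of ≥ 2 SNPs qualifies as a haplotype block when at least
95% of its *informative* (non-inconclusive) pairwise comparisons are in
strong LD and at least one comparison is informative. Qualifying spans are
accepted greedily — longest first, leftmost on ties — without overlap, and
capped at a configurable 50-SNP window for tractability. Blocks are named
`HB<chromosome>.<serial>` with the serial increasing along the chromosome.
On panels of ≤ 12 SNPs the implementation is checked against an exhaustive
span-enumeration oracle applying the identical rules.

Within a block, a line's haplotype allele is the concatenated base string
of its member SNPs; a single missing or heterozygous member makes the
whole block missing for that line. Alleles below a 5% frequency floor
(inferred from the pooled-MAF logic above; configurable) are pooled into a
rare class and excluded from the incidence columns. The result is a binary
line × haplotype-allele matrix with at most one 1 per line per block.

## Mixed-model association mapping

Per-trial scans use the mixed linear model
$y = X\beta + m\alpha + Zu + \epsilon$ with $u \sim N(0, K\sigma^2_g)$,
where $K$ is the VanRaden genomic relationship matrix
$ZZ'/(2\sum_k p_k(1-p_k))$ built from 0/1/2 dosages centered by $2p_k$
(missing calls contribute zero after centering; on a fully inbred panel
the mean diagonal is near $1 + f = 2$ on this outbred scale). Fixed
covariates are principal components of the centered genotype matrix — the
number of PCs is chosen by the BIC of the phenotype-on-PCs regression,
$k = 0..k_{\max}$ — plus optional phenology covariates (DH, PH as
line-level adjusted means of the same trial) and major-gene marker calls.

Variance components are estimated once per trial by REML on the null
model through a single eigendecomposition of $K$ (EMMA-style), and the
ratio $\lambda = \sigma^2_g/\sigma^2_e$ is reused for every marker — the
P3D/EMMAX approximation; exact per-marker REML is available behind
`exact = TRUE` at a large time cost and negligible p-value drift. Marker
p-values are F-tests on the whitened scale; marker $R^2$ is the marker
sum of squares over the total sum of squares on that scale. With $K = I$
the scan reduces exactly to ordinary least squares, which is asserted in
the tests. Note a desk-scale caveat checked in the tests: with only a few
dozen markers in $K$, the tested block dominates the kinship and the scan
loses power (proximal contamination); at realistic marker densities the
effect is negligible.

Haplotype blocks are tested with an omnibus F-test of the block's common
allele columns (most frequent allele dropped as reference; $a-1$ degrees
of freedom for $a$ alleles) in the same whitened model. Lines with a
missing or rare-pooled block call carry all-zero incidence and act as
reference-level observations. Per-allele effects are reported
descriptively as carrier mean minus block mean, absolute and as % of the
trial mean. The omnibus block $R^2$ is never below the $R^2$ of any member
SNP on the same data (a nesting property, tested).

No significance threshold is fixed by the method family; the default is
Bonferroni at $\alpha = 0.05$ over the tested loci and it is prominently
configurable. Per-trial results are never combined across trials for
multiple testing; only the consistency-group classifier aggregates:
group 1 = significant in a single cohort; group 2 = strictly one
environment across ≥ 2 cohorts; group 3 = ≥ 2 cohorts and ≥ 2 environments
within each significant cohort; group 4 = ≥ 2 cohorts, varying
environments.

## Epistasis scans

Two- and three-locus interactions are tested by ordinary least squares on
adjusted means: main effects (plus all two-way products for order 3)
against the model with the highest-order interaction term, an F-test of
that term, reporting tuples with $p < 0.001$. Kinship is deliberately not
included in the default interaction model (a kinship-adjusted variant can
be built by pre-whitening); the additional variance is the *sequential*
$\Delta R^2 = R^2_{\mathrm{full}} - R^2_{\mathrm{mains}}$, mains first.
Tuples with any genotype-combination cell under 5 observations are skipped
with a reason. Genome-wide scans are intended to be pruned to one locus
per block to bound the pair count.

## Genomic prediction

Four relationship matrices feed the G-BLUP models:

1. additive marker kernel $G_M = MM'$ from the $\{1, 0, -1\}$ codes;
2. haplotype-sharing kernel $G_H = HH'$ from the binary incidence matrix;
3. marker Gaussian kernel $G_{ij} = \exp(-D_{ij}/\theta)$ with
   $D_{ij} = [(1/4m) \sum_k (S_{ik}-S_{jk})^2]^{1/2}$ — the $1/(4m)$
   normaliser maps marker distances into $[0,1]$ because opposite
   homozygotes differ by 2;
4. haplotype Gaussian kernel, identical except the normaliser is $1/m$ so
   that binary scores also span $[0,1]$ — a deliberate deviation from the
   marker formula, which is written for $\{1,0,-1\}$ scores and would
   compress binary distances to $[0, 1/2]$.

$\theta$ is not fixed by the method family; the default is the median
off-diagonal distance (a standard self-tuning heuristic), configurable.
$G_M$ and $G_H$ are rescaled to unit mean diagonal by default. Epistasis
enters models 2–4 as an additional RKHS random term; its kernel is the
haplotype Gaussian kernel for model 2 and the Hadamard square of the main
(already Gaussian) kernel for models 3–4, the classical
additive-by-additive construction — duplicating the main Gaussian kernel
as its own epistasis term would be unidentifiable.

The mixed model $y = X\beta + \sum_k Z u_k + \epsilon$ stacks adjusted
means over the environments of one cohort, with one fixed intercept per
environment plus optional predefined locus columns (haplotype incidence
with the reference allele dropped, or marker dosages; collinear columns
are pruned by QR with a warning). Inference is a Gibbs sampler: flat
priors on fixed effects, independent $u_k \sim N(0, K_k\sigma^2_k)$, and
scaled-inverse-$\chi^2$ priors (df 5, scales set from half the phenotypic
variance, split across terms) on all variances. Each kernel is
eigendecomposed once on the training lines and its effect is sampled in
the eigenbasis, where the conditional precision is diagonal for balanced
designs — this is what makes repeated cross-validation affordable. Default
chain: 6,000 iterations, 1,000 burn-in, seeded and bit-reproducible;
shorter chains are used inside cross-validation where only posterior-mean
predictions are needed. Non-PSD kernels are bent (eigenvalue floor 1e-6)
with a warning; a variance draw exceeding $10^6$ times the phenotypic
variance aborts as divergent. A closed-form REML/ridge path
(`gblupRidgeOracle`) serves as the deterministic single-kernel oracle; the
sampler's posterior-mean predictions correlate ≥ 0.999 with it in the
tests.

Cross-validation follows the stricter whole-line reading of "90/10 within
each cohort": each repeat masks a random 10% of *lines* in every
environment (prediction of untested genotypes, CV1), refits, and records
the Pearson correlation between observed and predicted values over the
test observations; means and standard deviations are taken over repeats.
Note that with environment intercepts in the model, pooled-across-
environment correlations carry the environment-mean signal for every
model alike; model comparisons are therefore always made on *paired*
splits — the split sequence is derived from the seed alone and its hash is
compared before any contrast — with a least-significant-difference at
$\alpha = 0.05$ from the paired-repeat variance.

## The synthetic-data generator

The generator reproduces the statistical structure the analysis assumes,
not the biology: chromosomes are tiled with LD blocks of 2–9 SNPs; within
a block every line inherits one haplotype from a pool of 2–4 founders
(strong within-block D′, near-zero between-block LD — exactly the regime
the D′-CI block finder assumes, which is why no coalescent machinery is
needed); rejection sampling enforces the MAF floor; missingness is
injected uniformly at random so the 40% filter is exercised. Defaults
emulate the five-environment setting: environment means of 7.0, 6.7, 3.9,
2.5 and 3.5 t/ha (two irrigated regimes, mild and severe drought, heat),
three replications, incomplete blocks with one plot of a repeated check in
every block (two checks alternating), genetic standard deviation 400
kg/ha, replicate and field-block effect SDs of 100 and 200 kg/ha, and
strong G×E (line-by-environment deviation SD equal to 0.8 of the genetic
SD) — heritability targets in the 0.27–0.63 range then land in the
realistic band. Additive QTL are specified as (locus, per-environment
effect pattern, variance share) and scaled internally; two-locus epistasis
as coded products; checks are designated entries with fixed genetic values
not driven by any QTL, so the check-based adjustment can be tested against
known truth. The polygenic background is *marker-driven* — iid normal
effects on the genotyped markers, rescaled to its variance share, with
markers of QTL-hosting blocks excluded so planted shares stay
interpretable — because a background invisible to every genomic kernel
would make prediction models untestable. A QTL can alternatively be
attached to a haplotype allele (an observed member-SNP string) rather
than a genotyped SNP: by default the generator picks the common string
class least tagged (multiple $R^2$) by its member SNPs, emulating an
ungenotyped causal variant; note that a string-class indicator is linear
in the member SNPs unless the block carries more common strings than
SNPs + 1 (e.g. a 2-SNP block with all four corners common, where one
corner is a SNP×SNP interaction).

Two modelling stand-ins are worth naming. First, the line-by-environment
deviation is Gaussian by choice, not by inference — nothing in the MET
setting pins down that distribution. Second, the residual variance is
tuned so that the *across-environment broad-sense* $H^2$ of the pheno
module's estimator matches `h2_target` (the formula above solved for
$\sigma^2_\epsilon$, floored at a small positive value); per-environment
plot heritabilities are then lower whenever G×E is strong, which matches
how MET heritabilities behave in practice.

What passing tests do and do not show: the generator has block-uniform LD,
Gaussian effects, and balanced designs, so passing recovery tests
demonstrates correctness of the estimators under their own assumptions —
not robustness to real-data features such as LD decay within blocks,
confounded population structure, non-Gaussian residuals, or unbalanced
multi-year layouts.

## Problem sizes and numerical choices

The test-suite and acceptance runs use desk-scale sizes chosen as the
smallest that make the statistical contracts sharp: oracle-equality checks
on 100–500 random tables/panels of ≤ 12 SNPs; calibration of the
mixed-model scan on 500 lines × 2,000 markers over 20 seeds; prediction
contrasts on 20 seeded datasets of 500 lines × 5 environments with 20
paired CV repeats and short (600-iteration) chains; heritability recovery
over 50 seeds of 100-line cohorts. Ties in greedy span acceptance are
broken longest-first then leftmost; positions are 1-based inclusive (VCF
convention) everywhere; all randomness flows from a single seed through
named per-stage substreams, so inserting a stage never perturbs another
stage's draws.

A property of the model family worth understanding before comparing
models on synthetic data: the Gaussian kernels are *rougher* (more
local) than the linear kernels — $\exp(-D/\theta)$ with a root-Euclidean
distance is a Matérn-1/2 covariance — so on a purely additive genetic
architecture the additive kernel $G_M$ is the efficient choice and the
Gaussian-kernel models pay a small but systematic accuracy penalty (of
the order of 0.01–0.02 within-environment correlation at a few hundred
lines in our test conditions). A single medium-effect locus carried as a
fixed effect recovers at most the locus's share of phenotypic variance
not already spanned by the kernel, which under strong G×E and plot noise
is of the same order. Haplotype-based models with fixed GWAS loci
therefore pull ahead of the additive base model only when the data carry
what they are built for — several robust loci treated as fixed effects,
allelic series and local (within-block) interactions that single markers
tag poorly, and non-additive variance for the RKHS terms — and not on a
clean additive simulation with one QTL. The package reports paired
comparisons either way; the generator can plant haplotype-borne hidden
variants (`qtl_spec = list(list(block =, ...))`) and two-locus epistasis
to explore the regimes where each model family wins.

## Known limitations

No spatial field models (row–column, AR1) or BLUP entry means; no
phasing/imputation for heterozygous material; no multi-environment G×E
covariance structures in prediction beyond environment intercepts; no
Bayesian variable-selection models; the exhaustive three-locus scan is not
meant for genome-wide use at real-data scale.
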