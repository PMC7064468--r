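# HapMET

Haplotype-based GWAS, yield-stability analysis and genomic prediction for
multi-environment trials (METs) of inbred crop lines.

Breeding programmes evaluate cohorts of advanced lines (elite yield
trials, EYTs) for grain yield (GY) across contrasting environments —
irrigated, drought-stressed, heat-stressed — in small alpha-lattice
experiments with repeated checks, and genotype them with sparse
genotyping-by-sequencing SNPs. HapMET implements the full analysis path
for this setting:

* **Phenotypes** — moving-check adjustment of plot data for
  incomplete-block effects, check-mean scaling of covariate traits,
  factorial ANOVA (`Rep + Geno + Env + Geno:Env`), and broad-sense
  heritability \(H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{GE}/e +
  \sigma^2_\epsilon/(er))\) from expected mean squares.
* **Stability** — the Lin–Binns superiority index
  \(P_i = \sum_j (X_{ij}-M_j)^2/(2E)\) and the Eberhart–Russell
  regression slope on the environmental index.
* **Haplotype blocks** — SNP filtering (≤ 40% missing, MAF ≥ 0.15),
  D′ with likelihood-grid 95% confidence intervals, strong-LD
  classification (CI bounds ≥ 0.6 and ≥ 0.95), and greedy block
  construction requiring ≥ 95% of informative pairs in strong LD;
  per-line haplotype-allele calling with rare-allele pooling.
* **Association** — EMMA-style mixed linear model with VanRaden kinship
  and BIC-selected principal components (P3D approximation per marker),
  single-SNP and omnibus haplotype-block tests, allele-effect summaries,
  and the four-group cross-trial consistency classification.
* **Epistasis** — two- and three-locus interaction scans (OLS F-tests at
  p < 0.001) with sequential ΔR².
* **Genomic prediction** — G-BLUP with four relationship matrices
  (additive \(MM'\), haplotype-sharing \(HH'\), and Gaussian/RKHS kernels
  \(\exp(-D_{ij}/\theta)\) on marker or haplotype scores), GWAS-derived
  loci as fixed effects, a seeded Gibbs sampler, and repeated 90/10
  whole-line cross-validation on paired splits.
* **Synthetic data** — a first-class generator reproducing the assumed
  structure (founder-pool LD blocks, alpha-lattice layouts with repeated
  checks, environment-specific QTL, strong G×E, target heritability) so
  every stage is testable offline with known truth.

## Worked example

```r
library(HapMET)

cfg <- simConfig(n_lines = 300, n_chrom = 2, snps_per_chrom = 20,
                 qtl_spec = list(list(locus = 3, effects = rep(1, 5),
                                      share = 0.10)),
                 h2_target = 0.5, seed = 42)
geno <- simulateGenotypes(cfg)
geno
#> SnpMatrix: 300 lines x 40 SNPs on 2 chromosome(s); 0.0% missing

sim <- simulateTrials(geno, cfg)
broadSenseH2(sim$records)
#> H2 = 0.499          # target was 0.5

adj <- do.call(rbind, lapply(unique(sim$records$env), function(e)
  adjustBlockEffects(sim$records, "EYT1", e)))

blocks <- buildBlocks(filterSnps(geno))
head(blocks[, c("name", "chrom", "n_snps", "start", "end")], 3)
#>    name chrom n_snps start  end
#> 1 HB1.1     1      2  1000 2000
#> 2 HB1.2     1      3  3000 5000
#> 3 HB1.3     1      4  6000 9000

callHaplotypes(filterSnps(geno), blocks)
#> HapMatrix: 300 lines x 23 haplotype alleles in 8 blocks

pi_res <- superiorityIndex(adj)
head(pi_res[order(pi_res$Pi), ], 3)
#>      line      Pi  mean_gy n_env incomplete
#> 135 L0135 1866767 6681.712     5      FALSE
#> 141 L0141 1970718 6649.577     5      FALSE
#> 296 L0296 2100611 6728.874     5      FALSE
```

The simulated heritability comes back at its target; the block finder
recovers the planted LD structure (blocks named `HB<chromosome>.<serial>`
along each chromosome); the lowest-`Pi` lines are the cohort's stable
top-yielders (`Pi` is in (kg/ha)², lower is better). Association and
prediction stages continue from these objects — `vanRadenKinship()` +
`mlmScanSnp()` / `mlmScanHap()` for per-trial scans, `modelKernels()` +
`crossValidate()` + `compareModels()` for the four prediction models; at
this toy marker count the kinship absorbs much of a planted QTL
(proximal contamination), which is discussed in the methods vignette
(`vignettes/hapmet-methods.Rmd`). `runPipeline()` drives all stages from
one YAML config with a single seed.

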