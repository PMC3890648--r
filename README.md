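# haplopop

Population genetics of haploid multilocus SNP genotypes.

`haplopop` is an R package for regional population-structure surveys of
predominantly selfing plants (and other effectively haploid material),
where each wild-collected accession is a single haploid multilocus SNP
genotype.  It implements, as one tested pipeline, the analyses such a
survey needs:

* **Genotype handling** — reading delimited genotype/map/metadata tables
  into an S4 `SnpGenotypes` container (a `SummarizedExperiment`), locus
  filtering with a reproducible per-filter report, multilocus haplotype
  collapsing (strict or wildcard missing-data matching), and STRUCTURE /
  Newick interchange.
* **Diversity** — gene diversity H_S = 1 − Σ p², percentage of
  polymorphic loci, and exact hypergeometric rarefaction estimators of
  allelic richness R_S and private allelic richness R_P at a common
  sample size g.
* **Differentiation** — Excoffier-style AMOVA on squared
  allele-difference distances (one- and two-level designs), with
  permutation p-values, pairwise F_ST, and net between-group distances.
* **Isolation by distance** — haversine geographic distances, Mantel
  tests with joint row/column permutation, and a label-permutation test
  for between-region differences in IBD strength.
* **Structure inference** — three routes: PCA with allele-frequency
  normalization, optional neighbour-locus LD regression and Tracy–Widom
  component selection followed by Ward clustering; a haploid admixture
  mixture model L = Σᵢ Σₗ log Σₖ q\_{ik} p\_{kl}^{x} (1−p\_{kl})^{1−x}
  fitted by multi-start EM, with BIC-style model evidence, replicate-run
  alignment (CLUMPP-style H′) and Wilcoxon-stepped K selection; and
  neighbor-joining trees with locus-resampling bootstrap.
* **Quantitative traits** — right-censoring imputation for flowering
  experiments, obligate-vernalization scoring, Q_ST = V_B/(V_B+V_W) by
  REML or expected mean squares, Tukey letter displays, and trait-range
  permutation tests.
* **Synthetic truth** — seeded Balding–Nichols island, hierarchical,
  stepping-stone, admixture and trait generators whose latent truth is
  returned, so every estimator is validated against known values.

See the methods vignette (`vignettes/haplopop-methods.Rmd`) for the
models, estimators, numerical choices and limitations.

## Worked example

Simulate a stepping-stone survey (8 demes on a transect, 6 accessions
each, 120 SNPs), filter, and run the core analyses:

```r
library(haplopop)

sim <- simulateSteppingStone(nPops = 8, samplesPerPop = 6, nLoci = 120,
                             spatialSigma = 0.6, seed = 42)
g <- filterLoci(sim$genotypes)
g
#> SnpGenotypes: 48 samples x 115 loci
#>   populations: 8; missing calls: 0.0%
#>   filtered: input=120, missingness=0, monomorphic=5, populationMissing=0, retained=115

head(diversityTable(g), 3)
#>   unit N NH       PL        HS      HS_se       RS      RS_se RP RP_se g
#> 1 pop1 6  6 81.73913 0.3280193 0.01645376 1.817391 0.03618456  0     0 6
#> 2 pop2 6  6 74.78261 0.3053140 0.01809466 1.747826 0.04067223  0     0 6
#> 3 pop3 6  6 75.65217 0.2927536 0.01733648 1.756522 0.04019651  0     0 6

amova(g, nPerm = 999, seed = 1)
#> AMOVA (one-level, 999 permutations)
#>            df      SS  sigma2 percent
#> amongPops   7 191.396  1.3050     6.3
#> withinPops 40 780.500 19.5125    93.7
#>   indices: FST=0.0627
#>   p-values: 0.001

gen <- geneticDistances(g, level = "population")
mantelTest(sim$geo, gen, nPerm = 999, seed = 2)
#> Mantel test (n = 8): r = 0.583 (r2 = 0.340), slope = 0.0001695, p = 0.001 (greater, 999 permutations)

runAdmixture(g, K = 2, replicates = 10, seed = 3)
#> RunEnsemble: K = 2, 10 runs, H' = 0.963
```

Each deme holds modest allele-frequency differentiation (F_ST ≈ 0.06,
significant by permutation), genetic distance rises with transect
distance (Mantel r = 0.58, p = 0.001), and replicate admixture runs at
K = 2 agree closely after label alignment (H′ = 0.96).  `runPipeline()`
chains all stages from one call and writes CSV/Newick reports;
`reportTables()` emits survey-style diversity and AMOVA tables.

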