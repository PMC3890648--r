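---
title: "Population-genetic methods in haplopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genetic methods in haplopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplopop)
```

# Scope and data model

`haplopop` analyses panels of biallelic SNPs typed on predominantly
selfing plants (or other effectively haploid material).  Because selfing
lines are near-completely homozygous, each accession is treated as a
single haploid multilocus genotype: one allele per locus, coded 0/1 with
`NA` for missing calls.  The central container, `SnpGenotypes`, extends
`SummarizedExperiment` with loci as rows, samples as columns, the call
matrix as the single assay, the sample hierarchy
(accession → population → group/region, plus coordinates) in `colData`,
and the SNP map (chromosome, position, panel of origin) in `rowData`.

The package covers the stages of a regional population-structure survey:
locus filtering, haplotype collapsing, diversity statistics with
rarefaction, AMOVA and pairwise $F_{ST}$, Mantel tests of isolation by
distance, three clustering routes with replicate-run alignment, and
quantitative-trait differentiation ($Q_{ST}$), together with seeded
generators that produce data with known truth for every stage.

# Filtering and haplotypes

`filterLoci()` applies its filters in a fixed order — missingness, then
monomorphism, then population-missingness — so that the per-filter counts
in the report are reproducible.  The order matters when a locus fails
several criteria; the fixed order attributes it to the first.

`collapseHaplotypes()` implements two matching rules.  Under `strict`,
missing is a state of its own and two samples share a haplotype only when
their call vectors are identical.  Under `wildcard`, samples match when
they agree wherever both are observed, closed transitively with a
union–find; a largely missing sample can then bridge otherwise distinct
haplotypes, so the wildcard count is never larger than the strict count.
`strict` is the default because it is deterministic under resampling and
reproduces published haplotype counts from typed tables without requiring
assumptions about the unobserved calls.

# Diversity statistics

Per-locus gene diversity is $H = 1 - \sum_a p_a^2$ (the `plain`
estimator, matching the common survey convention) with an `unbiased`
variant multiplying by $n/(n-1)$.  Unit summaries are means over loci
with the standard error over loci, matching the ± columns of survey
tables; bootstrap SEs would mix locus and sampling variation and are not
used.

Allelic richness uses hypergeometric rarefaction to a common sample size
$g$: the expected number of distinct alleles in a subsample of $g$ calls
is $\sum_a [1 - \binom{N-N_a}{g}/\binom{N}{g}]$.  Private allelic
richness multiplies each allele's presence probability in the focal unit
by its absence probabilities in all other units.  Both estimators are
tested against exhaustive enumeration of all subsamples on instances with
$N \le 8$; they are exact, not approximations.  When `gSize` is not
given it defaults to the smallest per-locus call count across the
compared units, the largest size at which every unit can be rarefied;
loci below the chosen size in any unit are skipped and listed.

Nucleotide diversity for sequence fragments is the mean pairwise
proportion of differing sites with pairwise deletion of gaps and
ambiguities; silent-site diversity restricts to caller-supplied site
labels, since codon-context inference is outside the package's scope.

# AMOVA

`amova()` implements the Excoffier squared-distance framework for
haploid data.  The distance is the count of differing loci (the squared
Euclidean distance for 0/1 calls), computed with pairwise deletion and
rescaled to the panel size; with complete data it is exactly the
differing-locus count.  Sums of squares at each level of the
population (and optionally group) hierarchy yield variance components
via the standard unbalanced-design coefficients, and the fixation
indices $F_{ST}$, $F_{SC}$, $F_{CT}$.  On complete data the one-level
decomposition is identical to summing per-locus one-way variance
components, which the test suite verifies against an independent
`aov`-based oracle.

Negative variance components are reported raw and truncated to zero for
the percentage decomposition, the convention of the standard tools.
Permutation significance permutes samples among populations for
$F_{ST}$, whole populations among groups for $F_{CT}$, and samples among
populations within groups for $F_{SC}$; p-values use $(b+1)/(B+1)$ so
they are never exactly zero.  The conventional $B$ for final analyses is
20,000; tests use smaller $B$ because only calibration, not precision,
is at stake there.

# Isolation by distance

Geographic distances are haversine great-circle distances on a sphere of
radius 6371.0088 km; the error against an ellipsoidal model is far below
the positional uncertainty of field-collected populations at the scales
involved.  `mantelTest()` correlates off-diagonal entries, permutes rows
and columns of one matrix jointly, and reports the one-sided p for a
positive association by default (the IBD direction), together with the
genetic-on-geographic regression slope.  `compareIbd()` tests
between-region differences in $r$ and slope by permuting the
population-to-region labels; because permuted labels regroup populations
across regions, it takes pooled distance matrices plus a region factor
rather than two independent matrix pairs.  The label-permutation null is
a design choice of this package; the test it replaces in the original
workflow is not fully specified in the literature the package follows.

# Clustering

Three routes are provided, deliberately replacing MCMC-based Bayesian
ancestry inference; the replacement is justified by the high cross-method
agreement such surveys report between model-based clustering and
PCA-plus-Ward groupings, which this package measures rather than assumes.

**PCA.**  Loci are centred and scaled by $\sqrt{\hat p(1-\hat p)}$
(allele-frequency normalization for haploid calls), missing calls
imputed at the locus mean, and optionally residualized on one or two
preceding loci in map order to attenuate local linkage disequilibrium.
Component significance uses Tracy–Widom statistics after
moment-matching the eigenvalue spectrum to an effective marker count;
the TW$_1$ distribution function uses the shifted-gamma approximation
(Chiani 2014), accurate to about $10^{-3}$, ample for a component
screen.  `selectComponents()` keeps components explaining at least 2% of
variance, clipped to 3–5, weighted by eigenvalues.  `wardCluster()`
then applies Ward's minimum-variance criterion; when `k` is not fixed it
is chosen at the largest relative jump in merge heights.

**Admixture model.**  `admixtureFit()` maximizes the haploid admixture
log-likelihood
$L = \sum_i \sum_l \log \sum_k q_{ik}\, p_{kl}^{x_{il}} (1-p_{kl})^{1-x_{il}}$
by EM.  The likelihood is monotone and checked at every iteration.
Each fit runs `nStarts` short EM bursts from independent random starts
and refines the best (the em-EM strategy); 5 starts suffice on clean
mixtures, while strongly hierarchical data at larger K are multimodal
enough that ensemble analyses there use 20 starts — this is optimization
effort on a fixed objective, not a change of model.

**Model evidence and K.**  The maximized likelihood of nested mixtures
never decreases with K, so runs are compared on
$\mathrm{evidence} = L_{\max} - \frac12 K L \log n$, the BIC-style
Laplace approximation of the log marginal likelihood.  Following the
standard convention for mixture models, only the $K \times L$ component
frequencies are counted as parameters; per-sample memberships are latent
variables of the marginal model.  (A stricter variant that also
penalizes memberships by $\frac{n(K-1)}{2}\log L$ was examined and
found over-conservative: it prefers $K-1$ whenever a true cluster is
small, and in hand calculations prefers $K=1$ over a well-separated
two-cluster truth.)  `selectK()` then walks the published stepped rule:
the chosen K is the largest value whose replicate evidences exceed those
at $K-1$ by a two-sided Wilcoxon test at $\alpha = 0.005$, all smaller
steps also significant.  Because the signed-rank null is discrete, at
least 9 replicates per K are needed for significance to be attainable at
that $\alpha$; ensembles here use 10–20 replicates.

**Run alignment.**  Cluster labels are arbitrary per run.
`alignRuns()` finds, per run pair, the column permutation minimizing the
total absolute difference (exhaustive for $K \le 8$, greedy
lowest-index-first beyond), scores each pair as
$1 - \sum_{ik} |Q_{ik} - Q'_{ik}|/(2n)$, and reports the mean as $H'$;
the consensus is the mean of runs aligned to the highest-likelihood run.
`agreementPercent()` compares two hard assignments after optimal
one-to-one label matching on the confusion matrix.

**Neighbor joining.**  Trees come from `ape`'s Saitou–Nei implementation
on allele-difference distances, with bootstrap support from locus
resampling and bipartition counting.

# Quantitative traits

`imputeCensored()` handles plants that had not flowered when an
experiment ends: they receive the censoring limit as flowering time and
the leaf number predicted at that limit from the regression of leaf
number on flowering time among flowered plants, avoiding the downward
bias of discarding late genotypes.  `vernalizationRequirement()` scores
an accession as obligately requiring vernalization when no unvernalized
plant flowered (and vernalized plants, where present, did); regional
proportions are compared by Fisher's exact test, the natural choice at
survey sample sizes.

`qst()` decomposes a trait into between- and within-group components by
REML (random-intercept model) or by expected mean squares with the
unbalanced-design coefficient $n_0$; the two agree on balanced designs
to numerical precision.  $Q_{ST} = V_B/(V_B+V_W)$ without a factor of 2
on $V_W$ — the haploid-style ratio appropriate for selfing lines, where
accessions within groups are the replicates.  Accession means are the
default replicates; plant-level values can be supplied instead.
Negative moment estimates of $V_B$ are truncated at zero with the raw
value retained.

# Synthetic data: what it emulates and what it does not

The generators are first-class, seeded, and return their latent truth.

* `simulateIsland()` draws ancestral frequencies Uniform(0.05, 0.95)
  (avoiding monomorphic loci dominating small panels) and deme
  frequencies from the Balding–Nichols Beta, whose expected fixation
  index equals the `F` parameter exactly — giving closed-form recovery
  targets.  `selfingCollapse` duplicates within-deme haplotypes,
  emulating the extensive haplotype sharing of selfers.
* `simulateHierarchical()` stacks two Balding–Nichols layers (groups at
  `FCT`, populations within groups at `FSC`), with expected
  $F_{ST} = F_{CT} + (1-F_{CT})F_{SC}$.  Defaults FCT = 0.43 and
  FSC = 0.71 mirror the hierarchical decomposition reported for a
  strongly structured regional survey (43% among groups, 40% among
  populations within groups).
* `simulateSteppingStone()` walks logit frequencies along a transect so
  genetic distance grows with geographic distance; `spatialSigma = 0`
  switches to independent demes, removing the spatial signal while
  keeping differentiation.
* `simulateAdmixture()` draws calls from $\sum_k q_{ik} p_{kl}$ with
  cluster frequencies at divergence `clusterF` (default 0.4, strong
  differentiation typical of long-isolated regional lineages).
* `simulateTraits()` adds Normal group effects ($V_B$) and accession
  residuals ($V_W$) to a 100-day flowering-time baseline, derives leaf
  number by the 0.75 leaves/day allometry (the slope implied by a
  150-leaf/200-day late phenotype), and right-censors above `censorAt`.

These generators reproduce the statistical structure the estimators
assume — not mutation, linkage, selection, or coalescent genealogy.
Passing tests therefore demonstrate estimator correctness and pipeline
calibration under the assumed model, not robustness to demographic
misspecification on real data.

# Problem sizes and reproducibility

Simulation-based checks run at desk scale: differentiation recovery uses
20 demes × 8 samples × 200 loci over tens of replicates; Mantel
calibration uses 500 null matrices at $n = 15$; structure recovery uses
60–65 samples × 100–130 loci with 10–20 replicate runs per K.  These
sizes were chosen so that each property check pins its estimator with
comfortable Monte-Carlo margin while a full run of the suite stays
convenient on a laptop.  Every stochastic entry point takes a `seed`,
restores the caller's RNG state, and is bit-reproducible: re-running a
pipeline with the same seed writes byte-identical reports.

# Known limitations

* The admixture model assumes unlinked loci; dense panels with strong LD
  will overstate structure confidence (the PCA route offers neighbour
  regression as mitigation).
* Tracy–Widom p-values are approximate twice over (moment matching and
  the gamma surrogate); they are used for screening components, not as
  exact tail probabilities.
* `selectK` inherits the discreteness of the signed-rank test (see
  above) and, like any evidence criterion on hierarchically structured
  data, identifies the major-group level only when the evidence gain of
  the next split falls below the penalty; deeper genuine substructure
  is then deliberately not counted.
* AMOVA treats missing calls by pairwise deletion with mean imputation
  of fully unscorable pairs; panels where missingness tracks population
  membership can bias components.
* `compareIbd`'s label-permutation null conditions on the pooled
  geography; regions with radically different spatial extents should be
  compared with care.
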