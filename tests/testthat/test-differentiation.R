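test_that("pairwise distances use pairwise deletion of missing calls", {
  calls <- rbind(a = c(0L, 1L, 0L, 1L, NA),
                 b = c(0L, 0L, 1L, 1L, 1L),
                 c = c(0L, 1L, 0L, 1L, 1L))
  g <- toyGenotypes(calls)
  d <- geneticDistances(g, metric = "proportion")
  expect_equal(d["a", "b"], 2 / 4)  # 4 co-scored loci
  expect_equal(d["a", "c"], 0)
  expect_equal(d["b", "c"], 2 / 5)
  expect_true(isSymmetric(d))
  cnt <- geneticDistances(g, metric = "count")
  expect_equal(cnt["a", "b"], 2)
})

test_that("population-level distance is the mean over cross-population pairs", {
  calls <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 1L), c(1L, 1L))
  g <- toyGenotypes(calls, pop = c("A", "A", "B", "B"))
  d <- geneticDistances(g, level = "population")
  expect_equal(d["A", "B"], mean(c(1, 1, 0.5, 0.5)))
})

test_that("AMOVA matches the per-locus variance-component oracle", {
  sim <- simulateIsland(nPops = 4, samplesPerPop = c(5, 7, 6, 8),
                        nLoci = 40, F = 0.25, seed = 21)
  g <- sim$genotypes
  res <- amova(g)
  expect_equal(unname(res@indices["FST"]),
               aovFstOracle(callMatrix(g), populations(g)),
               tolerance = 1e-10)
  expect_equal(sum(res@percent), 100, tolerance = 1e-9)
})

test_that("AMOVA hits the degenerate endpoints", {
  # identical composition across populations -> no positive differentiation
  # (the unbiased estimate goes negative because cross-population pairs
  # include zero-distance duplicates)
  block <- rbind(c(0L, 1L, 0L), c(1L, 0L, 1L), c(0L, 0L, 1L))
  g0 <- toyGenotypes(rbind(block, block), pop = rep(c("A", "B"), each = 3))
  expect_lte(unname(amova(g0)@indices["FST"]), 0)
  # each population fixed for a distinct haplotype -> FST = 1
  g1 <- toyGenotypes(rbind(matrix(0L, 4, 6), matrix(1L, 4, 6)),
                     pop = rep(c("A", "B"), each = 4))
  expect_equal(unname(amova(g1)@indices["FST"]), 1)
  expect_error(amova(toyGenotypes(matrix(0:1, 4, 3))), "2 populations")
})

test_that("two-level AMOVA recovers hierarchical variance fractions", {
  sim <- simulateHierarchical(popsPerGroup = c(3, 3, 3), samplesPerPop = 8,
                              nLoci = 150, FCT = 0.3, FSC = 0.4, seed = 31)
  res <- amova(sim$genotypes, groups = sim$groups)
  expect_equal(sum(res@percent), 100, tolerance = 1e-9)
  expect_equal(unname(res@indices["FCT"]), 0.3, tolerance = 0.12)
  expect_equal(unname(res@indices["FSC"]), 0.4, tolerance = 0.12)
  expect_equal(length(res@components), 3)
})

test_that("AMOVA permutation p-values behave under signal and null", {
  sim <- simulateIsland(nPops = 4, samplesPerPop = 8, nLoci = 60, F = 0.3,
                        seed = 13)
  res <- amova(sim$genotypes, nPerm = 99, seed = 2)
  expect_equal(unname(res@pvalues["FST"]), 1 / 100)
  # panmictic data: p should not be small
  sim0 <- simulateIsland(nPops = 4, samplesPerPop = 8, nLoci = 60, F = 0,
                         seed = 14)
  res0 <- amova(sim0$genotypes, nPerm = 99, seed = 2)
  expect_gt(unname(res0@pvalues["FST"]), 0.05)
})

test_that("pairwiseFst equals the two-population AMOVA restriction", {
  sim <- simulateIsland(nPops = 3, samplesPerPop = 6, nLoci = 50, F = 0.3,
                        seed = 17)
  g <- sim$genotypes
  pf <- pairwiseFst(g)
  pops <- populations(g)
  sel <- which(pops %in% c("pop1", "pop2"))
  direct <- amova(g[, sel], populations = droplevels(pops[sel]))
  expect_equal(pf$fst["pop1", "pop2"], unname(direct@indices["FST"]))
  # duplicated unit -> FST ~ 0 with large p
  calls <- callMatrix(g)[pops == "pop1", ]
  gd <- toyGenotypes(rbind(calls, calls),
                     pop = rep(c("u", "v"), each = nrow(calls)))
  pd <- pairwiseFst(gd, nPerm = 99, seed = 5)
  expect_lte(pd$fst["u", "v"], 0)   # negative estimates reported as-is
  expect_gt(pd$p["u", "v"], 0.5)
})

test_that("group distance subtracts within-group means and is duplication-invariant", {
  sim <- simulateIsland(nPops = 2, samplesPerPop = 6, nLoci = 50, F = 0.3,
                        seed = 19)
  g <- sim$genotypes
  pops <- populations(g)
  ga <- which(pops == "pop1"); gb <- which(pops == "pop2")
  res <- groupDistance(g, ga, gb)
  expect_equal(res$corrected, res$raw - (res$withinA + res$withinB) / 2)
  expect_lte(res$corrected, res$raw)
  # group against itself: corrected 0
  self <- groupDistance(g, ga, ga)
  expect_equal(self$corrected, 0, tolerance = 1e-12)
  # duplicating every sample of a group leaves the corrected distance alone
  calls <- callMatrix(g)
  g2 <- toyGenotypes(rbind(calls, calls[ga, ]),
                     pop = c(as.character(pops), rep("pop1", length(ga))))
  res2 <- groupDistance(g2, c(ga, nrow(calls) + seq_along(ga)), gb)
  expect_equal(res2$corrected, res$corrected, tolerance = 1e-12)
})

test_that("Balding-Nichols F is recovered by the two-deme AMOVA estimate", {
  fst <- vapply(1:12, function(s) {
    sim <- simulateIsland(nPops = 2, samplesPerPop = 10, nLoci = 150,
                          F = 0.3, seed = 100 + s)
    unname(amova(sim$genotypes)@indices["FST"])
  }, numeric(1))
  expect_lt(abs(mean(fst) - 0.3), 0.05)
})
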