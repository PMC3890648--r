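test_that("gene diversity matches closed forms", {
  g <- toyGenotypes(rbind(c(0L, 0L), c(1L, 0L)))
  hd <- geneDiversity(g)
  # locus 1: n=2, p=0.5 -> plain 0.5; locus 2 monomorphic -> 0
  expect_equal(unname(hd$perLocus), c(0.5, 0))
  expect_equal(geneDiversity(g, estimator = "unbiased")$perLocus[[1]], 1)
  expect_error(geneDiversity(g, unit = 1), "at least 2")
})

test_that("plain gene diversity never exceeds the unbiased estimator", {
  sim <- simulateIsland(nPops = 3, samplesPerPop = 6, nLoci = 40, F = 0.2,
                        missingRate = 0.05, seed = 12)
  plain <- geneDiversity(sim$genotypes)$perLocus
  unb <- geneDiversity(sim$genotypes, estimator = "unbiased")$perLocus
  expect_true(all(plain <= unb + 1e-12))
})

test_that("percent polymorphic loci counts scorable loci only", {
  calls <- rbind(c(0L, 1L, NA), c(0L, 0L, NA), c(0L, 1L, NA))
  g <- toyGenotypes(calls)
  # L3 has no calls -> 2 scorable, 1 polymorphic
  expect_equal(polymorphicFraction(g), 50)
  expect_equal(polymorphicFraction(toyGenotypes(matrix(1L, 4, 5))), 0)
})

test_that("rarefied allelic richness equals the exhaustive-subset oracle", {
  rarefy <- haplopop:::.rarefyLocus
  # worked case: N=4 calls, 2 of allele 1, g=2
  v <- c(0L, 0L, 1L, 1L)
  expect_equal(rarefy(c(2, 2), 2), enumRichness(v, 2))

  set.seed(99)
  for (rep in 1:20) {
    N <- sample(3:8, 1)
    v <- rbinom(N, 1, runif(1, 0.2, 0.8))
    g <- sample(seq_len(N - 1), 1)
    counts <- c(sum(v == 0), sum(v == 1))
    expect_equal(rarefy(counts, g), enumRichness(v, g),
                 tolerance = 1e-12)
  }
})

test_that("allelicRichness rarefies all units to a common size", {
  calls <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 1L), c(1L, 0L),
                 c(0L, 0L), c(0L, 0L))
  g <- toyGenotypes(calls, pop = rep(c("A", "B"), each = 3))
  rs <- allelicRichness(g, gSize = 2)
  # unit A locus1 counts (2,1): oracle over all C(3,2) subsets
  expect_equal(rs$RS[rs$unit == "A"],
               mean(c(enumRichness(calls[1:3, 1], 2),
                      enumRichness(calls[1:3, 2], 2))))
  # monomorphic unit stays at exactly 1 allele
  expect_equal(rs$RS[rs$unit == "B"],
               mean(c(enumRichness(calls[4:6, 1], 2), 1)))
  # at gSize = N the observed allele count is recovered (no rarefaction loss)
  rsFull <- allelicRichness(g, gSize = 3)
  expect_equal(rsFull$RS[rsFull$unit == "A"], 2)
})

test_that("private allelic richness matches the paired-enumeration oracle", {
  # one unit-exclusive allele between two 3-sample units
  calls <- rbind(c(0L, 0L), c(0L, 1L), c(0L, 1L),
                 c(1L, 1L), c(1L, 1L), c(1L, 0L))
  g <- toyGenotypes(calls, pop = rep(c("A", "B"), each = 3))
  rp <- privateAllelicRichness(g, gSize = 2)
  oracleA <- mean(c(enumPrivate(calls[1:3, 1], calls[4:6, 1], 2),
                    enumPrivate(calls[1:3, 2], calls[4:6, 2], 2)))
  oracleB <- mean(c(enumPrivate(calls[4:6, 1], calls[1:3, 1], 2),
                    enumPrivate(calls[4:6, 2], calls[1:3, 2], 2)))
  expect_equal(rp$RP[rp$unit == "A"], oracleA, tolerance = 1e-12)
  expect_equal(rp$RP[rp$unit == "B"], oracleB, tolerance = 1e-12)

  # allele fixed everywhere contributes nothing
  gid <- toyGenotypes(matrix(1L, 6, 3), pop = rep(c("A", "B"), each = 3))
  rp0 <- privateAllelicRichness(gid, gSize = 2)
  expect_equal(rp0$RP, c(0, 0))
  expect_error(privateAllelicRichness(toyGenotypes(matrix(0:1, 4, 2))),
               ">= 2 units")
})

test_that("nucleotide diversity is mean pairwise difference per site", {
  expect_equal(nucleotideDiversity(c("ACGT", "ACGT"))$pi, 0)
  s <- strrep("A", 99)
  expect_equal(nucleotideDiversity(c(paste0(s, "C"), paste0(s, "G")))$pi,
               0.01)
  # gaps excluded pairwise; silent-site restriction
  aln <- c("ACG-", "ACGT", "TCGT")
  r <- nucleotideDiversity(aln, siteClasses = c("silent", "silent",
                                                "excluded", "silent"))
  expect_equal(r$nPolymorphisms, 1)
  # silent sites are 1,2,4; pairs: (1,2): 0/3 scorable 2; (1,3): 1/2; (2,3): 1/3
  expect_equal(r$piSilent, mean(c(0 / 2, 1 / 2, 1 / 3)))
  expect_error(nucleotideDiversity("ACGT"), "at least 2")
})

test_that("the per-unit diversity table has the reported columns", {
  sim <- simulateIsland(nPops = 3, samplesPerPop = c(5, 5, 1), nLoci = 30,
                        F = 0.3, seed = 3)
  tab <- diversityTable(sim$genotypes)
  expect_named(tab, c("unit", "N", "NH", "PL", "HS", "HS_se", "RS",
                      "RS_se", "RP", "RP_se", "g"))
  # a single-sample unit gets NA frequency statistics (as a dashed entry)
  expect_true(is.na(tab$HS[tab$N == 1]))
  expect_true(all(tab$PL >= 0 & tab$PL <= 100, na.rm = TRUE))
  expect_true(all(tab$HS >= 0 & tab$HS <= 1, na.rm = TRUE))
  expect_true(all(tab$RS >= 1 & tab$RS <= 2, na.rm = TRUE))
  expect_true(all(tab$RP >= 0, na.rm = TRUE))
})
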