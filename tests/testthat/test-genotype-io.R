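test_that("delimited round-trip preserves calls, metadata and missing cells", {
  m <- matrix(c(0L, 1L, NA, 1L, 0L, 1L), nrow = 3,
              dimnames = list(c("a1", "a2", "a3"), c("L1", "L2")))
  td <- withr::local_tempdir()
  tab <- file.path(td, "geno.tsv")
  df <- data.frame(accession = rownames(m), m, check.names = FALSE)
  write.table(df, tab, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- file.path(td, "meta.tsv")
  write.table(data.frame(accession = rownames(m),
                         population = c("A", "A", "B"),
                         latitude = c(31, 31, 33), longitude = c(-5, -5, -7)),
              meta, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- readGenotypes(tab, metaPath = meta)
  expect_s4_class(g, "SnpGenotypes")
  expect_identical(callMatrix(g), m)
  expect_identical(as.character(populations(g)), c("A", "A", "B"))

  # unknown symbol becomes missing, with a count
  df2 <- df; df2[1, "L1"] <- "Z"
  write.table(df2, tab, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(g2 <- readGenotypes(tab), "1 unknown")
  expect_true(is.na(callMatrix(g2)[1, "L1"]))

  # duplicate ids and missing metadata entries are structural errors
  df3 <- rbind(df, df[1, ])
  write.table(df3, tab, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readGenotypes(tab), "duplicate")
})

test_that("nucleotide alleles are decoded through the SNP map", {
  td <- withr::local_tempdir()
  tab <- file.path(td, "geno.tsv")
  write.table(data.frame(accession = c("x", "y"),
                         L1 = c("A", "G"), L2 = c("T", "T")),
              tab, sep = "\t", quote = FALSE, row.names = FALSE)
  map <- file.path(td, "map.tsv")
  write.table(data.frame(id = c("L1", "L2"), chromosome = c(1, 2),
                         position = c(100, 200), panel = c("CE", "W"),
                         allele0 = c("A", "T"), allele1 = c("G", "C")),
              map, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- readGenotypes(tab, mapPath = map)
  expect_equal(unname(callMatrix(g)), rbind(c(0L, 0L), c(1L, 0L)))
  expect_equal(lociInfo(g)$panel, c("CE", "W"))
})

test_that("locus filters apply in order missingness, monomorphism, population-missing", {
  # L1 30% missing; L2 monomorphic; L3 missing in all of (small) pop B
  # but under the 25% overall threshold; L4 clean
  calls <- rbind(
    c(NA, 1L, 1L, 0L), c(0L, 1L, 0L, 1L), c(1L, 1L, 1L, 0L),
    c(NA, 1L, 0L, 1L), c(0L, 1L, 1L, 0L), c(NA, 1L, 0L, 1L),
    c(1L, 1L, 1L, 0L), c(0L, 1L, 0L, 1L),
    c(1L, 1L, NA, 0L), c(0L, 1L, NA, 1L))
  g <- toyGenotypes(calls, pop = rep(c("A", "B"), c(8, 2)))
  gf <- filterLoci(g, maxMissing = 0.25, dropMonomorphic = TRUE,
                   dropPopulationMissing = TRUE)
  rep1 <- S4Vectors::metadata(gf)$filterReport
  expect_equal(rep1$missingness, 1)        # L1 at 40% >= 25%
  expect_equal(rep1$monomorphic, 1)        # L2
  expect_equal(rep1$populationMissing, 1)  # L3 absent in all of B
  expect_equal(rep1$retained, 1)
  expect_identical(colnames(callMatrix(gf)), "L4")

  # idempotence
  gff <- filterLoci(gf, maxMissing = 0.25, dropMonomorphic = TRUE,
                    dropPopulationMissing = TRUE)
  expect_identical(callMatrix(gff), callMatrix(gf))

  # complete data: only the monomorphism filter can fire
  sim <- simulateIsland(nPops = 2, samplesPerPop = 5, nLoci = 12, F = 0.3,
                        seed = 4)
  r <- S4Vectors::metadata(filterLoci(sim$genotypes))$filterReport
  expect_equal(r$missingness, 0)
  expect_equal(r$populationMissing, 0)
  expect_equal(r$retained, 12 - r$monomorphic)

  expect_error(filterLoci(g, maxMissing = 0), "empty panel")
})

test_that("haplotype collapsing honours the missing-data rule", {
  calls <- rbind(a = c(0L, 1L, 0L), b = c(0L, 1L, 0L),
                 c = c(0L, NA, 0L), d = c(1L, 1L, 0L))
  g <- toyGenotypes(calls, pop = c("p1", "p1", "p1", "p2"))
  hs <- collapseHaplotypes(g, "strict")
  expect_equal(nHaplotypes(hs), 3)  # missing is its own state
  hw <- collapseHaplotypes(g, "wildcard")
  expect_equal(nHaplotypes(hw), 2)  # c merges with a/b
  expect_gte(nHaplotypes(hs), nHaplotypes(hw))
  expect_equal(sum(haplotypeCounts(hs)), nrow(calls))

  # all identical -> one haplotype; counts track populations
  gid <- toyGenotypes(matrix(1L, 6, 4), pop = rep(c("x", "y"), 3))
  expect_equal(nHaplotypes(collapseHaplotypes(gid)), 1)
  expect_equal(unname(haplotypeCounts(collapseHaplotypes(gid))[, 1]),
               c(3L, 3L))
})

test_that("wildcard merging is transitive through bridging samples", {
  calls <- rbind(a = c(0L, NA), b = c(NA, 1L), c = c(0L, 1L))
  g <- toyGenotypes(calls)
  # c matches both a and b, pulling all three together
  expect_equal(nHaplotypes(collapseHaplotypes(g, "wildcard")), 1)
  expect_equal(nHaplotypes(collapseHaplotypes(g, "strict")), 3)
})

test_that("STRUCTURE format round-trips with -9 for missing", {
  sim <- simulateIsland(nPops = 3, samplesPerPop = 4, nLoci = 10, F = 0.2,
                        missingRate = 0.15, seed = 8)
  g <- sim$genotypes
  td <- withr::local_tempdir()
  f <- file.path(td, "str.txt")
  writeStructure(g, f)
  line2 <- readLines(f)[2]
  expect_match(line2, "^acc1 1 ")
  if (anyNA(callMatrix(g)[1, ])) expect_match(line2, "-9")
  g2 <- readStructure(f, populationLabels = levels(populations(g)))
  expect_identical(callMatrix(g2), callMatrix(g))
  expect_identical(as.character(populations(g2)),
                   as.character(populations(g)))
})

test_that("trees written as Newick are parseable with intact tip set", {
  d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- neighborJoining(d)
  td <- withr::local_tempdir()
  f <- file.path(td, "t.nwk")
  writeNewickTree(tr, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, letters[1:3])
})
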