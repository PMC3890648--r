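#' Run the full population-genetic analysis pipeline
#'
#' Orchestrates the analysis tiers on one genotype panel: locus filtering,
#' haplotype collapsing, per-unit diversity tables, AMOVA (with optional
#' supergroups), isolation by distance (when coordinates are present),
#' clustering by both routes (PCA + Ward and the EM admixture ensemble)
#' with their agreement, and optionally Q_ST on supplied traits.  Every
#' stochastic stage is seeded from `seed` by fixed offsets, so re-running
#' with the same inputs reproduces every output.
#'
#' @param g a [SnpGenotypes-class] (or paths list with `table`, `map`,
#'   `meta` for [readGenotypes()]).
#' @param tier `"regional"` (per-population focus, population-missing
#'   filter on), `"bi-regional"` or `"worldwide"` (monomorphic filter
#'   only).
#' @param maxMissing locus missingness threshold (default 0.25).
#' @param nPermAmova,nPermMantel permutation counts (scaled-down defaults;
#'   published analyses used 20000 and 10000).
#' @param kRange candidate K values for the admixture ensemble.
#' @param replicates admixture replicate runs per K.
#' @param seed master seed.
#' @param traits optional trait table for the Q_ST stage.
#' @param outDir optional directory to write CSV/Newick reports into.
#' @return named list of stage results (also written to `outDir` when
#'   given); stage errors abort with a stage-tagged message.
#' @export
runPipeline <- function(g, tier = c("regional", "bi-regional", "worldwide"),
                        maxMissing = 0.25, nPermAmova = 999L,
                        nPermMantel = 999L, kRange = 1:6, replicates = 10L,
                        seed = 1L, traits = NULL, outDir = NULL) {
  tier <- match.arg(tier)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "]: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is(g, "SnpGenotypes"))
    g <- stage("genotype_io",
               readGenotypes(g$table, g$map, g$meta))
  res <- list(tier = tier, seed = seed)

  res$filtered <- stage("filter", filterLoci(
    g, maxMissing = maxMissing, dropMonomorphic = TRUE,
    dropPopulationMissing = tier == "regional"))
  gf <- res$filtered
  res$filterReport <- S4Vectors::metadata(gf)$filterReport

  res$haplotypes <- stage("haplotypes", collapseHaplotypes(gf))
  res$diversity <- stage("diversity", diversityTable(gf))

  res$amova <- stage("amova",
                     amova(gf, nPerm = nPermAmova, seed = seed + 101L))

  si <- sampleInfo(gf)
  if (all(c("latitude", "longitude") %in% names(si)) &&
      !anyNA(si$latitude) && nlevels(populations(gf)) >= 4) {
    res$geo <- stage("ibd", geoDistances(gf))
    res$genDist <- stage("ibd",
                         geneticDistances(gf, level = "population"))
    res$mantel <- stage("ibd", mantelTest(
      res$geo, res$genDist, nPerm = nPermMantel, seed = seed + 202L))
  }

  res$pca <- stage("clustering", snpPca(gf))
  comps <- stage("clustering", selectComponents(res$pca))
  res$ward <- stage("clustering", wardCluster(comps))
  runsByK <- stage("clustering", lapply(kRange, function(K)
    runAdmixture(gf, K, replicates = replicates,
                 seed = seed + 1000L * K)))
  names(runsByK) <- kRange
  ll <- lapply(runsByK, function(e)
    vapply(e@runs, modelEvidence, numeric(1)))
  res$selectedK <- stage("clustering", selectK(ll))
  res$ensemble <- runsByK[[as.character(res$selectedK)]]
  res$agreement <- stage("clustering", agreementPercent(
    majorityAssignment(res$ensemble), res$ward$cluster))
  res$njTree <- stage("clustering", {
    gh <- uniqueHaplotypes(gf)
    d <- geneticDistances(gh, level = "sample")
    if (anyNA(d)) d[is.na(d)] <- mean(d, na.rm = TRUE)
    neighborJoining(d)
  })

  if (!is.null(traits)) {
    res$imputed <- stage("quantgen", imputeCensored(traits))
    groupsOfAcc <- majorityAssignment(res$ensemble)
    tm <- tapply(res$imputed$traits$FT, res$imputed$traits$accession, mean)
    common <- intersect(names(tm), names(groupsOfAcc))
    if (length(common) >= 4)
      res$qst <- stage("quantgen", qst(tm[common], groupsOfAcc[common],
                                       trait = "FT"))
  }

  if (!is.null(outDir)) reportTables(res, outDir)
  res
}

#' Write pipeline results as report tables
#'
#' Emits the per-unit diversity table (columns N, N_H, PL, H_S +/- SE,
#' R_S +/- SE, R_P +/- SE), the AMOVA component/percent/index/p table, the
#' consensus membership matrix, the Ward assignments, Mantel statistics and
#' the NJ tree in Newick, each as plain text under `dir`.
#'
#' @param results list returned by [runPipeline()].
#' @param dir output directory (created if needed).
#' @return invisible character vector of the files written.
#' @export
reportTables <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  put <- function(df, name) {
    f <- file.path(dir, name)
    write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  if (!is.null(results$diversity)) {
    d <- results$diversity
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], function(x) round(x, 3))
    put(d, "diversity.csv")
  }
  if (!is.null(results$amova)) {
    a <- results$amova
    put(data.frame(level = names(a@components),
                   df = a@df, SS = round(a@ss, 3),
                   sigma2 = signif(a@components, 4),
                   percent = round(a@percent, 1)),
        "amova_components.csv")
    put(data.frame(index = names(a@indices),
                   value = round(a@indices, 4),
                   p = signif(a@pvalues, 4)),
        "amova_indices.csv")
  }
  if (!is.null(results$mantel)) {
    m <- results$mantel
    put(data.frame(r = m@r, r2 = m@r^2, slope = m@slope,
                   intercept = m@intercept, p = m@p, nPerm = m@nPerm),
        "mantel.csv")
  }
  if (!is.null(results$ensemble)) {
    Q <- membership(results$ensemble)
    put(data.frame(accession = rownames(Q), round(Q, 4),
                   check.names = FALSE), "membership.csv")
  }
  if (!is.null(results$ward))
    put(data.frame(accession = names(results$ward$cluster),
                   wardCluster = as.integer(results$ward$cluster)),
        "ward_clusters.csv")
  if (!is.null(results$njTree)) {
    f <- file.path(dir, "nj_tree.nwk")
    writeNewickTree(results$njTree, f)
    files <- c(files, f)
  }
  invisible(files)
}
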