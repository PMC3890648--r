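#' Simulate haploid island-model genotypes (Balding-Nichols)
#'
#' Ancestral allele frequencies are drawn Uniform(0.05, 0.95); each deme's
#' frequency is Beta-distributed around the ancestral value with the
#' Balding-Nichols parameterisation
#' \eqn{\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)}, whose expected fixation
#' index equals `F` exactly (demes copy the ancestral frequency when
#' `F = 0`).  Haploid calls are Bernoulli draws from the deme frequency.
#' `selfingCollapse` is the probability that a sample duplicates an
#' already-drawn haplotype of its deme, emulating the extensive
#' within-population haplotype sharing of selfing species; at 1 every deme
#' is a single haplotype.
#'
#' @param nPops number of demes.
#' @param samplesPerPop samples per deme (recycled).
#' @param nLoci number of biallelic loci.
#' @param F target differentiation in \[0, 1).
#' @param selfingCollapse within-deme haplotype-duplication probability.
#' @param missingRate fraction of calls masked to missing.
#' @param seed integer seed (mandatory).
#' @return list: `genotypes` ([SnpGenotypes-class]) and `truth` (ancestral
#'   and deme frequencies, parameters).
#' @export
simulateIsland <- function(nPops, samplesPerPop, nLoci, F = 0.1,
                           selfingCollapse = 0, missingRate = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(F >= 0, F < 1, selfingCollapse >= 0, selfingCollapse <= 1,
            missingRate >= 0, missingRate < 1)
  old <- .seedSet(seed)
  on.exit(.seedRestore(old))
  sizes <- rep_len(samplesPerPop, nPops)
  pAnc <- runif(nLoci, 0.05, 0.95)
  demeP <- matrix(0, nPops, nLoci)
  for (k in seq_len(nPops)) {
    demeP[k, ] <- if (F == 0) pAnc
    else rbeta(nLoci, pAnc * (1 - F) / F, (1 - pAnc) * (1 - F) / F)
  }
  calls <- matrix(NA_integer_, sum(sizes), nLoci)
  popLab <- rep(paste0("pop", seq_len(nPops)), sizes)
  row <- 0
  for (k in seq_len(nPops)) {
    first <- row + 1
    for (s in seq_len(sizes[k])) {
      row <- row + 1
      if (s > 1 && runif(1) < selfingCollapse) {
        calls[row, ] <- calls[first + sample.int(s - 1, 1) - 1, ]
      } else {
        calls[row, ] <- rbinom(nLoci, 1, demeP[k, ])
      }
    }
  }
  if (missingRate > 0) {
    mask <- matrix(runif(length(calls)) < missingRate, nrow(calls))
    calls[mask] <- NA_integer_
  }
  dimnames(calls) <- list(paste0("acc", seq_len(nrow(calls))),
                          paste0("L", seq_len(nLoci)))
  g <- SnpGenotypes(calls, samples = data.frame(
    accession = rownames(calls), population = popLab))
  list(genotypes = g,
       truth = list(pAncestral = pAnc, demeFrequencies = demeP, F = F,
                    selfingCollapse = selfingCollapse,
                    missingRate = missingRate, seed = seed))
}

#' Simulate a linear stepping-stone with isolation by distance
#'
#' Demes are placed along a latitudinal transect with coordinates, and
#' allele frequencies follow a spatially autocorrelated random walk on the
#' logit scale: neighbouring demes differ by Normal(0, `spatialSigma`)
#' steps, so genetic distance grows with geographic distance.  With
#' `spatialSigma = 0` deme frequencies are instead drawn independently
#' (Balding-Nichols at `F`), removing the spatial signal while keeping
#' differentiation.
#'
#' @param nPops,samplesPerPop,nLoci,missingRate,seed as in
#'   [simulateIsland()].
#' @param spatialSigma random-walk step standard deviation (logit scale);
#'   0 disables spatial autocorrelation.
#' @param F differentiation used for the non-spatial draw when
#'   `spatialSigma = 0` (default 0.2).
#' @param spacingKm distance between neighbouring demes (default 50 km).
#' @return list: `genotypes`, `geo` (distance matrix in km), `truth`.
#' @export
simulateSteppingStone <- function(nPops, samplesPerPop, nLoci,
                                  spatialSigma = 0.5, F = 0.2,
                                  spacingKm = 50, missingRate = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  old <- .seedSet(seed)
  on.exit(.seedRestore(old))
  sizes <- rep_len(samplesPerPop, nPops)
  pAnc <- runif(nLoci, 0.05, 0.95)
  logit <- function(p) log(p / (1 - p))
  inv <- function(x) 1 / (1 + exp(-x))
  demeP <- matrix(0, nPops, nLoci)
  if (spatialSigma > 0) {
    x <- logit(pAnc)
    for (k in seq_len(nPops)) {
      demeP[k, ] <- pmin(pmax(inv(x), 0.02), 0.98)
      x <- x + rnorm(nLoci, 0, spatialSigma)
    }
  } else {
    for (k in seq_len(nPops))
      demeP[k, ] <- if (F == 0) pAnc
      else rbeta(nLoci, pAnc * (1 - F) / F, (1 - pAnc) * (1 - F) / F)
  }
  calls <- matrix(NA_integer_, sum(sizes), nLoci)
  popLab <- rep(paste0("pop", seq_len(nPops)), sizes)
  row <- 0
  for (k in seq_len(nPops)) for (s in seq_len(sizes[k])) {
    row <- row + 1
    calls[row, ] <- rbinom(nLoci, 1, demeP[k, ])
  }
  if (missingRate > 0) {
    mask <- matrix(runif(length(calls)) < missingRate, nrow(calls))
    calls[mask] <- NA_integer_
  }
  dimnames(calls) <- list(paste0("acc", seq_len(nrow(calls))),
                          paste0("L", seq_len(nLoci)))
  lat0 <- 31                       # transect anchored in mid-latitudes
  latStep <- spacingKm / 111.19    # km per degree of latitude
  lat <- lat0 + (seq_len(nPops) - 1) * latStep
  meta <- data.frame(accession = rownames(calls), population = popLab,
                     latitude = rep(lat, sizes),
                     longitude = -6)
  g <- SnpGenotypes(calls, samples = meta)
  list(genotypes = g, geo = geoDistances(g),
       truth = list(pAncestral = pAnc, demeFrequencies = demeP,
                    spatialSigma = spatialSigma, spacingKm = spacingKm,
                    seed = seed))
}

#' Simulate a two-level hierarchical island model
#'
#' Group allele frequencies diverge from the ancestral frequency by
#' Balding-Nichols at `FCT`, and population frequencies diverge from their
#' group's frequency at `FSC`, giving expected fixation indices
#' \eqn{F_{CT} = FCT}, \eqn{F_{SC} = FSC} and
#' \eqn{F_{ST} = FCT + (1-FCT) \cdot FSC}.  Useful as the truth model for
#' two-level AMOVA and for group-structure recovery at realistic strengths
#' of regional differentiation.
#'
#' @param popsPerGroup integer vector: populations in each group.
#' @param samplesPerPop samples per population (scalar or one per
#'   population, in group order).
#' @param nLoci number of loci.
#' @param FCT among-group differentiation.
#' @param FSC among-population-within-group differentiation.
#' @param missingRate fraction of calls masked.
#' @param seed integer seed.
#' @return list: `genotypes` (with `population` and `group` metadata),
#'   `groups` (named vector population -> group), `truth`.
#' @export
simulateHierarchical <- function(popsPerGroup, samplesPerPop, nLoci,
                                 FCT = 0.2, FSC = 0.2, missingRate = 0,
                                 seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(FCT >= 0, FCT < 1, FSC >= 0, FSC < 1)
  old <- .seedSet(seed)
  on.exit(.seedRestore(old))
  nGroups <- length(popsPerGroup)
  nPops <- sum(popsPerGroup)
  sizes <- rep_len(samplesPerPop, nPops)
  pAnc <- runif(nLoci, 0.05, 0.95)
  bn <- function(p, F) if (F == 0) p
    else rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  grpOfPop <- rep(seq_len(nGroups), popsPerGroup)
  groupP <- t(vapply(seq_len(nGroups), function(k) bn(pAnc, FCT),
                     numeric(nLoci)))
  popP <- t(vapply(seq_len(nPops), function(j) bn(groupP[grpOfPop[j], ], FSC),
                   numeric(nLoci)))
  calls <- matrix(NA_integer_, sum(sizes), nLoci)
  popLab <- rep(paste0("pop", seq_len(nPops)), sizes)
  row <- 0
  for (j in seq_len(nPops)) for (s in seq_len(sizes[j])) {
    row <- row + 1
    calls[row, ] <- rbinom(nLoci, 1, popP[j, ])
  }
  if (missingRate > 0) {
    mask <- matrix(runif(length(calls)) < missingRate, nrow(calls))
    calls[mask] <- NA_integer_
  }
  dimnames(calls) <- list(paste0("acc", seq_len(nrow(calls))),
                          paste0("L", seq_len(nLoci)))
  grpLab <- paste0("grp", grpOfPop)
  g <- SnpGenotypes(calls, samples = data.frame(
    accession = rownames(calls), population = popLab,
    group = rep(grpLab, sizes)))
  list(genotypes = g,
       groups = setNames(grpLab, paste0("pop", seq_len(nPops))),
       truth = list(pAncestral = pAnc, groupFrequencies = groupP,
                    popFrequencies = popP, FCT = FCT, FSC = FSC,
                    FSTexpected = FCT + (1 - FCT) * FSC, seed = seed))
}

#' Simulate genotypes under a known admixture matrix
#'
#' Cluster allele frequencies are Balding-Nichols draws around a shared
#' ancestral frequency at divergence `clusterF` (default 0.4, a strong
#' differentiation typical of long-isolated regional lineages); each call
#' for sample i at locus l is Bernoulli with mixed frequency
#' \eqn{\sum_k q_{ik} p_{kl}}.  A hard 0/1 `Q` at K = 2 reduces to a
#' two-deme island model.
#'
#' @param Q n x K membership matrix, rows on the simplex.
#' @param nLoci number of loci.
#' @param clusterF divergence of cluster frequencies.
#' @param P optional K x L cluster frequencies overriding the draw.
#' @param missingRate fraction of calls masked.
#' @param seed integer seed.
#' @return list: `genotypes`, `truth` (Q and P).
#' @export
simulateAdmixture <- function(Q, nLoci, clusterF = 0.4, P = NULL,
                              missingRate = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  Q <- as.matrix(Q)
  if (any(Q < 0) || any(abs(rowSums(Q) - 1) > 1e-8))
    stop("Q rows must be nonnegative and sum to 1")
  old <- .seedSet(seed)
  on.exit(.seedRestore(old))
  K <- ncol(Q); n <- nrow(Q)
  if (is.null(P)) {
    pAnc <- runif(nLoci, 0.05, 0.95)
    P <- matrix(0, K, nLoci)
    for (k in seq_len(K))
      P[k, ] <- rbeta(nLoci, pAnc * (1 - clusterF) / clusterF,
                      (1 - pAnc) * (1 - clusterF) / clusterF)
  }
  mixed <- Q %*% P
  calls <- matrix(rbinom(n * nLoci, 1, mixed), n, nLoci)
  if (missingRate > 0) {
    mask <- matrix(runif(length(calls)) < missingRate, n)
    calls[mask] <- NA_integer_
  }
  dimnames(calls) <- list(paste0("acc", seq_len(n)),
                          paste0("L", seq_len(nLoci)))
  major <- max.col(Q, ties.method = "first")
  g <- SnpGenotypes(calls, samples = data.frame(
    accession = rownames(calls),
    population = paste0("pop", major)))
  list(genotypes = g, truth = list(Q = Q, P = P, seed = seed))
}

#' Simulate quantitative traits with known variance components
#'
#' Group effects are Normal(0, `VB`) and accession residuals Normal(0,
#' `VW`), so the true \eqn{Q_{ST} = V_B/(V_B+V_W)}.  Each accession is
#' expanded to `plantsPerAccession` plant rows; flowering time is the
#' accession value on a days scale (baseline 100 d) and leaf number follows
#' the linear allometry `LN = lnSlope * FT`.  With `censorAt`, plants whose
#' flowering time exceeds the limit are marked unflowered with FT/LN
#' missing, emulating right-censoring at the end of the experiment.
#'
#' @param nGroups,perGroup design size (ignored when `grouping` given).
#' @param grouping optional factor of group labels per accession.
#' @param VB,VW between/within variances (days^2).
#' @param censorAt optional censoring limit in days.
#' @param plantsPerAccession plant rows per accession (default 5).
#' @param baselineFT mean flowering time in days (default 100).
#' @param lnSlope leaves per day (default 0.75, the allometry implied by
#'   a 150-leaf / 200-day late phenotype).
#' @param seed integer seed.
#' @return list: `traits` (plant-level table), `traitMeans` (per-accession
#'   FT means over flowered plants; NA when none flowered), `grouping`,
#'   `truth` (group effects, accession values).
#' @export
simulateTraits <- function(nGroups = 5, perGroup = 10, grouping = NULL,
                           VB = 100, VW = 100, censorAt = NULL,
                           plantsPerAccession = 5, baselineFT = 100,
                           lnSlope = 0.75, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(VB >= 0, VW >= 0)
  old <- .seedSet(seed)
  on.exit(.seedRestore(old))
  if (is.null(grouping))
    grouping <- factor(rep(paste0("grp", seq_len(nGroups)), each = perGroup))
  grouping <- factor(grouping)
  nAcc <- length(grouping)
  gEff <- setNames(rnorm(nlevels(grouping), 0, sqrt(VB)), levels(grouping))
  accVal <- baselineFT + gEff[as.character(grouping)] + rnorm(nAcc, 0, sqrt(VW))
  acc <- paste0("acc", seq_len(nAcc))
  rows <- lapply(seq_len(nAcc), function(i) {
    ft <- rep(accVal[i], plantsPerAccession)
    flowered <- if (is.null(censorAt)) rep(TRUE, plantsPerAccession)
                else ft <= censorAt
    data.frame(accession = acc[i],
               plant = seq_len(plantsPerAccession),
               FT = ifelse(flowered, ft, NA_real_),
               LN = ifelse(flowered, lnSlope * ft, NA_real_),
               flowered = flowered, vernalized = FALSE)
  })
  traits <- do.call(rbind, rows)
  means <- tapply(traits$FT, factor(traits$accession, levels = acc),
                  mean, na.rm = TRUE)
  means[is.nan(means)] <- NA_real_
  list(traits = traits,
       traitMeans = setNames(as.numeric(means), acc),
       grouping = setNames(grouping, acc),
       truth = list(groupEffects = gEff, accessionValues = accVal,
                    VB = VB, VW = VW, seed = seed))
}
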