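#' Pairwise genetic distances between samples, haplotypes or populations
#'
#' Sample- and haplotype-level distances are the count (or proportion) of
#' differing loci among co-scored loci (pairwise deletion of missing calls).
#' Population-level distances are the mean over all cross-population sample
#' pairs.
#'
#' @param g a [SnpGenotypes-class].
#' @param level `"sample"`, `"haplotype"` or `"population"`.
#' @param metric `"proportion"` (default) or `"count"`.
#' @return symmetric numeric matrix; pairs with zero co-scored loci get NA
#'   (a warning reports how many).
#' @export
geneticDistances <- function(g, level = c("sample", "haplotype",
                                          "population"),
                             metric = c("proportion", "count")) {
  level <- match.arg(level)
  metric <- match.arg(metric)
  if (level == "haplotype") g <- uniqueHaplotypes(g)
  calls <- callMatrix(g)
  if (nrow(calls) < 2) stop("need at least 2 units")
  d <- .pairDiff(calls, metric)
  if (anyNA(d[upper.tri(d)]))
    warning(sum(is.na(d[upper.tri(d)])),
            " pair(s) share no co-scored locus; distance set to NA")
  if (level == "population") {
    pop <- populations(g)
    lev <- levels(pop)
    out <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
    for (i in seq_along(lev)) for (j in seq_along(lev)) if (i < j) {
      block <- d[pop == lev[i], pop == lev[j], drop = FALSE]
      out[i, j] <- out[j, i] <- mean(block, na.rm = TRUE)
    }
    return(out)
  }
  d
}

## pairwise different-locus count/proportion with pairwise deletion
.pairDiff <- function(calls, metric = "proportion") {
  M <- !is.na(calls)
  A <- calls; A[!M] <- 0L                 # allele-1 indicator
  B <- (1L - calls); B[!M] <- 0L          # allele-0 indicator
  co <- M %*% t(M)
  same <- A %*% t(A) + B %*% t(B)
  diffs <- co - same
  d <- if (metric == "proportion") diffs / co else diffs
  d[co == 0] <- NA
  diag(d) <- 0
  dimnames(d) <- list(rownames(calls), rownames(calls))
  d
}

## squared allele-difference distance used by AMOVA: proportion of differing
## co-scored loci scaled to the panel size (equals the differing-locus count
## on complete data)
.amovaDist <- function(calls) {
  d <- .pairDiff(calls, "proportion") * ncol(calls)
  if (anyNA(d)) {
    mu <- mean(d[upper.tri(d)], na.rm = TRUE)
    d[is.na(d)] <- mu
    diag(d) <- 0
  }
  d
}

#' Analysis of molecular variance (AMOVA) for haploid genotypes
#'
#' Partitions squared allele-difference distances among hierarchical levels
#' in the Excoffier framework.  With populations only, variance is split
#' among and within populations and \eqn{F_{ST}} is reported.  Adding a
#' `groups` map (population -> group) yields the three-level design with
#' \eqn{F_{CT}} (among groups), \eqn{F_{SC}} (among populations within
#' groups) and \eqn{F_{ST}} (among populations overall).  Significance is
#' assessed by permutation: samples among populations for \eqn{F_{ST}},
#' whole populations among groups for \eqn{F_{CT}}, and samples among
#' populations within groups for \eqn{F_{SC}}.
#'
#' Negative variance components are retained in `components` and truncated
#' at zero when computing the percentage decomposition, matching the usual
#' reporting convention.
#'
#' @param g a [SnpGenotypes-class].
#' @param populations optional factor overriding the metadata populations.
#' @param groups optional named vector mapping population labels to group
#'   labels (or a factor over samples).
#' @param nPerm number of permutations (0 skips significance testing);
#'   the conventional choice for final analyses is 20000.
#' @param seed integer seed for the permutation stream.
#' @return an [AmovaResult-class].
#' @examples
#' sim <- simulateIsland(nPops = 4, samplesPerPop = 6, nLoci = 50,
#'                       F = 0.3, seed = 7)
#' amova(sim$genotypes, nPerm = 99, seed = 1)
#' @export
amova <- function(g, populations = NULL, groups = NULL, nPerm = 0L,
                  seed = 1L) {
  calls <- callMatrix(g)
  pop <- if (is.null(populations)) factor(sampleInfo(g)$population)
         else factor(populations)
  if (nlevels(pop) < 2) stop("AMOVA needs at least 2 populations")
  d <- .amovaDist(calls)
  grp <- NULL
  if (!is.null(groups)) {
    grp <- if (length(groups) == nSamples(g) && is.null(names(groups)))
      factor(groups)
    else factor(groups[as.character(pop)])
    if (anyNA(grp)) stop("groups must map every population")
  }
  obs <- .amovaComponents(d, pop, grp)
  pv <- rep(NA_real_, length(obs$indices))
  names(pv) <- names(obs$indices)
  if (nPerm > 0) {
    old <- .seedSet(seed)
    on.exit(.seedRestore(old))
    hits <- numeric(length(obs$indices))
    n <- length(pop)
    for (b in seq_len(nPerm)) {
      if (is.null(grp)) {
        pp <- pop[sample.int(n)]
        st <- .amovaComponents(d, pp, NULL)$indices
        hits[1] <- hits[1] + (st["FST"] >= obs$indices["FST"])
      } else {
        ## FST: samples among populations (ignoring groups)
        ppop <- pop[sample.int(n)]
        pgrp <- grp  # group of each sample fixed by its original position
        hits[match("FST", names(obs$indices))] <-
          hits[match("FST", names(obs$indices))] +
          (.amovaComponents(d, ppop, pgrp)$indices["FST"] >=
             obs$indices["FST"])
        ## FCT: permute whole populations among groups
        popLev <- levels(pop)
        g2p <- tapply(as.character(grp), pop, `[`, 1)
        permMap <- setNames(sample(g2p), popLev)
        pg <- factor(permMap[as.character(pop)])
        hits[match("FCT", names(obs$indices))] <-
          hits[match("FCT", names(obs$indices))] +
          (.amovaComponents(d, pop, pg)$indices["FCT"] >=
             obs$indices["FCT"])
        ## FSC: permute samples among populations within their group
        pp <- pop
        for (gl in levels(grp)) {
          sel <- which(grp == gl)
          pp[sel] <- pop[sel][sample.int(length(sel))]
        }
        hits[match("FSC", names(obs$indices))] <-
          hits[match("FSC", names(obs$indices))] +
          (.amovaComponents(d, pp, grp)$indices["FSC"] >=
             obs$indices["FSC"])
      }
    }
    pv <- (hits + 1) / (nPerm + 1)
    names(pv) <- names(obs$indices)
  }
  new("AmovaResult",
      design = if (is.null(grp)) "one-level" else "two-level",
      components = obs$components, percent = obs$percent,
      indices = obs$indices, pvalues = pv, df = obs$df, ss = obs$ss,
      nPerm = as.integer(nPerm), truncated = any(obs$components < 0))
}

## Excoffier variance components from a squared-distance matrix
.amovaComponents <- function(d, pop, grp = NULL) {
  n <- length(pop)
  tot <- sum(d[upper.tri(d)])
  ssWithin <- function(f) {
    s <- 0
    for (l in levels(f)) {
      idx <- which(f == l)
      if (length(idx) > 1)
        s <- s + sum(d[idx, idx][upper.tri(d[idx, idx])]) / length(idx)
    }
    s
  }
  SST <- tot / n
  SSWP <- ssWithin(pop)
  np <- table(pop)
  P <- nlevels(pop)
  if (is.null(grp)) {
    SSAP <- SST - SSWP
    dfA <- P - 1; dfW <- n - P
    MSA <- SSAP / dfA; MSW <- SSWP / dfW
    n0 <- (n - sum(np^2) / n) / dfA
    s2w <- MSW
    s2a <- (MSA - MSW) / n0
    totv <- max(s2a, 0) + max(s2w, 0)
    pct <- 100 * c(max(s2a, 0), max(s2w, 0)) / totv
    fst <- s2a / (s2a + s2w)
    list(components = c(amongPops = s2a, withinPops = s2w),
         percent = c(amongPops = pct[1], withinPops = pct[2]),
         indices = c(FST = fst),
         df = c(amongPops = dfA, withinPops = dfW),
         ss = c(amongPops = SSAP, withinPops = SSWP))
  } else {
    G <- nlevels(grp)
    ## within-group totals at the sample level
    SSWG <- ssWithin(grp)               # among pops within groups + within pops
    SSAPWG <- SSWG - SSWP
    SSAG <- SST - SSWG
    dfAG <- G - 1; dfAP <- P - G; dfWP <- n - P
    MSAG <- SSAG / dfAG; MSAP <- SSAPWG / dfAP; MSWP <- SSWP / dfWP
    ng <- tapply(seq_len(n), grp, length)
    ## population sizes within each group
    sumNp2ByG <- tapply(seq_len(n), grp, function(idx)
      sum(table(factor(pop[idx])[drop = TRUE])^2))
    n1 <- (n - sum(sumNp2ByG / ng)) / dfAP
    n2 <- (sum(sumNp2ByG / ng) - sum(np^2) / n) / dfAG
    n3 <- (n - sum(ng^2) / n) / dfAG
    s2c <- MSWP
    s2b <- (MSAP - s2c) / n1
    s2a <- (MSAG - s2c - n2 * s2b) / n3
    tr <- pmax(c(s2a, s2b, s2c), 0)
    pct <- 100 * tr / sum(tr)
    tot2 <- s2a + s2b + s2c
    list(components = c(amongGroups = s2a, amongPopsWithinGroups = s2b,
                        withinPops = s2c),
         percent = c(amongGroups = pct[1], amongPopsWithinGroups = pct[2],
                     withinPops = pct[3]),
         indices = c(FCT = s2a / tot2,
                     FSC = s2b / (s2b + s2c),
                     FST = (s2a + s2b) / tot2),
         df = c(amongGroups = dfAG, amongPopsWithinGroups = dfAP,
                withinPops = dfWP),
         ss = c(amongGroups = SSAG, amongPopsWithinGroups = SSAPWG,
                withinPops = SSWP))
  }
}

#' Pairwise F_ST between units with permutation p-values
#'
#' Each pair is analysed by the two-population AMOVA restricted to the
#' pair's samples; negative estimates are reported as computed.
#'
#' @param g a [SnpGenotypes-class].
#' @param units unit factor or `sampleInfo` column name (default
#'   `"population"`).
#' @param nPerm permutations per pair (0 = none).
#' @param seed integer seed.
#' @return list of matrices `fst` and `p`.
#' @export
pairwiseFst <- function(g, units = "population", nPerm = 0L, seed = 1L) {
  units <- .unitFactor(g, units)
  lev <- levels(units)
  sizes <- table(units)
  if (any(sizes < 2)) stop("each unit needs >= 2 samples: ",
                           paste(names(sizes)[sizes < 2], collapse = ", "))
  fst <- p <- matrix(NA_real_, length(lev), length(lev),
                     dimnames = list(lev, lev))
  diag(fst) <- 0
  for (i in seq_along(lev)) for (j in seq_along(lev)) if (i < j) {
    sel <- which(units %in% lev[c(i, j)])
    res <- amova(g[, sel], populations = droplevels(units[sel]),
                 nPerm = nPerm, seed = seed + i * length(lev) + j)
    fst[i, j] <- fst[j, i] <- res@indices["FST"]
    p[i, j] <- p[j, i] <- res@pvalues["FST"]
  }
  list(fst = fst, p = p)
}

#' Raw and net (corrected) allele differences between two groups
#'
#' Raw distance is the mean proportion of differing loci over cross-group
#' sample pairs; the net distance subtracts the mean within-group distances:
#' `corrected = raw - (withinA + withinB) / 2`.  The two-group F_ST comes
#' from the pairwise AMOVA.
#'
#' @param g a [SnpGenotypes-class].
#' @param groupA,groupB accession ids (or index vectors) of the two groups.
#' @param nPerm permutations for the F_ST p-value.
#' @param seed integer seed.
#' @return list with `raw`, `withinA`, `withinB`, `corrected`, `fst`, `p`.
#' @export
groupDistance <- function(g, groupA, groupB, nPerm = 0L, seed = 1L) {
  calls <- callMatrix(g)
  ix <- function(sel) {
    if (is.character(sel)) match(sel, rownames(calls)) else sel
  }
  ia <- ix(groupA); ib <- ix(groupB)
  if (length(ia) < 2 || length(ib) < 2) stop("both groups need >= 2 samples")
  d <- .pairDiff(calls, "proportion")
  ## frequency-weighted means (self-pairs included): invariant under
  ## duplicating samples, as befits distances between haplotype pools
  raw <- mean(d[ia, ib], na.rm = TRUE)
  wa <- mean(d[ia, ia], na.rm = TRUE)
  wb <- mean(d[ib, ib], na.rm = TRUE)
  sel <- c(ia, ib)
  lab <- factor(rep(c("A", "B"), c(length(ia), length(ib))))
  res <- amova(g[, sel], populations = lab, nPerm = nPerm, seed = seed)
  list(raw = raw, withinA = wa, withinB = wb,
       corrected = raw - (wa + wb) / 2,
       fst = unname(res@indices["FST"]), p = unname(res@pvalues["FST"]))
}
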