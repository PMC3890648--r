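#' Gene diversity (expected heterozygosity) per unit
#'
#' Per locus, the plain estimator is \eqn{1 - \sum_a p_a^2} over observed
#' allele frequencies; the unbiased estimator multiplies by
#' \eqn{n/(n-1)} with \eqn{n} the number of non-missing haploid calls at the
#' locus.  The unit value is the mean over loci with its standard error
#' (SE over loci, matching the +/- presentation of per-population diversity
#' tables).
#'
#' @param g a [SnpGenotypes-class].
#' @param unit accession ids or index selecting the samples; default all.
#' @param estimator `"plain"` (default, GenAlEx convention) or `"unbiased"`.
#' @return list with `mean`, `se`, and `perLocus` values.
#' @examples
#' g <- SnpGenotypes(matrix(c(0, 1), 2, 1,
#'                   dimnames = list(c("a", "b"), "L1")))
#' geneDiversity(g)$mean                      # 0.5
#' geneDiversity(g, estimator = "unbiased")$mean  # 1
#' @export
geneDiversity <- function(g, unit = NULL, estimator = c("plain", "unbiased")) {
  estimator <- match.arg(estimator)
  calls <- .unitCalls(g, unit)
  if (nrow(calls) < 2) stop("unit must contain at least 2 samples")
  per <- apply(calls, 2, function(v) {
    v <- v[!is.na(v)]
    n <- length(v)
    if (n == 0) return(NA_real_)
    p <- mean(v)
    h <- 1 - p^2 - (1 - p)^2
    if (estimator == "unbiased" && n > 1) h <- h * n / (n - 1)
    h
  })
  per <- per[!is.na(per)]
  if (!length(per)) stop("no scorable loci in unit")
  list(mean = mean(per), se = .se(per), perLocus = per)
}

#' Percentage of polymorphic loci in a unit
#'
#' 100 x (loci with at least two observed alleles within the unit) /
#' (loci with at least one observed call within the unit).
#'
#' @inheritParams geneDiversity
#' @return percentage in \[0, 100\].
#' @export
polymorphicFraction <- function(g, unit = NULL) {
  calls <- .unitCalls(g, unit)
  nAll <- apply(calls, 2, function(v) length(unique(na.omit(v))))
  scorable <- nAll >= 1
  if (!any(scorable)) stop("no scorable loci in unit")
  100 * sum(nAll >= 2) / sum(scorable)
}

## expected number of distinct alleles in a subsample of size g:
## sum over alleles of P(allele present) = 1 - C(N - N_a, g)/C(N, g)
.rarefyLocus <- function(counts, gSize) {
  N <- sum(counts)
  sum(1 - choose(N - counts, gSize) / choose(N, gSize))
}

.alleleCounts <- function(v) {
  v <- v[!is.na(v)]
  c(`0` = sum(v == 0), `1` = sum(v == 1))
}

#' Rarefied allelic richness per unit
#'
#' For each locus and unit, the expected number of distinct alleles in a
#' random subsample of `gSize` haploid calls:
#' \deqn{R = \sum_a \left[1 - \binom{N - N_a}{g} / \binom{N}{g}\right]}
#' with \eqn{N} non-missing calls in the unit and \eqn{N_a} copies of allele
#' \eqn{a}.  Loci at which any unit has fewer than `gSize` calls are skipped
#' (and listed in the result) so all units are rarefied to a common size.
#'
#' @param g a [SnpGenotypes-class].
#' @param units factor of unit labels per sample (or name of a `sampleInfo`
#'   column, default `"population"`).
#' @param gSize rarefaction subsample size; default the smallest per-locus
#'   non-missing call count across the compared units (ignoring empty loci).
#' @return data.frame with one row per unit: `unit`, `g`, `RS` (mean over
#'   loci), `se`, `nLoci`; skipped loci in `attr(., "skipped")`.
#' @examples
#' sim <- simulateIsland(nPops = 2, samplesPerPop = 6, nLoci = 30,
#'                       F = 0.2, seed = 1)
#' allelicRichness(sim$genotypes, gSize = 4)
#' @export
allelicRichness <- function(g, units = "population", gSize = NULL) {
  calls <- callMatrix(g)
  units <- .unitFactor(g, units)
  cnt <- .unitAlleleCounts(calls, units)   # list: unit -> 2 x L matrix
  Ns <- vapply(cnt, colSums, numeric(ncol(calls)))
  if (is.null(gSize)) {
    pos <- Ns[Ns > 0]
    if (!length(pos)) stop("no observed calls")
    gSize <- min(pos)
  }
  if (gSize < 1) stop("gSize must be >= 1")
  usable <- apply(Ns >= gSize, 1, all)
  if (!any(usable)) stop("no locus has gSize calls in every unit")
  res <- lapply(names(cnt), function(u) {
    vals <- vapply(which(usable), function(l)
      .rarefyLocus(cnt[[u]][, l], gSize), numeric(1))
    data.frame(unit = u, g = gSize, RS = mean(vals), se = .se(vals),
               nLoci = length(vals))
  })
  out <- do.call(rbind, res)
  attr(out, "skipped") <- colnames(calls)[!usable]
  out
}

#' Rarefied private allelic richness per unit
#'
#' The expected number of alleles present in a rarefied subsample of the
#' focal unit and absent from equally rarefied subsamples of every other
#' unit: with \eqn{Q_u(a) = 1 - \binom{N_u - N_{u,a}}{g}/\binom{N_u}{g}} the
#' probability that allele \eqn{a} appears in unit \eqn{u}'s subsample,
#' \deqn{R_P(j) = \sum_a Q_j(a) \prod_{k \ne j} (1 - Q_k(a)).}
#'
#' @inheritParams allelicRichness
#' @return data.frame with `unit`, `g`, `RP`, `se`, `nLoci`.
#' @export
privateAllelicRichness <- function(g, units = "population", gSize = NULL) {
  calls <- callMatrix(g)
  units <- .unitFactor(g, units)
  if (nlevels(units) < 2) stop("private allelic richness needs >= 2 units")
  cnt <- .unitAlleleCounts(calls, units)
  Ns <- vapply(cnt, colSums, numeric(ncol(calls)))
  if (is.null(gSize)) {
    pos <- Ns[Ns > 0]
    gSize <- min(pos)
  }
  if (gSize < 1) stop("gSize must be >= 1")
  usable <- apply(Ns >= gSize, 1, all)
  if (!any(usable)) stop("no locus has gSize calls in every unit")
  ## Q[[u]]: 2 x L matrix of subsample-presence probabilities
  Q <- lapply(cnt, function(m) {
    N <- colSums(m)
    t(vapply(seq_len(ncol(m)), function(l) {
      if (N[l] < gSize) return(c(NA_real_, NA_real_))
      1 - choose(N[l] - m[, l], gSize) / choose(N[l], gSize)
    }, numeric(2)))                         # L x 2
  })
  res <- lapply(names(cnt), function(u) {
    others <- setdiff(names(cnt), u)
    vals <- vapply(which(usable), function(l) {
      sum(vapply(1:2, function(a) {
        Q[[u]][l, a] * prod(vapply(others, function(k)
          1 - Q[[k]][l, a], numeric(1)))
      }, numeric(1)))
    }, numeric(1))
    data.frame(unit = u, g = gSize, RP = mean(vals), se = .se(vals),
               nLoci = length(vals))
  })
  out <- do.call(rbind, res)
  attr(out, "skipped") <- colnames(calls)[!usable]
  out
}

#' Nucleotide diversity of an alignment
#'
#' \eqn{\pi} is the mean over sequence pairs of (differences / compared
#' sites), with gaps and ambiguity codes excluded pairwise.  When a site
#' classification is supplied, `piSilent` restricts the computation to sites
#' labelled `"silent"`.
#'
#' @param alignment a [Biostrings::DNAStringSet], character vector of
#'   equal-length sequences, or character matrix (sequences x sites).
#' @param siteClasses optional per-site labels in
#'   `{"silent", "nonsilent", "excluded"}`.
#' @return list with `pi`, `piSilent` (NA without classification),
#'   `nSequences`, `nPolymorphisms`, and `siteClasses`.
#' @export
nucleotideDiversity <- function(alignment, siteClasses = NULL) {
  if (is(alignment, "DNAStringSet"))
    alignment <- as.character(alignment)
  if (is.character(alignment) && !is.matrix(alignment)) {
    if (length(unique(nchar(alignment))) != 1)
      stop("sequences must be aligned to equal length")
    alignment <- do.call(rbind, strsplit(toupper(alignment), ""))
  }
  m <- toupper(alignment)
  if (nrow(m) < 2) stop("need at least 2 sequences")
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  piOver <- function(sites) {
    if (!length(sites)) stop("no comparable sites")
    tot <- 0; np <- 0
    for (pr in combn(nrow(m), 2, simplify = FALSE)) {
      ok <- valid[pr[1], sites] & valid[pr[2], sites]
      if (!any(ok)) stop("a sequence pair has zero comparable sites")
      tot <- tot + sum(m[pr[1], sites][ok] != m[pr[2], sites][ok]) / sum(ok)
      np <- np + 1
    }
    tot / np
  }
  allSites <- seq_len(ncol(m))
  poly <- vapply(allSites, function(s) {
    v <- m[valid[, s], s]
    length(unique(v)) > 1
  }, logical(1))
  out <- list(pi = piOver(allSites), piSilent = NA_real_,
              nSequences = nrow(m), nPolymorphisms = sum(poly),
              siteClasses = siteClasses)
  if (!is.null(siteClasses)) {
    stopifnot(length(siteClasses) == ncol(m))
    out$piSilent <- piOver(which(siteClasses == "silent"))
  }
  out
}

#' Per-unit diversity table
#'
#' Assembles the per-population (or per-region) diversity summary: sample
#' count N, haplotype count N_H, percentage of polymorphic loci PL, gene
#' diversity H_S +/- SE, rarefied allelic richness R_S +/- SE and private
#' allelic richness R_P +/- SE.  Units with a single sample get NA for the
#' frequency-based statistics.
#'
#' @param g a [SnpGenotypes-class].
#' @param units unit factor or `sampleInfo` column name (default
#'   `"population"`).
#' @param gSize rarefaction size, see [allelicRichness()].
#' @param estimator gene-diversity estimator, see [geneDiversity()].
#' @return data.frame with one row per unit.
#' @export
diversityTable <- function(g, units = "population", gSize = NULL,
                           estimator = "plain") {
  units <- .unitFactor(g, units)
  hs <- collapseHaplotypes(g)
  nh <- apply(haplotypeCounts(hs)[levels(units), , drop = FALSE] > 0, 1, sum)
  rs <- tryCatch(allelicRichness(g, units, gSize), error = function(e) NULL)
  rp <- tryCatch(privateAllelicRichness(g, units, gSize),
                 error = function(e) NULL)
  rows <- lapply(levels(units), function(u) {
    sel <- which(units == u)
    one <- length(sel) < 2
    hd <- if (one) NULL else geneDiversity(g, sel, estimator)
    data.frame(
      unit = u, N = length(sel), NH = unname(nh[u]),
      PL = if (one) NA_real_ else polymorphicFraction(g, sel),
      HS = if (one) NA_real_ else hd$mean,
      HS_se = if (one) NA_real_ else hd$se,
      RS = if (is.null(rs)) NA_real_ else rs$RS[rs$unit == u],
      RS_se = if (is.null(rs)) NA_real_ else rs$se[rs$unit == u],
      RP = if (is.null(rp)) NA_real_ else rp$RP[rp$unit == u],
      RP_se = if (is.null(rp)) NA_real_ else rp$se[rp$unit == u],
      g = if (is.null(rs)) NA_real_ else rs$g[1])
  })
  do.call(rbind, rows)
}

## ---- internal helpers ----

.se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0

.unitCalls <- function(g, unit) {
  calls <- callMatrix(g)
  if (is.null(unit)) return(calls)
  if (is.character(unit)) {
    idx <- match(unit, rownames(calls))
    if (anyNA(idx)) stop("unknown accession id(s) in unit")
    unit <- idx
  }
  calls[unit, , drop = FALSE]
}

.unitFactor <- function(g, units) {
  if (is.character(units) && length(units) == 1) {
    si <- sampleInfo(g)
    if (!units %in% names(si)) stop("no sample column '", units, "'")
    units <- si[[units]]
  }
  if (length(units) != nSamples(g))
    stop("units must have one label per sample")
  factor(units)
}

.unitAlleleCounts <- function(calls, units) {
  out <- lapply(levels(units), function(u) {
    sub <- calls[units == u, , drop = FALSE]
    rbind(`0` = colSums(sub == 0, na.rm = TRUE),
          `1` = colSums(sub == 1, na.rm = TRUE))
  })
  names(out) <- levels(units)
  out
}
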