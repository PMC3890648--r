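#' Great-circle distances between population sites
#'
#' Haversine distances on a sphere of radius 6371.0088 km between the
#' recorded site of each population (the coordinates of its first sample).
#'
#' @param g a [SnpGenotypes-class] with `latitude`/`longitude` in
#'   `sampleInfo`, or a data.frame with columns `population`, `latitude`,
#'   `longitude`.
#' @return symmetric matrix of distances in km.
#' @export
geoDistances <- function(g) {
  meta <- if (is(g, "SnpGenotypes")) sampleInfo(g) else as.data.frame(g)
  if (!all(c("latitude", "longitude") %in% names(meta)))
    stop("latitude/longitude columns required")
  pop <- factor(meta$population)
  lat <- tapply(meta$latitude, pop, `[`, 1)
  lon <- tapply(meta$longitude, pop, `[`, 1)
  if (anyNA(lat) || anyNA(lon))
    stop("missing coordinates for population(s): ",
         paste(levels(pop)[is.na(lat) | is.na(lon)], collapse = ", "))
  pts <- cbind(lon, lat)
  n <- nlevels(pop)
  d <- matrix(0, n, n, dimnames = list(levels(pop), levels(pop)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    d[i, j] <- d[j, i] <-
      geosphere::distHaversine(pts[i, ], pts[j, ], r = 6371008.8) / 1000
  }
  d
}

#' Mantel test of association between two distance matrices
#'
#' The statistic is the Pearson correlation over off-diagonal pairs; the
#' permutation null jointly permutes rows and columns of the second matrix.
#' The regression of `b` on `a` over the same pairs is reported
#' (isolation-by-distance slope when `a` is geographic and `b` genetic).
#'
#' @param a,b symmetric distance matrices with identical unit order.
#' @param nPerm permutations, default 10000.
#' @param seed integer seed.
#' @param alternative `"greater"` (default; positive association, the usual
#'   IBD direction), `"less"`, or `"two.sided"`.
#' @return a [MantelResult-class].
#' @examples
#' sim <- simulateSteppingStone(nPops = 8, samplesPerPop = 4, nLoci = 60,
#'                              spatialSigma = 0.6, seed = 2)
#' gen <- geneticDistances(sim$genotypes, level = "population")
#' mantelTest(sim$geo, gen, nPerm = 199, seed = 3)
#' @export
mantelTest <- function(a, b, nPerm = 10000L, seed = 1L,
                       alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(identical(dim(a), dim(b)))
  n <- nrow(a)
  if (n < 4) stop("Mantel test needs at least 4 units")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b)))
    stop("matrix unit ids do not match")
  ut <- upper.tri(a)
  x <- a[ut]; y <- b[ut]
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant distance matrix: Mantel r undefined")
  r <- cor(x, y)
  fit <- lm(y ~ x)
  old <- .seedSet(seed)
  on.exit(.seedRestore(old))
  hits <- 0L
  for (k in seq_len(nPerm)) {
    idx <- sample.int(n)
    rp <- cor(x, b[idx, idx][ut])
    hits <- hits + switch(alternative,
      greater = rp >= r, less = rp <= r, two.sided = abs(rp) >= abs(r))
  }
  p <- if (nPerm > 0) (hits + 1) / (nPerm + 1) else NA_real_
  new("MantelResult", r = r, slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]), p = p, nPerm = as.integer(nPerm),
      alternative = alternative, n = as.integer(n))
}

#' Compare isolation-by-distance strength between two regions
#'
#' Tests whether the Mantel correlation and IBD regression slope differ
#' between two sets of populations.  Both regions' statistics are computed
#' on the within-region blocks of pooled distance matrices; the null
#' distribution permutes the population-to-region labels and recomputes both
#' statistics, giving a two-sided p-value for each difference (A minus B).
#'
#' The pooled-matrix interface (rather than two independent matrix pairs) is
#' required because label permutation reassigns populations across regions
#' and therefore needs the cross-region distances.
#'
#' @param geo,gen pooled symmetric matrices over all populations of both
#'   regions, identical order.
#' @param regions factor with two levels assigning each population to a
#'   region.
#' @param nPerm label permutations.
#' @param seed integer seed.
#' @return list with `dr`, `dslope` (observed differences), `pR`, `pSlope`,
#'   and the per-region [MantelResult-class] objects.
#' @export
compareIbd <- function(geo, gen, regions, nPerm = 999L, seed = 1L) {
  geo <- as.matrix(geo); gen <- as.matrix(gen)
  regions <- factor(regions)
  stopifnot(nrow(geo) == length(regions), nlevels(regions) == 2)
  lev <- levels(regions)
  stat <- function(lab) {
    out <- lapply(lev, function(l) {
      sel <- which(lab == l)
      ut <- upper.tri(geo[sel, sel])
      x <- geo[sel, sel][ut]; y <- gen[sel, sel][ut]
      if (length(x) < 3 || sd(x) == 0) return(c(NA, NA))
      c(cor(x, y), unname(coef(lm(y ~ x))[2]))
    })
    c(out[[1]][1] - out[[2]][1], out[[1]][2] - out[[2]][2])
  }
  mA <- .subMantel(geo, gen, regions == lev[1])
  mB <- .subMantel(geo, gen, regions == lev[2])
  obs <- stat(regions)
  old <- .seedSet(seed)
  on.exit(.seedRestore(old))
  hitsR <- hitsS <- 0L
  for (k in seq_len(nPerm)) {
    st <- stat(regions[sample.int(length(regions))])
    if (!anyNA(st)) {
      hitsR <- hitsR + (abs(st[1]) >= abs(obs[1]))
      hitsS <- hitsS + (abs(st[2]) >= abs(obs[2]))
    } else { hitsR <- hitsR + 1L; hitsS <- hitsS + 1L }
  }
  list(dr = obs[1], dslope = obs[2],
       pR = (hitsR + 1) / (nPerm + 1), pSlope = (hitsS + 1) / (nPerm + 1),
       mantelA = mA, mantelB = mB)
}

.subMantel <- function(geo, gen, sel) {
  mantelTest(geo[sel, sel], gen[sel, sel], nPerm = 0L)
}
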