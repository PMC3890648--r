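#' Read a haploid SNP genotype table with its SNP map and sample metadata
#'
#' The genotype table is delimited text with a header row of locus ids and
#' the accession id in the first column; calls may be coded `0`/`1`, `A`/`B`,
#' or as the two mapped nucleotides when the SNP map provides `allele0` /
#' `allele1` columns.  Any other symbol is mapped to missing and counted.
#'
#' @param tablePath path to the genotype table (samples x loci).
#' @param mapPath optional path to the SNP map (columns `id`, and optionally
#'   `chromosome`, `position`, `panel`, `allele0`, `allele1`).
#' @param metaPath optional path to sample metadata (columns `accession`,
#'   `population`, optionally `subregion`, `region`, `latitude`,
#'   `longitude`).
#' @param sep field separator, default tab (`","` also common).
#' @param missingCodes symbols treated as missing in addition to unmappable
#'   ones.
#' @param idColumn name or index of the accession-id column, default 1.
#' @return a [SnpGenotypes-class]; the number of calls coerced to missing is
#'   recorded in `metadata(x)$unknownCalls` and reported via `message()`.
#' @export
readGenotypes <- function(tablePath, mapPath = NULL, metaPath = NULL,
                          sep = "\t", missingCodes = c("", "NA", "N", "-9",
                                                       "?", "-"),
                          idColumn = 1L) {
  tab <- read.delim(tablePath, sep = sep, header = TRUE,
                    check.names = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (is.character(idColumn)) idColumn <- match(idColumn, names(tab))
  ids <- as.character(tab[[idColumn]])
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  raw <- as.matrix(tab[, -idColumn, drop = FALSE])
  rownames(raw) <- ids

  map <- NULL
  if (!is.null(mapPath)) {
    map <- read.delim(mapPath, sep = sep, header = TRUE,
                      stringsAsFactors = FALSE)
    if (!"id" %in% names(map)) names(map)[1] <- "id"
    miss <- setdiff(colnames(raw), as.character(map$id))
    if (length(miss))
      stop("locus id(s) absent from map: ",
           paste(head(miss), collapse = ", "))
  }

  calls <- matrix(NA_integer_, nrow(raw), ncol(raw),
                  dimnames = dimnames(raw))
  unknown <- 0L
  for (j in seq_len(ncol(raw))) {
    v <- trimws(raw[, j])
    v[v %in% missingCodes] <- NA
    code <- rep(NA_integer_, length(v))
    code[v %in% c("0", "A", "a")] <- 0L
    code[v %in% c("1", "B", "b")] <- 1L
    if (!is.null(map) && all(c("allele0", "allele1") %in% names(map))) {
      row <- map[match(colnames(raw)[j], map$id), ]
      code[v == toupper(row$allele0)] <- 0L
      code[v == toupper(row$allele1)] <- 1L
    }
    unknown <- unknown + sum(is.na(code) & !is.na(v))
    calls[, j] <- code
  }
  if (unknown > 0)
    message(unknown, " unknown call symbol(s) mapped to missing")

  meta <- NULL
  if (!is.null(metaPath)) {
    meta <- read.delim(metaPath, sep = sep, header = TRUE,
                       stringsAsFactors = FALSE)
    if (!"accession" %in% names(meta)) names(meta)[1] <- "accession"
    miss <- setdiff(ids, as.character(meta$accession))
    if (length(miss))
      stop("sample(s) absent from metadata: ",
           paste(head(miss), collapse = ", "))
  }
  g <- SnpGenotypes(calls, samples = meta, loci = map)
  S4Vectors::metadata(g)$unknownCalls <- unknown
  g
}

#' Filter SNP loci by missingness, monomorphism and population coverage
#'
#' Filters are applied in a fixed order so the per-filter counts are
#' reproducible: (1) loci whose missing fraction is at or above `maxMissing`
#' are removed; (2) within `scope`, loci with a single observed allele are
#' removed when `dropMonomorphic`; (3) loci with no observed call in every
#' member of at least one population of the scope are removed when
#' `dropPopulationMissing`.
#'
#' @param g a [SnpGenotypes-class].
#' @param maxMissing maximum tolerated per-locus missing fraction (computed
#'   over `scope`); loci with fraction `>= maxMissing` are dropped.  Use
#'   `1` (default `0.25`) to disable.
#' @param dropMonomorphic drop loci with a single observed allele in scope.
#' @param dropPopulationMissing drop loci entirely missing within any scope
#'   population.
#' @param scope accession ids (or logical/integer index) restricting both
#'   the filter statistics and the returned samples; default all samples.
#' @return the filtered [SnpGenotypes-class] restricted to `scope`, with the
#'   per-filter counts in `metadata(.)$filterReport` (fields `input`,
#'   `missingness`, `monomorphic`, `populationMissing`, `retained`).
#' @examples
#' sim <- simulateIsland(nPops = 3, samplesPerPop = 4, nLoci = 20,
#'                       F = 0.2, seed = 1)
#' gf <- filterLoci(sim$genotypes)
#' S4Vectors::metadata(gf)$filterReport
#' @export
filterLoci <- function(g, maxMissing = 0.25, dropMonomorphic = TRUE,
                       dropPopulationMissing = FALSE, scope = NULL) {
  stopifnot(is(g, "SnpGenotypes"))
  calls <- callMatrix(g)
  if (!is.null(scope)) {
    if (is.character(scope)) scope <- match(scope, rownames(calls))
    if (anyNA(scope)) stop("scope contains unknown accession ids")
    g <- g[, scope]
    calls <- calls[scope, , drop = FALSE]
  }
  if (nrow(calls) == 0) stop("empty scope")
  pop <- populations(g)
  keep <- rep(TRUE, ncol(calls))
  report <- list(input = ncol(calls))

  missFrac <- colMeans(is.na(calls))
  dropMiss <- missFrac >= maxMissing
  report$missingness <- sum(dropMiss)
  keep <- keep & !dropMiss

  if (dropMonomorphic) {
    nAll <- vapply(seq_len(ncol(calls)), function(j)
      length(unique(na.omit(calls[, j]))), integer(1))
    dropMono <- keep & nAll < 2
    report$monomorphic <- sum(dropMono)
    keep <- keep & !dropMono
  } else report$monomorphic <- 0L

  if (dropPopulationMissing) {
    popAllMissing <- vapply(seq_len(ncol(calls)), function(j) {
      any(tapply(is.na(calls[, j]), pop, all))
    }, logical(1))
    dropPop <- keep & popAllMissing
    report$populationMissing <- sum(dropPop)
    keep <- keep & !dropPop
  } else report$populationMissing <- 0L

  report$retained <- sum(keep)
  if (!any(keep)) stop("all loci removed by filtering: empty panel")
  out <- g[keep, ]
  S4Vectors::metadata(out)$filterReport <- report
  out
}

#' Collapse samples into distinct multilocus haplotypes
#'
#' Under the `strict` rule two samples share a haplotype iff their call
#' vectors are identical, with missing treated as a state of its own.  Under
#' the `wildcard` rule two samples match iff they agree at every locus where
#' both are observed; matching is closed transitively (union-find), so a
#' largely missing sample can bridge otherwise distinct haplotypes.
#'
#' @param g a [SnpGenotypes-class].
#' @param missingRule `"strict"` (default) or `"wildcard"`.
#' @return a [HaplotypeSet-class].
#' @export
collapseHaplotypes <- function(g, missingRule = c("strict", "wildcard")) {
  missingRule <- match.arg(missingRule)
  calls <- callMatrix(g)
  if (nrow(calls) == 0) stop("empty genotype matrix")
  pop <- populations(g)
  n <- nrow(calls)

  if (missingRule == "strict") {
    key <- apply(calls, 1, function(v)
      paste(ifelse(is.na(v), ".", v), collapse = ""))
    idx <- as.integer(factor(key, levels = unique(key)))
  } else {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      ri <- find(i); rj <- find(j)
      if (ri == rj) next
      both <- !is.na(calls[i, ]) & !is.na(calls[j, ])
      if (!any(calls[i, both] != calls[j, both]))
        parent[max(ri, rj)] <- min(ri, rj)
    }
    roots <- vapply(seq_len(n), find, integer(1))
    idx <- as.integer(factor(roots, levels = unique(roots)))
  }

  reps <- match(seq_len(max(idx)), idx)
  haps <- calls[reps, , drop = FALSE]
  rownames(haps) <- paste0("H", seq_len(nrow(haps)))
  tab <- table(pop, factor(idx, levels = seq_len(nrow(haps))))
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = list(levels(pop), rownames(haps)))
  new("HaplotypeSet", haplotypes = haps,
      assignment = setNames(idx, rownames(calls)),
      population = pop, counts = counts, rule = missingRule)
}

#' Reduce a genotype matrix to one sample per distinct haplotype
#'
#' Convenience for clustering analyses that operate on distinct haplotypes
#' (the first sample carrying each haplotype is retained).
#'
#' @param g a [SnpGenotypes-class].
#' @param missingRule passed to [collapseHaplotypes()].
#' @return a [SnpGenotypes-class] with one column per haplotype.
#' @export
uniqueHaplotypes <- function(g, missingRule = "strict") {
  hs <- collapseHaplotypes(g, missingRule)
  reps <- match(seq_len(nHaplotypes(hs)), hs@assignment)
  g[, reps]
}

#' Write genotypes in STRUCTURE plain-text format
#'
#' One row per haploid individual: label, integer population code, then one
#' allele column per locus with `-9` for missing.  A header row of locus ids
#' is written.
#'
#' @param g a [SnpGenotypes-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(g, path) {
  calls <- callMatrix(g)
  pop <- as.integer(populations(g))
  body <- calls
  body[is.na(body)] <- -9L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(calls), collapse = " "), con)
  for (i in seq_len(nrow(calls)))
    writeLines(paste(c(rownames(calls)[i], pop[i], body[i, ]),
                     collapse = " "), con)
  invisible(path)
}

#' Read a STRUCTURE-format file written by [writeStructure()]
#'
#' @param path file path.
#' @param populationLabels optional labels for the integer population codes.
#' @return a [SnpGenotypes-class].
#' @export
readStructure <- function(path, populationLabels = NULL) {
  lines <- readLines(path)
  lociIds <- strsplit(lines[1], " +")[[1]]
  rows <- strsplit(lines[-1], " +")
  ids <- vapply(rows, `[`, character(1), 1)
  pop <- as.integer(vapply(rows, `[`, character(1), 2))
  calls <- t(vapply(rows, function(r) as.integer(r[-(1:2)]),
                    integer(length(lociIds))))
  calls[calls == -9L] <- NA_integer_
  dimnames(calls) <- list(ids, lociIds)
  popLab <- if (is.null(populationLabels)) as.character(pop)
            else populationLabels[pop]
  SnpGenotypes(calls,
               samples = data.frame(accession = ids, population = popLab))
}

#' Write a phylogenetic tree as Newick
#'
#' Thin wrapper over [ape::write.tree()] so pipeline outputs go through one
#' surface; bootstrap supports stored in `tree$node.label` are written.
#'
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNewickTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
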