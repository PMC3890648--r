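#' @import methods
#' @import stats
#' @importFrom utils combn head read.delim write.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
NULL

#' SnpGenotypes: haploid biallelic SNP calls with sample and locus metadata
#'
#' `SnpGenotypes` extends
#' [SummarizedExperiment::SummarizedExperiment-class] to hold a panel of
#' haploid biallelic SNP calls.  Loci are rows and samples are columns; the
#' single assay `"calls"` stores integer codes `0`/`1` with `NA` for missing
#' data.  `colData` carries the sample hierarchy (accession, population,
#' optional subregion/region and coordinates) and `rowData` the SNP map
#' (chromosome, position, panel of origin).
#'
#' Selfing lines are treated as effectively haploid: each accession
#' contributes one allele per locus, so all diversity statistics in this
#' package are computed on haploid allele counts.
#'
#' @slot .. inherited from SummarizedExperiment.
#' @seealso [SnpGenotypes()] for construction, [callMatrix()],
#'   [sampleInfo()], [lociInfo()], [populations()].
#' @export
setClass("SnpGenotypes", contains = "SummarizedExperiment")

setValidity("SnpGenotypes", function(object) {
  msg <- character()
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'calls' is required")
  else {
    a <- SummarizedExperiment::assay(object, "calls")
    bad <- a[!is.na(a)]
    if (length(bad) && !all(bad %in% c(0L, 1L)))
      msg <- c(msg, "calls must be coded 0/1 with NA for missing")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("accession", "population") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'accession' and 'population'")
  else if (anyDuplicated(cd$accession))
    msg <- c(msg, "duplicate accession ids")
  if ("latitude" %in% colnames(cd)) {
    lat <- cd$latitude
    if (any(abs(lat[!is.na(lat)]) > 90)) msg <- c(msg, "|latitude| > 90")
  }
  if ("longitude" %in% colnames(cd)) {
    lon <- cd$longitude
    if (any(abs(lon[!is.na(lon)]) > 180)) msg <- c(msg, "|longitude| > 180")
  }
  rd <- SummarizedExperiment::rowData(object)
  if ("position" %in% colnames(rd)) {
    pos <- rd$position
    if (any(pos[!is.na(pos)] < 1)) msg <- c(msg, "positions must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SnpGenotypes object
#'
#' @param calls integer/numeric matrix of haploid calls, samples in rows and
#'   loci in columns, coded 0/1 with `NA` for missing.  Row names are
#'   accession ids, column names locus ids.
#' @param samples data.frame of sample metadata with at least columns
#'   `accession` and `population` (optionally `subregion`, `region`,
#'   `latitude`, `longitude`).  Defaults to accession = rownames, one
#'   population.
#' @param loci data.frame of locus metadata (optionally `chromosome`,
#'   `position`, `panel`), one row per locus.
#' @return a [SnpGenotypes-class] object.
#' @examples
#' m <- matrix(c(0, 1, 0, 1, 1, 0), nrow = 3,
#'             dimnames = list(paste0("s", 1:3), c("L1", "L2")))
#' g <- SnpGenotypes(m, samples = data.frame(
#'   accession = paste0("s", 1:3), population = c("A", "A", "B")))
#' g
#' @export
SnpGenotypes <- function(calls, samples = NULL, loci = NULL) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("sample", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("locus", seq_len(ncol(calls)))
  storage.mode(calls) <- "integer"
  if (is.null(samples))
    samples <- data.frame(accession = rownames(calls), population = "pop1")
  if (is.null(loci))
    loci <- data.frame(row.names = colnames(calls))
  if (!is.null(samples$accession) &&
      !identical(as.character(samples$accession), rownames(calls))) {
    idx <- match(rownames(calls), as.character(samples$accession))
    if (anyNA(idx))
      stop("sample metadata missing accession(s): ",
           paste(head(rownames(calls)[is.na(idx)]), collapse = ", "))
    samples <- samples[idx, , drop = FALSE]
  }
  rownames(samples) <- rownames(calls)
  if (!is.null(loci$id) &&
      !identical(as.character(loci$id), colnames(calls))) {
    idx <- match(colnames(calls), as.character(loci$id))
    if (anyNA(idx))
      stop("locus map missing locus id(s): ",
           paste(head(colnames(calls)[is.na(idx)]), collapse = ", "))
    loci <- loci[idx, , drop = FALSE]
  }
  rownames(loci) <- colnames(calls)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = t(calls)),
    colData = S4Vectors::DataFrame(samples),
    rowData = S4Vectors::DataFrame(loci))
  new("SnpGenotypes", se)
}

#' HaplotypeSet: distinct multilocus haplotypes and their sample assignment
#'
#' @slot haplotypes integer matrix, one row per distinct haplotype,
#'   loci in columns (NA = missing under the strict rule; representative
#'   calls under the wildcard rule).
#' @slot assignment integer vector mapping each sample to a haplotype row,
#'   named by accession.
#' @slot population factor of population labels per sample.
#' @slot counts integer matrix population x haplotype.
#' @slot rule matching rule used, `"strict"` or `"wildcard"`.
#' @seealso [collapseHaplotypes()]
#' @export
setClass("HaplotypeSet",
  representation(haplotypes = "matrix", assignment = "integer",
                 population = "factor", counts = "matrix",
                 rule = "character"))

setValidity("HaplotypeSet", function(object) {
  msg <- character()
  if (length(object@assignment) != length(object@population))
    msg <- c(msg, "assignment and population lengths differ")
  if (any(object@assignment < 1L) ||
      any(object@assignment > nrow(object@haplotypes)))
    msg <- c(msg, "assignment indexes outside haplotype table")
  if (sum(object@counts) != length(object@assignment))
    msg <- c(msg, "per-population counts do not sum to the sample count")
  if (length(msg)) msg else TRUE
})

#' AmovaResult: hierarchical variance components with permutation p-values
#'
#' @slot design `"one-level"` (among/within populations) or `"two-level"`
#'   (among groups / among populations within groups / within populations).
#' @slot components named numeric variance components (raw, may be negative).
#' @slot percent named numeric percentages of total (negative components
#'   truncated at zero before computing percentages).
#' @slot indices named fixation indices (FST; and FSC, FCT for two-level).
#' @slot pvalues permutation p-values for the indices (NA when nPerm = 0).
#' @slot df,ss degrees of freedom and sums of squares per stratum.
#' @slot nPerm number of permutations used.
#' @slot truncated TRUE if any raw component was negative.
#' @export
setClass("AmovaResult",
  representation(design = "character", components = "numeric",
                 percent = "numeric", indices = "numeric",
                 pvalues = "numeric", df = "numeric", ss = "numeric",
                 nPerm = "integer", truncated = "logical"))

#' MantelResult: Mantel correlation with regression summary
#'
#' @slot r Pearson correlation over off-diagonal pairs.
#' @slot slope,intercept least-squares regression of the second matrix on
#'   the first.
#' @slot p permutation p-value.
#' @slot nPerm permutations used; @slot alternative test direction;
#'   @slot n number of units.
#' @export
setClass("MantelResult",
  representation(r = "numeric", slope = "numeric", intercept = "numeric",
                 p = "numeric", nPerm = "integer", alternative = "character",
                 n = "integer"))

#' MembershipMatrix: ancestry proportions from one admixture-model run
#'
#' @slot Q n x K matrix of membership proportions (rows on the simplex).
#' @slot P K x L matrix of cluster allele-1 frequencies.
#' @slot logLik final observed-data log-likelihood.
#' @slot evidence penalized log-likelihood approximating the log marginal
#'   likelihood of the model (see [admixtureFit()]); the quantity compared
#'   across K by [selectK()].
#' @slot seed integer seed of the run.
#' @slot converged,iterations EM convergence status.
#' @seealso [admixtureFit()], [runAdmixture()], [alignRuns()]
#' @export
setClass("MembershipMatrix",
  representation(Q = "matrix", P = "matrix", logLik = "numeric",
                 evidence = "numeric", seed = "integer",
                 converged = "logical", iterations = "integer"))

setValidity("MembershipMatrix", function(object) {
  rs <- rowSums(object@Q)
  if (any(abs(rs - 1) > 1e-6)) return("Q rows must sum to 1")
  if (any(object@Q < -1e-9 | object@Q > 1 + 1e-9))
    return("Q entries must lie in [0,1]")
  TRUE
})

#' RunEnsemble: replicate admixture runs at one K, aligned
#'
#' @slot runs list of [MembershipMatrix-class] replicates.
#' @slot consensus mean of the label-aligned Q matrices.
#' @slot Hprime mean pairwise symmetric similarity after alignment.
#' @slot K number of clusters.
#' @export
setClass("RunEnsemble",
  representation(runs = "list", consensus = "matrix", Hprime = "numeric",
                 K = "integer"))

#' QstResult: quantitative-trait differentiation from variance components
#'
#' @slot trait trait label.
#' @slot VB,VW between- and within-group variance components (VB truncated at
#'   zero; the raw estimate is kept in VBraw).
#' @slot VBraw raw between-group component, possibly negative.
#' @slot Qst VB / (VB + VW).
#' @slot method `"reml"` or `"anova"`.
#' @slot p permutation p-value (NA unless requested).
#' @slot groups group labels used.
#' @slot truncated TRUE if VBraw < 0.
#' @export
setClass("QstResult",
  representation(trait = "character", VB = "numeric", VW = "numeric",
                 VBraw = "numeric", Qst = "numeric", method = "character",
                 p = "numeric", groups = "character", truncated = "logical"))
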