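#' Accessors for SnpGenotypes
#'
#' `callMatrix` returns the calls as a samples x loci integer matrix (the
#' orientation all statistics in this package work in); `sampleInfo` and
#' `lociInfo` return the metadata tables; `populations` the per-sample
#' population factor.
#'
#' @param x a [SnpGenotypes-class] object.
#' @return `callMatrix`: integer matrix; `sampleInfo`/`lociInfo`: data.frame;
#'   `populations`: factor.
#' @name snp-accessors
NULL

#' @rdname snp-accessors
#' @export
setGeneric("callMatrix", function(x) standardGeneric("callMatrix"))

#' @rdname snp-accessors
#' @export
setMethod("callMatrix", "SnpGenotypes", function(x)
  t(SummarizedExperiment::assay(x, "calls")))

#' @rdname snp-accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname snp-accessors
#' @export
setMethod("sampleInfo", "SnpGenotypes", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname snp-accessors
#' @export
setGeneric("lociInfo", function(x) standardGeneric("lociInfo"))

#' @rdname snp-accessors
#' @export
setMethod("lociInfo", "SnpGenotypes", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname snp-accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname snp-accessors
#' @export
setMethod("populations", "SnpGenotypes", function(x)
  factor(SummarizedExperiment::colData(x)$population))

#' @rdname snp-accessors
#' @export
nSamples <- function(x) ncol(x)

#' @rdname snp-accessors
#' @export
nLoci <- function(x) nrow(x)

setMethod("show", "SnpGenotypes", function(object) {
  cd <- SummarizedExperiment::colData(object)
  a <- SummarizedExperiment::assay(object, "calls")
  cat("SnpGenotypes: ", ncol(object), " samples x ", nrow(object),
      " loci\n", sep = "")
  cat("  populations: ", length(unique(cd$population)),
      "; missing calls: ", sprintf("%.1f%%", 100 * mean(is.na(a))),
      "\n", sep = "")
  fr <- S4Vectors::metadata(object)$filterReport
  if (!is.null(fr))
    cat("  filtered: ", paste(names(fr), unlist(fr), sep = "=",
                              collapse = ", "), "\n", sep = "")
})

#' @describeIn collapseHaplotypes number of distinct haplotypes.
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))

#' @export
setMethod("nHaplotypes", "HaplotypeSet", function(x) nrow(x@haplotypes))

#' Per-population haplotype counts
#' @param x a [HaplotypeSet-class].
#' @return integer matrix, populations x haplotypes.
#' @export
haplotypeCounts <- function(x) x@counts

setMethod("show", "HaplotypeSet", function(object) {
  cat("HaplotypeSet: ", nrow(object@haplotypes), " haplotypes among ",
      length(object@assignment), " samples (rule: ", object@rule, ")\n",
      sep = "")
  nh <- apply(object@counts > 0, 1, sum)
  cat("  haplotypes per population: ",
      paste(range(nh), collapse = "-"), "\n", sep = "")
})

setMethod("show", "AmovaResult", function(object) {
  cat("AMOVA (", object@design, ", ", object@nPerm, " permutations)\n",
      sep = "")
  tab <- data.frame(df = object@df, SS = round(object@ss, 3),
                    sigma2 = round(object@components, 4),
                    percent = round(object@percent, 1))
  print(tab)
  idx <- paste0(names(object@indices), "=",
                sprintf("%.4f", object@indices))
  cat("  indices: ", paste(idx, collapse = ", "), "\n", sep = "")
  if (!all(is.na(object@pvalues)))
    cat("  p-values: ", paste(sprintf("%.4g", object@pvalues),
                              collapse = ", "), "\n", sep = "")
})

setMethod("show", "MantelResult", function(object) {
  cat(sprintf(
    "Mantel test (n = %d): r = %.3f (r2 = %.3f), slope = %.4g, p = %.4g (%s, %d permutations)\n",
    object@n, object@r, object@r^2, object@slope, object@p,
    object@alternative, object@nPerm))
})

setMethod("show", "MembershipMatrix", function(object) {
  cat("MembershipMatrix: ", nrow(object@Q), " samples x ", ncol(object@Q),
      " clusters; logLik = ", sprintf("%.2f", object@logLik),
      if (!object@converged) " (not converged)", "\n", sep = "")
})

setMethod("show", "RunEnsemble", function(object) {
  cat("RunEnsemble: K = ", object@K, ", ", length(object@runs),
      " runs, H' = ", sprintf("%.3f", object@Hprime), "\n", sep = "")
})

setMethod("show", "QstResult", function(object) {
  cat(sprintf("Q_ST[%s] = %.3f (V_B = %.4g, V_W = %.4g, %s%s)",
              object@trait, object@Qst, object@VB, object@VW, object@method,
              if (object@truncated) ", V_B truncated at 0" else ""))
  if (!is.na(object@p)) cat(sprintf(", p = %.4g", object@p))
  cat("\n")
})

#' Extract the membership matrix
#' @param x a [MembershipMatrix-class] or [RunEnsemble-class] (consensus).
#' @return numeric matrix of membership proportions.
#' @export
membership <- function(x) {
  if (is(x, "MembershipMatrix")) x@Q
  else if (is(x, "RunEnsemble")) x@consensus
  else stop("no membership matrix in object of class ", class(x))
}

#' @describeIn qst the Q_ST point estimate.
#' @param x a QstResult.
#' @export
qstValue <- function(x) x@Qst
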