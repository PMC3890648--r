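# Small builders used across tests; all fixtures are generated in code.

toyGenotypes <- function(calls, pop = NULL) {
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("s", seq_len(nrow(calls)))
  rownames(calls) <- make.unique(rownames(calls))
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("L", seq_len(ncol(calls)))
  if (is.null(pop)) pop <- rep("p1", nrow(calls))
  SnpGenotypes(calls, samples = data.frame(
    accession = rownames(calls), population = pop))
}

hardQ <- function(n, K, sizes = NULL) {
  lab <- if (is.null(sizes)) rep(seq_len(K), length.out = n)
         else rep(seq_len(K), sizes)
  Q <- matrix(0, length(lab), K)
  Q[cbind(seq_along(lab), lab)] <- 1
  Q
}

# exhaustive-enumeration oracle for rarefied allelic richness: mean number
# of distinct alleles over all size-g subsets of the observed calls
enumRichness <- function(callsVec, g) {
  v <- callsVec[!is.na(callsVec)]
  subs <- combn(length(v), g, simplify = FALSE)
  mean(vapply(subs, function(ix) length(unique(v[ix])), numeric(1)))
}

# exhaustive oracle for private allelic richness of the focal unit against
# one other unit: average over the product space of both units' subsets
enumPrivate <- function(focal, other, g) {
  f <- focal[!is.na(focal)]
  o <- other[!is.na(other)]
  fs <- combn(length(f), g, simplify = FALSE)
  os <- combn(length(o), g, simplify = FALSE)
  tot <- 0
  for (a in fs) for (b in os)
    tot <- tot + length(setdiff(unique(f[a]), unique(o[b])))
  tot / (length(fs) * length(os))
}

# independent AMOVA oracle for complete haploid data: per-locus one-way
# variance components from expected mean squares, summed over loci
aovFstOracle <- function(calls, pop) {
  pop <- factor(pop)
  sa <- sw <- 0
  N <- nrow(calls); P <- nlevels(pop)
  n0 <- (N - sum(table(pop)^2) / N) / (P - 1)
  for (j in seq_len(ncol(calls))) {
    # monomorphic loci trigger perfect-fit warnings; their components are 0
    a <- suppressWarnings(anova(aov(calls[, j] ~ pop)))
    msb <- a$`Mean Sq`[1]; msw <- a$`Mean Sq`[2]
    sa <- sa + (msb - msw) / n0
    sw <- sw + msw
  }
  sa / (sa + sw)
}
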