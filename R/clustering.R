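#' PcaResult: genotype PCA with Tracy-Widom component significance
#'
#' @slot eigenvalues non-increasing eigenvalues of the sample covariance.
#' @slot varianceExplained eigenvalue fractions of the total.
#' @slot scores sample x component matrix of eigenvector coordinates
#'   (columns unit norm).
#' @slot twPvalues Tracy-Widom p-value per component.
#' @slot settings list: `ldCorrect` neighbour count, `nLociUsed`.
#' @export
setClass("PcaResult",
  representation(eigenvalues = "numeric", varianceExplained = "numeric",
                 scores = "matrix", twPvalues = "numeric",
                 settings = "list"))

setMethod("show", "PcaResult", function(object) {
  k <- min(5, length(object@eigenvalues))
  cat("PCA of ", nrow(object@scores), " samples x ",
      object@settings$nLociUsed, " loci (ldCorrect = ",
      object@settings$ldCorrect, ")\n", sep = "")
  cat("  top components: ",
      paste(sprintf("%.1f%%", 100 * object@varianceExplained[1:k]),
            collapse = ", "), "\n", sep = "")
})

## Tracy-Widom (beta = 1) distribution function via the shifted-gamma
## approximation of Chiani (2014); accurate to ~1e-3 over the bulk.
.ptw1 <- function(x) {
  k <- 46.44604884387337
  theta <- 0.18605402228279347
  alpha <- 9.848007781128567
  pgamma(x + alpha, shape = k, scale = theta)
}

#' Principal component analysis of SNP genotypes
#'
#' Each locus is centred by its mean call and scaled by
#' \eqn{\sqrt{\hat p (1 - \hat p)}} (allele-frequency normalization for
#' haploid calls); missing calls are imputed to the locus mean before
#' scaling; monomorphic loci are dropped.  With `ldCorrect` > 0 each locus is
#' replaced by its residual after regression on the 1-2 preceding loci in
#' map order (within chromosomes when a map is present), attenuating local
#' linkage disequilibrium.  Component significance uses Tracy-Widom
#' statistics with the effective-marker-count moment matching of the
#' eigenvalue spectrum.
#'
#' @param g a [SnpGenotypes-class].
#' @param ldCorrect number of preceding neighbour loci to regress out
#'   (0, 1 or 2).
#' @return a [PcaResult-class].
#' @examples
#' sim <- simulateIsland(nPops = 2, samplesPerPop = 10, nLoci = 80,
#'                       F = 0.3, seed = 5)
#' p <- snpPca(sim$genotypes)
#' p@twPvalues[1] < 0.01
#' @export
snpPca <- function(g, ldCorrect = 0L) {
  stopifnot(ldCorrect %in% 0:2)
  calls <- callMatrix(g)
  if (nrow(calls) < 3) stop("PCA needs at least 3 samples")
  li <- lociInfo(g)
  ord <- seq_len(ncol(calls))
  if (all(c("chromosome", "position") %in% names(li)))
    ord <- order(li$chromosome, li$position)
  calls <- calls[, ord, drop = FALSE]
  li <- li[ord, , drop = FALSE]

  p <- colMeans(calls, na.rm = TRUE)
  keep <- p > 0 & p < 1 & !is.nan(p)
  if (!any(keep)) stop("all loci are constant")
  calls <- calls[, keep, drop = FALSE]
  p <- p[keep]
  X <- sweep(calls, 2, p)
  X[is.na(X)] <- 0
  X <- sweep(X, 2, sqrt(p * (1 - p)), "/")

  if (ldCorrect > 0) {
    chr <- if ("chromosome" %in% names(li)) li$chromosome[keep]
           else rep(1L, ncol(X))
    for (j in seq_len(ncol(X))) {
      prev <- j - seq_len(ldCorrect)
      prev <- prev[prev >= 1 & chr[pmax(prev, 1)] == chr[j]]
      if (length(prev))
        X[, j] <- lm.fit(cbind(1, X[, prev, drop = FALSE]), X[, j])$residuals
    }
  }

  n <- nrow(X); L <- ncol(X)
  C <- tcrossprod(X) / L
  e <- eigen(C, symmetric = TRUE)
  m <- min(n - 1, L)
  ev <- pmax(e$values[seq_len(m)], 0)
  scores <- e$vectors[, seq_len(m), drop = FALSE]
  rownames(scores) <- rownames(calls)
  colnames(scores) <- paste0("PC", seq_len(m))

  tw <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    lam <- ev[i:m]
    mp <- length(lam)
    if (mp < 3 || sum(lam) <= 0) break
    S1 <- sum(lam); S2 <- sum(lam^2)
    denom <- (mp - 1) * S2 - S1^2
    if (denom <= 0) break
    neff <- (mp + 1) * S1^2 / denom
    l1 <- mp * lam[1] / S1
    mu <- (sqrt(neff - 1) + sqrt(mp))^2 / neff
    sig <- (sqrt(neff - 1) + sqrt(mp)) / neff *
      (1 / sqrt(neff - 1) + 1 / sqrt(mp))^(1 / 3)
    tw[i] <- 1 - .ptw1((l1 - mu) / sig)
  }
  new("PcaResult", eigenvalues = ev,
      varianceExplained = ev / sum(ev), scores = scores, twPvalues = tw,
      settings = list(ldCorrect = as.integer(ldCorrect), nLociUsed = L))
}

#' Select principal components for clustering
#'
#' Keeps the largest components each explaining at least `minFraction` of
#' the variance, clipped to between 3 and 5 components, and returns their
#' scores weighted by the corresponding eigenvalues.
#'
#' @param p a [PcaResult-class].
#' @param minFraction minimum variance fraction per component (default
#'   0.02).
#' @param kRange allowed number of components, default `c(3, 5)`.
#' @return matrix of eigenvalue-weighted scores (attribute `"k"` holds the
#'   number kept).
#' @export
selectComponents <- function(p, minFraction = 0.02, kRange = c(3L, 5L)) {
  eligible <- sum(p@varianceExplained >= minFraction)
  k <- min(max(eligible, kRange[1]), kRange[2])
  if (eligible < kRange[1])
    warning("only ", eligible, " components reach ", minFraction,
            "; returning the ", kRange[1], " largest")
  w <- p@scores[, seq_len(k), drop = FALSE] %*%
    diag(p@eigenvalues[seq_len(k)], k)
  colnames(w) <- colnames(p@scores)[seq_len(k)]
  attr(w, "k") <- k
  w
}

#' Ward hierarchical clustering of component scores
#'
#' Agglomerative clustering of Euclidean distances with Ward's
#' minimum-variance criterion.  When `k` is not given it is chosen at the
#' largest relative jump in merge heights (the relative height between the
#' merge creating k clusters and the one dissolving them), searched over
#' `2:kMax`.
#'
#' @param scores numeric matrix, samples x dimensions.
#' @param k number of clusters, or NULL to choose by the height criterion.
#' @param kMax largest k considered by the automatic choice.
#' @return list with `cluster` (factor), `k`, `heights`, `relativeJumps`
#'   and the `hclust` tree.
#' @export
wardCluster <- function(scores, k = NULL, kMax = 10L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (!is.null(k) && k > n) stop("k exceeds the number of samples")
  tr <- hclust(dist(scores), method = "ward.D2")
  h <- tr$height
  jumps <- rep(NA_real_, n)
  for (kk in 2:min(kMax, n - 1)) {
    lower <- h[n - kk]
    upper <- h[n - kk + 1]
    jumps[kk] <- if (lower <= .Machine$double.eps) Inf else upper / lower
  }
  if (is.null(k)) {
    k <- if (all(is.na(jumps)) || max(jumps, na.rm = TRUE) <= 1 + 1e-8) 1L
         else which.max(jumps)
  }
  cl <- if (k == 1) factor(rep(1L, n)) else factor(cutree(tr, k = k))
  names(cl) <- rownames(scores)
  list(cluster = cl, k = as.integer(k), heights = h,
       relativeJumps = jumps, tree = tr)
}

#' Fit the haploid admixture model by EM
#'
#' Models each haploid call as drawn from a mixture of K cluster allele
#' frequencies: the observed-data log-likelihood is
#' \deqn{L = \sum_i \sum_l \log \sum_k q_{ik}
#'   \left[p_{kl}^{x_{il}} (1-p_{kl})^{1-x_{il}}\right]}
#' maximized over the membership rows \eqn{q_i} (on the simplex) and the
#' cluster frequencies \eqn{p_{kl}} by EM from a seeded random start.
#' Missing calls are skipped.  The likelihood is monotone by construction
#' and checked at every iteration.
#'
#' This mixture model deliberately replaces MCMC-based ancestry inference:
#' it shares the same likelihood core (independent loci, cluster-specific
#' frequencies) while being deterministic given the seed and fast enough
#' for replicate-run ensembles.
#'
#' Because the maximized likelihood of nested mixtures grows monotonically
#' with K, K comparison uses a model-evidence approximation rather than the
#' raw likelihood: following the standard BIC convention for mixture
#' models, only the component parameters (the K x L cluster frequencies)
#' are counted -- the per-sample memberships are latent variables, not
#' free parameters of the marginal model --
#' \deqn{\mathrm{evidence} = L_{max} - \tfrac12 K L \log n,}
#' a Laplace-style approximation of the log marginal likelihood that MCMC
#' samplers estimate for the same purpose.
#'
#' Each fit runs `nStarts` short EM bursts from independent random starts
#' and refines the best to convergence (the usual em-EM strategy), which
#' makes replicate runs concentrate near the global optimum so that
#' replicate-based K selection compares optima rather than local traps.
#'
#' @param g a [SnpGenotypes-class] or samples x loci 0/1 matrix.
#' @param K number of clusters (>= 1).
#' @param seed integer seed for the random starts.
#' @param tol relative log-likelihood change declaring convergence.
#' @param maxIter iteration cap; non-convergence flags the result rather
#'   than failing.
#' @param nStarts number of short random starts before refining the best
#'   (default 5; 1 disables the multi-start phase).
#' @return a [MembershipMatrix-class].
#' @export
admixtureFit <- function(g, K, seed = 1L, tol = 1e-6, maxIter = 500L,
                         nStarts = 5L) {
  X <- if (is(g, "SnpGenotypes")) callMatrix(g) else as.matrix(g)
  n <- nrow(X); L <- ncol(X)
  if (K > n) stop("K exceeds the number of samples")
  if (K < 1) stop("K must be >= 1")
  obs <- !is.na(X)
  X0 <- X; X0[!obs] <- 0L
  nObs <- rowSums(obs)
  if (any(nObs == 0)) stop("sample(s) with no observed calls")

  old <- .seedSet(seed)
  on.exit(.seedRestore(old))
  randomStart <- function() {
    Q <- matrix(rgamma(n * K, 1), n, K)
    list(Q = Q / rowSums(Q), P = matrix(runif(K * L, 0.1, 0.9), K, L))
  }
  starts <- replicate(max(1L, nStarts), randomStart(), simplify = FALSE)
  # short bursts from independent starts, then refine the best (em-EM)
  if (length(starts) > 1) {
    burst <- lapply(starts, function(s)
      .admixtureEm(s$Q, s$P, X0, obs, nObs, tol = 0, maxIter = 30L))
    starts <- burst[which.max(vapply(burst, `[[`, numeric(1), "ll"))]
  }
  fit <- .admixtureEm(starts[[1]]$Q, starts[[1]]$P, X0, obs, nObs,
                      tol = tol, maxIter = maxIter)
  Q <- fit$Q
  dimnames(Q) <- list(rownames(X), paste0("K", seq_len(K)))
  ev <- fit$ll - 0.5 * K * L * log(n)
  new("MembershipMatrix", Q = Q, P = fit$P, logLik = fit$ll, evidence = ev,
      seed = as.integer(seed), converged = fit$converged,
      iterations = fit$iter)
}

## EM core; monotone likelihood asserted each iteration
.admixtureEm <- function(Q, P, X0, obs, nObs, tol, maxIter) {
  n <- nrow(X0); L <- ncol(X0); K <- ncol(Q)
  llOld <- -Inf; iter <- 0L; converged <- FALSE
  repeat {
    iter <- iter + 1L
    Tk <- vector("list", K)
    D <- matrix(0, n, L)
    for (k in seq_len(K)) {
      Fk <- matrix(P[k, ], n, L, byrow = TRUE)
      Fk <- X0 * Fk + (1 - X0) * (1 - Fk)
      Fk[!obs] <- 1
      Tk[[k]] <- Q[, k] * Fk
      D <- D + Tk[[k]]
    }
    ll <- sum(log(D[obs]))
    if (ll < llOld - 1e-8 * max(1, abs(llOld)))
      stop("EM likelihood decreased: internal error")
    for (k in seq_len(K)) {
      R <- Tk[[k]] / D
      Q[, k] <- rowSums(R * obs) / nObs
      num <- colSums(R * X0)
      den <- colSums(R * obs)
      P[k, ] <- pmin(pmax(num / pmax(den, 1e-12), 1e-6), 1 - 1e-6)
    }
    Q <- pmin(pmax(Q, 0), 1)
    Q <- Q / rowSums(Q)
    if (is.finite(llOld) && abs(ll - llOld) <= tol * abs(llOld)) {
      converged <- TRUE
      break
    }
    if (iter >= maxIter) break
    llOld <- ll
  }
  list(Q = Q, P = P, ll = ll, iter = iter, converged = converged)
}

#' @describeIn admixtureFit the penalized log-likelihood (model-evidence
#'   approximation) of a fit.
#' @param x a [MembershipMatrix-class].
#' @export
modelEvidence <- function(x) x@evidence

#' Replicate admixture runs at one K
#'
#' Runs [admixtureFit()] `replicates` times with seeds
#' `seed + 0 .. seed + replicates - 1`, aligns the runs and computes the
#' consensus matrix and H'.
#'
#' @param g genotypes as in [admixtureFit()].
#' @param K number of clusters.
#' @param replicates replicate runs (20 is the conventional ensemble size).
#' @param seed base seed.
#' @param ... passed to [admixtureFit()].
#' @return a [RunEnsemble-class].
#' @export
runAdmixture <- function(g, K, replicates = 20L, seed = 1L, ...) {
  runs <- lapply(seq_len(replicates) - 1L, function(r)
    admixtureFit(g, K, seed = seed + r, ...))
  alignRuns(runs)
}

## all permutations of 1..k (k <= 8 kept exhaustive)
.permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- .permutations(k - 1)
    for (r in rest) out[[length(out) + 1]] <-
      c(i, setdiff(seq_len(k), i)[r])
  }
  out
}

## best column permutation of Q onto ref minimising sum |Q - ref|;
## exhaustive for K <= 8, greedy (lowest-index column first) otherwise
.bestPermutation <- function(Q, ref) {
  K <- ncol(Q)
  C <- matrix(0, K, K)
  for (a in seq_len(K)) for (b in seq_len(K))
    C[a, b] <- sum(abs(Q[, a] - ref[, b]))
  if (K <= 8) {
    best <- NULL; bestCost <- Inf
    for (pm in .permutations(K)) {
      cost <- sum(C[cbind(seq_len(K), pm)])
      if (cost < bestCost) { bestCost <- cost; best <- pm }
    }
    list(perm = best, cost = bestCost)
  } else {
    perm <- integer(K); used <- logical(K); cost <- 0
    for (a in seq_len(K)) {
      cand <- which(!used)
      b <- cand[which.min(C[a, cand])]
      perm[a] <- b; used[b] <- TRUE; cost <- cost + C[a, b]
    }
    list(perm = perm, cost = cost)
  }
}

#' Align replicate membership matrices and compute H'
#'
#' Cluster labels are arbitrary per run; each run is aligned by the column
#' permutation minimising the total absolute difference (exhaustive search
#' for K <= 8, greedy lowest-index-first matching otherwise).  For each run
#' pair the symmetric similarity after its best pairwise alignment is
#' \deqn{1 - \frac{\sum_i \sum_k |Q_{ik} - Q'_{ik}|}{2n}}
#' and H' is the mean over pairs.  The consensus is the mean of all runs
#' aligned to the highest-likelihood run.
#'
#' @param runs list of [MembershipMatrix-class] objects (or a
#'   [RunEnsemble-class] to re-align).
#' @return a [RunEnsemble-class].
#' @export
alignRuns <- function(runs) {
  if (is(runs, "RunEnsemble")) runs <- runs@runs
  stopifnot(length(runs) >= 1)
  Qs <- lapply(runs, membership)
  dims <- vapply(Qs, dim, integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1)
    stop("all runs must share the same n and K")
  n <- nrow(Qs[[1]]); K <- ncol(Qs[[1]])
  refIdx <- which.max(vapply(runs, function(r) r@logLik, numeric(1)))
  ref <- Qs[[refIdx]]
  aligned <- lapply(Qs, function(Q) {
    pm <- .bestPermutation(Q, ref)$perm
    out <- Q
    out[, pm] <- Q
    colnames(out) <- colnames(ref)
    out
  })
  nr <- length(runs)
  if (nr > 1) {
    sims <- c()
    for (a in seq_len(nr - 1)) for (b in seq(a + 1, nr)) {
      cost <- .bestPermutation(Qs[[a]], Qs[[b]])$cost
      sims <- c(sims, 1 - cost / (2 * n))
    }
    Hp <- mean(sims)
  } else Hp <- 1
  consensus <- Reduce(`+`, aligned) / nr
  new("RunEnsemble", runs = runs, consensus = consensus,
      Hprime = Hp, K = as.integer(K))
}

#' Choose K from replicate run scores
#'
#' For each K >= 2 the replicate scores at K are compared with those at
#' K-1 by a two-sided Wilcoxon test (signed-rank, paired by replicate
#' index, by default; a rank-sum variant via `paired = FALSE`).  The chosen
#' K is the largest value whose step up from K-1 is significant at `alpha`
#' with higher median score, with all smaller steps also significant.
#' The score compared should be each run's model evidence
#' ([modelEvidence()]); with the raw maximized likelihood the criterion
#' cannot plateau, since nested mixtures never lose likelihood.
#' Note the signed-rank null distribution is discrete: at `alpha = 0.005`
#' at least 9 replicates per K are required for significance to be
#' attainable.
#'
#' @param runsLogLik named list: K value (as integer-convertible name) ->
#'   numeric vector of replicate scores; K values must be contiguous
#'   from 1.
#' @param alpha significance level, default 0.005.
#' @param paired use the signed-rank (paired) test.
#' @return chosen K (integer) with attribute `"pvalues"`.
#' @export
selectK <- function(runsLogLik, alpha = 0.005, paired = TRUE) {
  Ks <- sort(as.integer(names(runsLogLik)))
  if (!identical(Ks, seq_len(length(Ks))))
    stop("K values must be contiguous from 1")
  pv <- rep(NA_real_, length(Ks))
  chosen <- 1L
  for (K in Ks[-1]) {
    a <- runsLogLik[[as.character(K)]]
    b <- runsLogLik[[as.character(K - 1)]]
    if (length(a) < 2 || length(b) < 2) stop("need >= 2 replicates per K")
    pv[K] <- tryCatch(
      suppressWarnings(wilcox.test(a, b, paired = paired,
                                   alternative = "two.sided")$p.value),
      error = function(e) 1)
    if (is.na(pv[K])) pv[K] <- 1
    if (pv[K] < alpha && median(a) > median(b)) chosen <- K else break
  }
  if (chosen == 1L && all(is.na(pv[-1]) | pv[-1] >= alpha))
    attr(chosen, "note") <- "no step significant; K = 1"
  attr(chosen, "pvalues") <- pv
  chosen
}

#' Hard cluster assignment from membership proportions
#'
#' @param x a [MembershipMatrix-class], [RunEnsemble-class] or Q matrix.
#' @return factor of majority-membership cluster labels.
#' @export
majorityAssignment <- function(x) {
  Q <- if (is.matrix(x)) x else membership(x)
  f <- factor(max.col(Q, ties.method = "first"))
  names(f) <- rownames(Q)
  f
}

#' Percent agreement between two hard assignments
#'
#' Labels are matched one-to-one by solving the assignment problem on the
#' confusion matrix (exhaustive over label permutations up to 8 labels,
#' greedy beyond); the score is the percentage of samples on the matched
#' diagonal.  Symmetric and invariant to relabelling either side.
#'
#' @param a,b factors/vectors of cluster labels over the same samples (or
#'   objects accepted by [majorityAssignment()]).
#' @return percent in \[0, 100\].
#' @export
agreementPercent <- function(a, b) {
  lab <- function(x) {
    if (is(x, "MembershipMatrix") || is(x, "RunEnsemble") || is.matrix(x))
      x <- majorityAssignment(x)
    if (is.list(x) && !is.null(x$cluster)) x <- x$cluster
    factor(x)
  }
  a <- lab(a); b <- lab(b)
  if (length(a) != length(b)) stop("assignments cover different samples")
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop("assignments cover different samples")
    b <- b[names(a)]
  }
  tab <- table(a, b)
  k <- max(dim(tab))
  C <- matrix(0, k, k)
  C[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  if (k <= 8) {
    best <- 0
    for (pm in .permutations(k))
      best <- max(best, sum(C[cbind(seq_len(k), pm)]))
  } else {
    best <- 0; used <- logical(k)
    for (i in order(-apply(C, 1, max))) {
      cand <- which(!used)
      j <- cand[which.max(C[i, cand])]
      best <- best + C[i, j]; used[j] <- TRUE
    }
  }
  100 * best / length(a)
}

#' Neighbor-joining tree with locus-resampling bootstrap
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) on a genetic distance
#' matrix.  When the underlying calls are supplied, loci are resampled with
#' replacement `nBoot` times, distances and trees recomputed, and bipartition
#' frequencies attached as `node.label` (percent).
#'
#' @param d symmetric distance matrix (no missing entries).
#' @param calls optional samples x loci matrix (or [SnpGenotypes-class])
#'   for bootstrapping; row order must match `d`.
#' @param nBoot bootstrap replicates (0 = none).
#' @param seed integer seed.
#' @param metric distance metric used on resampled loci.
#' @return an [ape::phylo] tree.
#' @export
neighborJoining <- function(d, calls = NULL, nBoot = 0L, seed = 1L,
                            metric = "proportion") {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 taxa")
  if (anyNA(d)) stop("distance matrix contains missing entries")
  tree <- ape::nj(as.dist(d))
  if (nBoot > 0) {
    if (is.null(calls)) stop("bootstrap needs the genotype calls")
    if (is(calls, "SnpGenotypes")) calls <- callMatrix(calls)
    stopifnot(nrow(calls) == nrow(d))
    rownames(calls) <- rownames(d)
    old <- .seedSet(seed)
    on.exit(.seedRestore(old))
    boots <- vector("list", nBoot)
    for (b in seq_len(nBoot)) {
      idx <- sample.int(ncol(calls), replace = TRUE)
      db <- .pairDiff(calls[, idx, drop = FALSE], metric)
      if (anyNA(db)) db[is.na(db)] <- mean(db, na.rm = TRUE)
      boots[[b]] <- ape::nj(as.dist(db))
    }
    cnt <- ape::prop.clades(tree, boots, rooted = FALSE)
    cnt[is.na(cnt)] <- 0
    tree$node.label <- round(100 * cnt / nBoot)
  }
  tree
}
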