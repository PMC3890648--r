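test_that("PCA separates simulated demes and reports a full spectrum", {
  sim <- simulateIsland(nPops = 2, samplesPerPop = 10, nLoci = 80, F = 0.3,
                        seed = 5)
  p <- snpPca(sim$genotypes)
  expect_lt(p@twPvalues[1], 0.01)
  pops <- populations(sim$genotypes)
  s1 <- p@scores[, 1]
  expect_true(max(s1[pops == "pop1"]) < min(s1[pops == "pop2"]) ||
              min(s1[pops == "pop1"]) > max(s1[pops == "pop2"]))
  # complete data, no LD correction: fractions sum to 1
  expect_equal(sum(p@varianceExplained), 1, tolerance = 1e-9)
  expect_true(all(diff(p@eigenvalues) <= 1e-9))
})

test_that("duplicating every sample leaves the leading PCA axis intact", {
  sim <- simulateIsland(nPops = 2, samplesPerPop = 6, nLoci = 50, F = 0.4,
                        seed = 6)
  g <- sim$genotypes
  calls <- callMatrix(g)
  gd <- toyGenotypes(rbind(calls, calls),
                     pop = rep(as.character(populations(g)), 2))
  p1 <- snpPca(g); p2 <- snpPca(gd)
  n <- nrow(calls)
  # scores repeat across the duplicate block (up to sign and scale)
  a <- p2@scores[seq_len(n), 1]; b <- p2@scores[n + seq_len(n), 1]
  expect_equal(unname(a), unname(b), tolerance = 1e-6)
  expect_gt(abs(cor(p1@scores[, 1], a)), 0.999)
})

test_that("LD correction leaves a valid spectrum and score matrix", {
  sim <- simulateIsland(nPops = 2, samplesPerPop = 8, nLoci = 40, F = 0.3,
                        seed = 7)
  p <- snpPca(sim$genotypes, ldCorrect = 2)
  expect_equal(p@settings$ldCorrect, 2L)
  expect_true(all(is.finite(p@scores)))
  expect_true(all(diff(p@eigenvalues) <= 1e-9))
  expect_lte(sum(p@varianceExplained), 1 + 1e-9)
  expect_equal(nrow(p@scores), 16)
  expect_error(snpPca(toyGenotypes(matrix(1L, 4, 5))), "constant")
})

test_that("component selection respects the variance floor and 3-5 clip", {
  mk <- function(fracs) {
    n <- 20
    new("PcaResult", eigenvalues = fracs,
        varianceExplained = fracs,
        scores = matrix(rnorm(n * length(fracs)), n),
        twPvalues = rep(NA_real_, length(fracs)),
        settings = list(ldCorrect = 0L, nLociUsed = 100L))
  }
  expect_equal(attr(selectComponents(mk(c(0.10, 0.05, 0.03, 0.01,
                                          rep(0.005, 10)))), "k"), 3)
  expect_equal(attr(selectComponents(mk(c(rep(0.05, 7),
                                          rep(0.005, 10)))), "k"), 5)
  expect_warning(w <- selectComponents(mk(c(0.9, rep(0.004, 20)))),
                 "3 largest")
  expect_equal(attr(w, "k"), 3)
})

test_that("Ward clustering finds two tight blobs and k by relative height jump", {
  set.seed(9)
  scores <- rbind(matrix(rnorm(40, 0, 0.1), 20),
                  matrix(rnorm(40, 5, 0.1), 20))
  w <- wardCluster(scores)
  expect_equal(w$k, 2L)
  expect_equal(length(unique(w$cluster[1:20])), 1)
  w1 <- wardCluster(scores, k = 1)
  expect_equal(nlevels(w1$cluster), 1)
  expect_error(wardCluster(scores, k = 100), "exceeds")
})

test_that("EM admixture likelihood is monotone and exact at K = 1", {
  sim <- simulateIsland(nPops = 2, samplesPerPop = 6, nLoci = 30, F = 0.3,
                        missingRate = 0.1, seed = 15)
  X <- callMatrix(sim$genotypes)
  fit1 <- admixtureFit(X, K = 1, seed = 1)
  # closed form: independent-locus frequency log-likelihood
  ll <- 0
  for (j in seq_len(ncol(X))) {
    v <- X[!is.na(X[, j]), j]
    ph <- mean(v)
    ph <- min(max(ph, 1e-6), 1 - 1e-6)
    ll <- ll + sum(v * log(ph) + (1 - v) * log(1 - ph))
  }
  expect_equal(fit1@logLik, ll, tolerance = 1e-6)
  expect_true(all(membership(fit1) == 1))
  expect_error(admixtureFit(X, K = nrow(X) + 1), "exceeds")
})

test_that("admixture fit recovers a simulated Q within 0.1 MAE", {
  Q <- rbind(hardQ(20, 2), matrix(0.5, 6, 2))
  sim <- simulateAdmixture(Q = Q, nLoci = 150, seed = 33)
  fit <- admixtureFit(sim$genotypes, K = 2, seed = 44)
  Qh <- membership(fit)
  mae <- min(mean(abs(Qh - Q)), mean(abs(Qh[, 2:1] - Q)))
  expect_lt(mae, 0.1)
  # likelihood at the generating (Q, P) is no better than the EM optimum
  X <- callMatrix(sim$genotypes)
  obs <- !is.na(X); X0 <- X; X0[!obs] <- 0L
  llTruth <- haplopop:::.admixtureEm(Q, sim$truth$P, X0, obs,
                                     rowSums(obs), tol = 1,
                                     maxIter = 1)$ll
  expect_gte(fit@logLik, llTruth - 1e-6)
})

test_that("run alignment recovers permuted labels and the H' endpoints", {
  sim <- simulateAdmixture(Q = hardQ(18, 3), nLoci = 60, seed = 55)
  f1 <- admixtureFit(sim$genotypes, K = 3, seed = 2)
  # identical runs: H' = 1
  expect_equal(alignRuns(list(f1, f1))@Hprime, 1)
  # column-permuted duplicate: alignment must recover H' = 1
  f2 <- f1
  f2@Q <- f1@Q[, c(3, 1, 2)]
  f2@P <- f1@P[c(3, 1, 2), ]
  ens <- alignRuns(list(f1, f2))
  expect_equal(ens@Hprime, 1)
  expect_equal(ens@consensus, unname(membership(f1)),
               ignore_attr = TRUE)
})

test_that("H' equals 1/2 for half-swapped hard assignments", {
  n <- 20
  Q1 <- hardQ(n, 2, c(10, 10))
  Q2 <- Q1
  Q2[1:5, ] <- Q1[1:5, 2:1]   # swap half of cluster 1
  Q2[11:15, ] <- Q1[11:15, 2:1]
  mk <- function(Q, ll) new("MembershipMatrix", Q = Q,
                            P = matrix(0.5, 2, 2), logLik = ll,
                            evidence = ll, seed = 1L, converged = TRUE,
                            iterations = 1L)
  ens <- alignRuns(list(mk(Q1, -1), mk(Q2, -2)))
  expect_equal(ens@Hprime, 0.5)
})

test_that("K selection walks Wilcoxon steps on replicate evidence", {
  set.seed(1)
  # synthetic evidence: clear gains up to K = 3, noise beyond
  runs <- list(`1` = rnorm(10, -5000, 1), `2` = rnorm(10, -4000, 1),
               `3` = rnorm(10, -3500, 1), `4` = rnorm(10, -3501, 1))
  expect_equal(as.integer(selectK(runs)), 3L)
  flat <- list(`1` = rnorm(10, -5000, 1), `2` = rnorm(10, -5000, 1))
  expect_equal(as.integer(selectK(flat)), 1L)
  expect_error(selectK(list(`2` = 1:5, `3` = 1:5)), "contiguous")
})

test_that("select_k finds K = 1 for panmictic data", {
  sim <- simulateAdmixture(Q = matrix(1, 40, 1), nLoci = 80, seed = 77)
  runs <- lapply(1:3, function(K)
    vapply(0:9, function(r)
      modelEvidence(admixtureFit(sim$genotypes, K, seed = 100 * K + r)),
      numeric(1)))
  names(runs) <- 1:3
  expect_equal(as.integer(selectK(runs)), 1L)
})

test_that("agreement is symmetric, relabel-invariant and exact on identity", {
  a <- factor(rep(1:3, each = 5))
  expect_equal(agreementPercent(a, a), 100)
  b <- factor(rep(c("x", "y", "z"), each = 5))  # pure relabelling
  expect_equal(agreementPercent(a, b), 100)
  bswap <- b
  bswap[1:2] <- c("y", "z")
  expect_equal(agreementPercent(a, bswap), agreementPercent(bswap, a))
  expect_equal(agreementPercent(a, bswap), 100 * 13 / 15)
  expect_error(agreementPercent(a, factor(rep(1, 4))), "different samples")
})

test_that("NJ solves the three-point case and recovers additive trees", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighborJoining(d)
  # closed form: x = (dab + dac - dbc)/2 etc.
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(2, 3, 7))

  ref <- ape::rtree(5, br = function(n) runif(n, 0.5, 2))
  ref <- ape::unroot(ref)
  dAdd <- cophenetic(ref)
  rec <- neighborJoining(dAdd)
  expect_equal(ape::dist.topo(ape::unroot(rec), ref), 0,
               ignore_attr = TRUE)
  expect_equal(cophenetic(rec)[rownames(dAdd), colnames(dAdd)], dAdd,
               tolerance = 1e-10)
})

test_that("NJ bootstrap supports strong simulated splits", {
  sim <- simulateIsland(nPops = 2, samplesPerPop = 3, nLoci = 100, F = 0.6,
                        seed = 66)
  g <- sim$genotypes
  d <- geneticDistances(g)
  tr <- neighborJoining(d, calls = g, nBoot = 50, seed = 3)
  expect_true(!is.null(tr$node.label))
  expect_true(any(tr$node.label >= 80))
})
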