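#' Impute right-censored flowering records
#'
#' Plants still unflowered when the experiment ends would otherwise be
#' dropped, biasing flowering onset downward.  Such plants receive
#' `FT = ftLimit` days and a leaf number predicted at `ftLimit` from the
#' least-squares regression of LN on FT fitted to the flowered plants.
#' With the conventional 200-day limit and a typical LN~FT relationship the
#' imputed pair is 200 days / 150 leaves.
#'
#' @param traits data.frame with columns `accession`, `plant`, `FT`
#'   (days), `LN` (leaves), `flowered` (logical), `vernalized` (logical).
#' @param ftLimit censoring limit in days (default 200).
#' @return list: `traits` (imputed table), `fit` (regression coefficients),
#'   `nImputed`.
#' @export
imputeCensored <- function(traits, ftLimit = 200) {
  stopifnot(all(c("FT", "LN", "flowered") %in% names(traits)))
  fl <- traits[traits$flowered & !is.na(traits$FT) & !is.na(traits$LN), ]
  if (nrow(fl) < 2) stop("need at least 2 flowered plants for the regression")
  fit <- lm(LN ~ FT, data = fl)
  lnAtLimit <- unname(predict(fit, data.frame(FT = ftLimit)))
  cens <- which(!traits$flowered)
  out <- traits
  if (length(cens)) {
    out$FT[cens] <- pmax(ftLimit, out$FT[cens], na.rm = TRUE)
    out$LN[cens] <- pmax(lnAtLimit, out$LN[cens], na.rm = TRUE)
  }
  list(traits = out, fit = coef(fit), nImputed = length(cens),
       lnAtLimit = lnAtLimit)
}

#' Obligate vernalization requirement per accession
#'
#' An accession is scored as obligately requiring vernalization when none
#' of its unvernalized plants flowered (and, where vernalized records
#' exist, at least one vernalized plant flowered).  The percent of
#' non-flowering unvernalized plants is also reported.  When a `region`
#' mapping is given, regional obligate proportions are compared by Fisher's
#' exact test.
#'
#' @param traits trait table as in [imputeCensored()].
#' @param region optional named vector accession -> region label.
#' @return list: `summary` (per-accession data.frame), and with regions
#'   `test` (fisher.test) plus `regionTable`.
#' @export
vernalizationRequirement <- function(traits, region = NULL) {
  unv <- traits[!traits$vernalized, ]
  if (nrow(unv) == 0) stop("no unvernalized records")
  acc <- unique(as.character(traits$accession))
  rows <- lapply(acc, function(a) {
    u <- unv[unv$accession == a, ]
    if (nrow(u) == 0) return(NULL)   # skipped, no unvernalized plants
    v <- traits[traits$vernalized & traits$accession == a, ]
    obligate <- !any(u$flowered) &&
      (nrow(v) == 0 || any(v$flowered))
    data.frame(accession = a,
               nPlants = nrow(u),
               pctNonFlowering = 100 * mean(!u$flowered),
               meanFT = mean(u$FT[u$flowered], na.rm = TRUE),
               meanLN = mean(u$LN[u$flowered], na.rm = TRUE),
               obligate = obligate)
  })
  dropped <- acc[vapply(rows, is.null, logical(1))]
  if (length(dropped))
    message("accession(s) without unvernalized plants skipped: ",
            paste(dropped, collapse = ", "))
  summ <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- list(summary = summ)
  if (!is.null(region)) {
    reg <- factor(region[as.character(summ$accession)])
    tab <- table(reg, factor(summ$obligate, levels = c(FALSE, TRUE)))
    out$regionTable <- tab
    out$test <- fisher.test(tab)
  }
  out
}

#' Quantitative-trait differentiation Q_ST
#'
#' One-way random-effects decomposition of a trait into between-group
#' (\eqn{V_B}) and within-group (\eqn{V_W}) variance components, with
#' \deqn{Q_{ST} = V_B / (V_B + V_W).}
#' `method = "reml"` fits the random-intercept model by restricted maximum
#' likelihood; `method = "anova"` uses expected mean squares with the
#' unbalanced-design coefficient
#' \eqn{n_0 = (N - \sum n_g^2/N)/(G-1)}.  The two agree on balanced
#' designs.  A negative moment estimate of \eqn{V_B} is truncated at zero
#' (raw value retained).  This is the haploid-style ratio without a factor
#' of 2 on \eqn{V_W}, appropriate when the replicates are selfing lines.
#'
#' @param values numeric trait values (typically accession means).
#' @param grouping factor of group labels.
#' @param method `"reml"` (default) or `"anova"`.
#' @param nPerm optional label permutations for a p-value on Q_ST.
#' @param seed seed for permutations.
#' @param trait label carried into the result.
#' @return a [QstResult-class].
#' @examples
#' sim <- simulateTraits(nGroups = 6, perGroup = 8, VB = 1, VW = 1,
#'                       seed = 1)
#' qst(sim$traitMeans, sim$grouping)
#' @export
qst <- function(values, grouping, method = c("reml", "anova"),
                nPerm = 0L, seed = 1L, trait = "trait") {
  method <- match.arg(method)
  grouping <- factor(grouping)
  ok <- !is.na(values) & !is.na(grouping)
  values <- values[ok]; grouping <- droplevels(grouping[ok])
  sizes <- table(grouping)
  if (any(sizes < 2)) {
    warning("dropping group(s) with a single member: ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
    keep <- grouping %in% names(sizes)[sizes >= 2]
    values <- values[keep]; grouping <- droplevels(grouping[keep])
  }
  if (nlevels(grouping) < 2) stop("need at least 2 usable groups")

  est <- function(v, g) {
    if (method == "anova") {
      a <- anova(aov(v ~ g))
      msb <- a$`Mean Sq`[1]; msw <- a$`Mean Sq`[2]
      N <- length(v); ng <- table(g); G <- nlevels(g)
      n0 <- (N - sum(ng^2) / N) / (G - 1)
      c(VB = (msb - msw) / n0, VW = msw)
    } else {
      fit <- suppressMessages(
        lme4::lmer(v ~ 1 + (1 | g), REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular =
                     lme4::.makeCC(action = "ignore", tol = 1e-4))))
      vc <- as.data.frame(lme4::VarCorr(fit))
      c(VB = vc$vcov[vc$grp == "g"], VW = vc$vcov[vc$grp == "Residual"])
    }
  }
  e <- est(values, grouping)
  vbRaw <- unname(e["VB"]); vw <- unname(e["VW"])
  vb <- max(vbRaw, 0)
  q <- vb / (vb + vw)
  p <- NA_real_
  if (nPerm > 0) {
    old <- .seedSet(seed)
    on.exit(.seedRestore(old))
    hits <- 0L
    for (b in seq_len(nPerm)) {
      e2 <- est(values, grouping[sample.int(length(grouping))])
      q2 <- max(e2["VB"], 0) / (max(e2["VB"], 0) + e2["VW"])
      hits <- hits + (q2 >= q)
    }
    p <- (hits + 1) / (nPerm + 1)
  }
  new("QstResult", trait = trait, VB = vb, VW = vw, VBraw = vbRaw,
      Qst = q, method = method, p = p, groups = levels(grouping),
      truncated = vbRaw < 0)
}

#' Tukey HSD group comparison with compact letter display
#'
#' One-way ANOVA followed by Tukey's honest significant differences;
#' groups sharing a letter do not differ at `alpha`.
#'
#' @param values numeric trait values.
#' @param grouping factor of group labels.
#' @param alpha significance level, default 0.05.
#' @return list: `letters` (named character), `tukey` (the TukeyHSD
#'   table), `anova` p-value.
#' @export
groupTukey <- function(values, grouping, alpha = 0.05) {
  grouping <- factor(grouping)
  if (nlevels(grouping) < 2) stop("need at least 2 groups")
  if (any(table(grouping) < 2)) stop("every group needs >= 2 values")
  fit <- aov(values ~ grouping)
  tk <- TukeyHSD(fit)$grouping
  lev <- levels(grouping)
  sig <- matrix(FALSE, length(lev), length(lev),
                dimnames = list(lev, lev))
  for (rn in rownames(tk)) {
    pr <- strsplit(rn, "-", fixed = TRUE)[[1]]
    s <- tk[rn, "p adj"] < alpha
    sig[pr[1], pr[2]] <- sig[pr[2], pr[1]] <- s
  }
  list(letters = .letterDisplay(sig), tukey = tk,
       anovaP = anova(fit)$`Pr(>F)`[1])
}

#' Compare trait ranges between two sets
#'
#' Reports each set's min/max and tests the difference in range
#' (max - min) by permuting set labels.
#'
#' @param a,b numeric trait values.
#' @param nPerm permutations, default 999.
#' @param seed integer seed.
#' @return list: `rangeA`, `rangeB`, `diff` (rangeA - rangeB width
#'   difference), `p` (two-sided).
#' @export
traitRangeCompare <- function(a, b, nPerm = 999L, seed = 1L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both sets must be non-empty")
  width <- function(x) diff(range(x))
  obs <- width(a) - width(b)
  pool <- c(a, b); na <- length(a)
  old <- .seedSet(seed)
  on.exit(.seedRestore(old))
  hits <- 0L
  for (k in seq_len(nPerm)) {
    idx <- sample.int(length(pool), na)
    d <- width(pool[idx]) - width(pool[-idx])
    hits <- hits + (abs(d) >= abs(obs))
  }
  list(rangeA = range(a), rangeB = range(b), diff = obs,
       p = (hits + 1) / (nPerm + 1))
}
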