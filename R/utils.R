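## Seed handling: every stochastic entry point sets the RNG from its `seed`
## argument and restores the caller's RNG state on exit, so results are
## reproducible without perturbing the user's session stream.

.seedSet <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  old
}

.seedRestore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

## compact letter display from a symmetric logical "significantly different"
## matrix (insert-and-absorb)
.letterDisplay <- function(sig) {
  k <- nrow(sig)
  groups <- list(seq_len(k))  # start with one letter containing everything
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (!sig[i, j]) next
    for (gi in seq_along(groups)) {
      if (all(c(i, j) %in% groups[[gi]])) {
        a <- setdiff(groups[[gi]], i)
        b <- setdiff(groups[[gi]], j)
        groups[[gi]] <- a
        groups <- c(groups, list(b))
      }
    }
    ## absorb duplicates / subsets
    keep <- rep(TRUE, length(groups))
    for (x in seq_along(groups)) for (y in seq_along(groups)) {
      if (x != y && keep[x] && keep[y] &&
          all(groups[[x]] %in% groups[[y]]))
        keep[x] <- FALSE
    }
    groups <- groups[keep]
  }
  letters_ <- letters[seq_along(groups)]
  out <- vapply(seq_len(k), function(i)
    paste(letters_[vapply(groups, function(gp) i %in% gp, logical(1))],
          collapse = ""), character(1))
  rownames(sig) -> nm
  if (!is.null(nm)) names(out) <- nm
  out
}
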