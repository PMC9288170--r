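# Independent brute-force oracles, deliberately written without reusing
# any package internals.

VALID_BASES <- c("A", "C", "G", "T")

# random toy alignment as a character matrix, with missing characters
randomToy <- function(nSeq, nSite, pMissing = 0.1) {
  pool <- c(VALID_BASES, "N", "-")
  probs <- c(rep((1 - pMissing) / 4, 4), pMissing / 2, pMissing / 2)
  matrix(sample(pool, nSeq * nSite, replace = TRUE, prob = probs),
         nrow = nSeq)
}

# pi by exhaustive pair enumeration, pairwise deletion per site
brutePi <- function(m) {
  n <- nrow(m)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- 0; comp <- 0
    for (s in seq_len(ncol(m))) {
      a <- m[i, s]; b <- m[j, s]
      if (a %in% VALID_BASES && b %in% VALID_BASES) {
        comp <- comp + 1
        if (a != b) d <- d + 1
      }
    }
    if (comp > 0) vals <- c(vals, d / comp)
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

bruteBetween <- function(me, mw) {
  vals <- c()
  for (i in seq_len(nrow(me))) for (j in seq_len(nrow(mw))) {
    d <- 0; comp <- 0
    for (s in seq_len(ncol(me))) {
      a <- me[i, s]; b <- mw[j, s]
      if (a %in% VALID_BASES && b %in% VALID_BASES) {
        comp <- comp + 1
        if (a != b) d <- d + 1
      }
    }
    if (comp > 0) vals <- c(vals, d / comp)
  }
  mean(vals)
}

bruteWatterson <- function(m) {
  n <- nrow(m)
  s <- 0; lEff <- 0
  for (j in seq_len(ncol(m))) {
    b <- m[, j]
    b <- b[b %in% VALID_BASES]
    if (length(b) >= 2) {
      lEff <- lEff + 1
      if (length(unique(b)) >= 2) s <- s + 1
    }
  }
  an <- sum(1 / seq_len(n - 1))
  c(theta_w = if (s == 0) 0 else s / (lEff * an), s = s)
}

# independent draw from the divergence-pulse hyperprior (for prior-tail
# cross-checks); returns omega values
bruteOmegaPrior <- function(nDraws, nTaxa, tauMax) {
  vapply(seq_len(nDraws), function(i) {
    psi <- sample.int(nTaxa, 1)
    repeat {
      a <- sample.int(psi, nTaxa, replace = TRUE)
      if (length(unique(a)) == psi) break
    }
    tau <- runif(psi, 0, tauMax)[a]
    m <- mean(tau)
    mean((tau - m)^2) / m
  }, numeric(1))
}

# ---- tree-screening oracles (ape::is.monophyletic as the clade check) --

oracleClassify <- function(tree, sides) {
  s <- sides[tree$tip.label]
  eC <- ape::is.monophyletic(tree, tree$tip.label[s == "E"])
  wC <- ape::is.monophyletic(tree, tree$tip.label[s == "W"])
  if (eC && wC) "reciprocal_monophyly"
  else if (eC || wC) "paraphyly" else "polyphyly"
}

oracleRM <- function(tree, keep, sides) {
  sk <- sides[keep]
  if (!all(c("E", "W") %in% sk)) return(FALSE)
  if (length(keep) == 2) return(TRUE)
  sub <- ape::keep.tip(tree, keep)
  identical(oracleClassify(sub, sides), "reciprocal_monophyly")
}

# exhaustive search over every (internal node, removal set) pair, with
# the documented tie-break (max retained, min removals, min priority sum
# over retained tips, node order, set order)
oracleSelect <- function(tree, sides, priority = NULL, maxRemovals = 2) {
  nt <- length(tree$tip.label)
  prio <- setNames(rep(0, nt), tree$tip.label)
  if (!is.null(priority)) prio[names(priority)] <- priority
  best <- NULL
  for (v in (nt + 1):(nt + tree$Nnode)) {
    sub <- ape::extract.clade(tree, v)
    tips <- sub$tip.label
    if (!all(c("E", "W") %in% sides[tips])) next
    for (r in 0:min(maxRemovals, length(tips) - 2)) {
      sets <- if (r == 0) list(character(0)) else
        apply(combn(tips, r), 2, identity, simplify = FALSE)
      for (k in seq_along(sets)) {
        keep <- setdiff(tips, sets[[k]])
        if (!oracleRM(tree, keep, sides)) next
        sc <- c(-length(keep), r, sum(prio[keep]), v, k)
        better <- is.null(best)
        if (!better) {
          for (z in seq_along(sc)) {
            if (sc[z] < best$score[z]) { better <- TRUE; break }
            if (sc[z] > best$score[z]) break
          }
        }
        if (better) best <- list(tips = keep, removed = sets[[k]],
                                 node = v, score = sc)
      }
    }
  }
  best
}

# random E/W labelled rooted binary tree with both sides present
randomLabelledTree <- function(nTips) {
  tr <- ape::rtree(nTips, rooted = TRUE, br = NULL)
  tr$tip.label <- sprintf("t%02d", seq_len(nTips))
  repeat {
    s <- sample(c("E", "W"), nTips, replace = TRUE)
    if (all(c("E", "W") %in% s)) break
  }
  list(tree = tr, sides = setNames(s, tr$tip.label))
}
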