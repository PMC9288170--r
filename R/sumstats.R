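# Population-genetic summary statistics, computed identically for
# observed and simulated alignments.  Missing data (N, gaps, ambiguity
# codes) are handled by pairwise deletion per site.

.VALID <- c("A", "C", "G", "T")

# coerce sequences to an uppercase character matrix (rows = sequences)
.seqMatrix <- function(x) {
  if (length(x) == 0L) stop("insufficient data: no sequences")
  if (is(x, "DNAStringSet") || is(x, "XStringSet")) {
    m <- as.matrix(x)
  } else if (is.matrix(x) && is.character(x)) {
    m <- x
  } else if (is.character(x)) {
    if (length(unique(nchar(x))) > 1L)
      stop("sequences must have equal aligned length")
    m <- do.call(rbind, strsplit(x, ""))
  } else {
    stop("cannot interpret sequences of class ", class(x)[1])
  }
  toupper(m)
}

# per-pair (differences, comparable sites) with pairwise deletion
.pairDiff <- function(m, i, j) {
  ok <- m[i, ] %in% .VALID & m[j, ] %in% .VALID
  c(diff = sum(m[i, ok] != m[j, ok]), comp = sum(ok))
}

#' Within-population nucleotide diversity (pi)
#'
#' Mean over all sequence pairs of per-site differences, counting only
#' sites where both members of the pair have an unambiguous base
#' (pairwise deletion); pairs with no comparable site are excluded.
#'
#' @param seqs >= 2 aligned sequences (DNAStringSet, character vector, or
#'   character matrix with one row per sequence).
#' @return per-site diversity (scalar).
#' @examples
#' withinDiversity(c("AAAA", "AAAT"))  # 0.25
#' @export
withinDiversity <- function(seqs) {
  m <- .seqMatrix(seqs)
  n <- nrow(m)
  if (n < 2L) stop("insufficient data: need >= 2 sequences")
  valid <- matrix(m %in% .VALID, nrow = n)
  num <- 0; cnt <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- valid[i, ] & valid[j, ]
    nc <- sum(ok)
    if (nc == 0L) next
    num <- num + sum(m[i, ok] != m[j, ok]) / nc
    cnt <- cnt + 1L
  }
  if (cnt == 0L) {
    warning("no sequence pair shares a comparable site")
    return(NA_real_)
  }
  num / cnt
}

#' Between-population divergence and net divergence
#'
#' \code{pi_b} is the mean per-site difference over all cross-side pairs;
#' \code{pi_net = pi_b - (pi_w_east + pi_w_west)/2} (Nei's net
#' divergence).  When a side has a single sequence its within term cannot
#' be estimated and is set to 0 with a warning.
#'
#' @param east,west aligned sequence sets, >= 1 each (same aligned length).
#' @return named vector \code{c(pi_b, pi_net)}.
#' @examples
#' betweenAndNet(c("AAAA", "AAAA"), c("TTAA", "TTAA"))  # pi_b 0.5, net 0.5
#' @export
betweenAndNet <- function(east, west) {
  me <- .seqMatrix(east); mw <- .seqMatrix(west)
  if (nrow(me) < 1L || nrow(mw) < 1L)
    stop("insufficient data: both sides need >= 1 sequence")
  if (ncol(me) != ncol(mw)) stop("east and west aligned lengths differ")
  num <- 0; cnt <- 0L
  for (i in seq_len(nrow(me))) for (j in seq_len(nrow(mw))) {
    ok <- me[i, ] %in% .VALID & mw[j, ] %in% .VALID
    nc <- sum(ok)
    if (nc == 0L) next
    num <- num + sum(me[i, ok] != mw[j, ok]) / nc
    cnt <- cnt + 1L
  }
  if (cnt == 0L) stop("no comparable cross-side pair")
  pib <- num / cnt
  wfun <- function(m, lab) {
    if (nrow(m) >= 2L) return(withinDiversity(m))
    warning("single sequence on the ", lab,
            " side; its within-diversity term set to 0")
    0
  }
  c(pi_b = pib, pi_net = pib - (wfun(me, "east") + wfun(mw, "west")) / 2)
}

#' Watterson's theta and segregating sites
#'
#' \code{s} counts alignment columns with at least two distinct
#' unambiguous bases; \code{theta_w = s / (L_eff * a_n)} per site, where
#' \code{L_eff} is the number of columns with at least two unambiguous
#' bases and \code{a_n = sum(1/i, i = 1..n-1)}.
#'
#' @param pooled >= 2 aligned sequences (both sides pooled).
#' @return named vector \code{c(theta_w, s)}.
#' @examples
#' wattersonTheta(c("AAAA", "AATT", "ATTT"))
#' @export
wattersonTheta <- function(pooled) {
  m <- .seqMatrix(pooled)
  n <- nrow(m)
  if (n < 2L) stop("insufficient data: need >= 2 sequences")
  nValid <- colSums(matrix(m %in% .VALID, nrow = n))
  poly <- vapply(seq_len(ncol(m)), function(j) {
    b <- m[, j]; length(unique(b[b %in% .VALID])) >= 2L
  }, logical(1))
  s <- sum(poly & nValid >= 2L)
  lEff <- sum(nValid >= 2L)
  an <- sum(1 / seq_len(n - 1L))
  thetaW <- if (s == 0L) 0 else s / (lEff * an)
  c(theta_w = thetaW, s = as.numeric(s))
}

#' Summary statistics for one taxon pair
#'
#' @param x a \linkS4class{TaxonPairAlignment} with >= 2 sequences per
#'   side.
#' @return one-row data.frame: taxon, n_west, n_east, L, pi_w1 (west),
#'   pi_w2 (east), pi_b, pi_net, theta_w, s.
#' @export
taxonSummary <- function(x) {
  stopifnot(is(x, "TaxonPairAlignment"))
  if (length(x@east) < 2L || length(x@west) < 2L)
    stop("taxon '", x@taxon, "': need >= 2 sequences per side")
  bn <- betweenAndNet(x@east, x@west)
  wt <- wattersonTheta(c(x@west, x@east))
  data.frame(taxon = x@taxon, n_west = length(x@west),
             n_east = length(x@east), L = alignedLength(x),
             pi_w1 = withinDiversity(x@west),
             pi_w2 = withinDiversity(x@east),
             pi_b = unname(bn["pi_b"]), pi_net = unname(bn["pi_net"]),
             theta_w = unname(wt["theta_w"]), s = unname(wt["s"]))
}

.STAT_NAMES <- c("mean_pib", "var_pib", "mean_piw", "var_piw",
                 "mean_pinet", "var_pinet", "mean_thw", "var_thw")

.popVar <- function(x) mean((x - mean(x))^2)

# the 8-number ABC statistic vector: cross-taxon mean and population
# variance of (pi_b, pi_w1 + pi_w2, pi_net, theta_w)
.aggregateStats <- function(perTaxon) {
  piw <- perTaxon$pi_w1 + perTaxon$pi_w2
  v <- c(mean(perTaxon$pi_b), .popVar(perTaxon$pi_b),
         mean(piw), .popVar(piw),
         mean(perTaxon$pi_net), .popVar(perTaxon$pi_net),
         mean(perTaxon$theta_w), .popVar(perTaxon$theta_w))
  names(v) <- .STAT_NAMES
  v
}

#' Summarise a multi-taxon dataset
#'
#' Computes one summary vector per taxon plus the cross-taxon aggregate
#' that feeds the ABC distance: the mean and population variance of
#' \code{pi_b}, \code{pi_w1 + pi_w2}, \code{pi_net} and \code{theta_w}
#' (8 numbers).  The aggregate is invariant to taxon order.
#'
#' @param data list of \linkS4class{TaxonPairAlignment}.
#' @return list with \code{perTaxon} (data.frame, input order),
#'   \code{aggregate} (named numeric of length 8) and \code{nTaxa}.
#' @export
summarizeDataset <- function(data) {
  if (is(data, "TaxonPairAlignment")) data <- list(data)
  perTaxon <- do.call(rbind, lapply(data, taxonSummary))
  list(perTaxon = perTaxon, aggregate = .aggregateStats(perTaxon),
       nTaxa = length(data))
}
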