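# Two-population isolation coalescent: hyperprior draws, genealogies,
# finite-sites mutation.  The heavy lifting is in src/coalsim.cpp; these
# wrappers define the user-facing model surface.

#' Simulated genealogy of a taxon pair
#'
#' Rooted binary genealogy over \code{n1 + n2} tips in coalescent time
#' units.  Tips \code{1..n1} are the western samples, \code{n1+1..n1+n2}
#' the eastern; internal nodes are numbered in coalescence order so a
#' parent's index always exceeds its children's.
#'
#' @slot parent parent index per node (NA for the root).
#' @slot nodeTime node times (0 at the tips).
#' @slot n1,n2 per-side sample counts.
#' @export
setClass("Genealogy",
  representation(parent = "integer", nodeTime = "numeric",
                 n1 = "integer", n2 = "integer"))

setValidity("Genealogy", function(object) {
  n <- object@n1 + object@n2
  if (length(object@parent) != 2L * n - 1L)
    return("a binary genealogy over n tips has 2n-1 nodes")
  if (sum(is.na(object@parent)) != 1L) return("exactly one root expected")
  if (any(diff(object@nodeTime[(n + 1L):(2L * n - 1L)]) < 0) && n > 2L)
    return("internal node times must be non-decreasing")
  TRUE
})

setMethod("show", "Genealogy", function(object) {
  n <- object@n1 + object@n2
  cat("Genealogy:", object@n1, "west +", object@n2, "east tips, TMRCA =",
      signif(max(object@nodeTime), 4), "coalescent units\n")
})

#' @describeIn Genealogy-class time of the most recent common ancestor
#' @param x a Genealogy.
#' @export
tmrca <- function(x) max(x@nodeTime)

#' @describeIn Genealogy-class total branch length (coalescent units)
#' @export
totalBranchLength <- function(x) {
  ok <- !is.na(x@parent)
  sum(x@nodeTime[x@parent[ok]] - x@nodeTime[ok])
}

#' Draw one realisation of the divergence-pulse hyperprior
#'
#' Psi is uniform on \code{1..nTaxa}; the Psi pulse times are iid
#' Uniform(0, tauMax]; the taxon-to-pulse assignment is uniform over
#' surjections (rejection sampling, so every pulse receives at least one
#' taxon); theta1, theta2, thetaA are iid uniform on the prior interval
#' for each taxon.  Omega is the population-variance dispersion index
#' Var(tau)/E(tau).
#'
#' @param nTaxa number of taxon pairs (>= 2).
#' @param prior a \code{\link{priorSpec}}.
#' @param design optional per-taxon data.frame with columns \code{n1},
#'   \code{n2}, \code{L} (recycled if a single row); NA placeholders are
#'   used when absent.
#' @param psi optionally force the number of pulses (e.g. \code{psi = 1}
#'   for a synchronous draw).
#' @return a \linkS4class{HyperDraw}.
#' @examples
#' set.seed(1)
#' drawHyperparams(6, priorSpec(5))
#' @export
drawHyperparams <- function(nTaxa, prior, design = NULL, psi = NULL) {
  if (nTaxa < 2L) stop("nTaxa must be >= 2")
  if (!inherits(prior, "PriorSpec")) stop("'prior' must be a priorSpec()")
  if (is.null(psi)) psi <- sample.int(nTaxa, 1L)
  psi <- as.integer(psi)
  if (psi < 1L || psi > nTaxa) stop("psi must lie in 1..nTaxa")
  pulse <- runif(psi, 0, prior$tauMax)
  repeat {
    assign <- sample.int(psi, nTaxa, replace = TRUE)
    if (length(unique(assign)) == psi) break
  }
  tau <- pulse[assign]
  if (is.null(design)) {
    design <- data.frame(n1 = NA_integer_, n2 = NA_integer_, L = NA_integer_)
  }
  design <- design[rep_len(seq_len(nrow(design)), nTaxa), , drop = FALSE]
  th <- matrix(runif(3L * nTaxa, prior$thetaRange[1], prior$thetaRange[2]),
               ncol = 3L)
  params <- data.frame(n1 = as.integer(design$n1),
                       n2 = as.integer(design$n2),
                       L = as.integer(design$L),
                       theta1 = th[, 1], theta2 = th[, 2], thetaA = th[, 3],
                       tau = tau)
  new("HyperDraw", psi = psi, pulseTimes = pulse,
      assignment = as.integer(assign), tauVector = tau,
      omega = dispersionIndex(tau), eTau = mean(tau), params = params,
      taxonSeeds = integer(0))
}

#' Dispersion index of a divergence-time vector
#'
#' \code{Var(tau)/E(tau)} with the population variance (divide by n).
#' Zero iff all entries are equal (in particular whenever Psi = 1).
#'
#' @param tau vector of per-taxon divergence times.
#' @param sampleVariance use the n-1 denominator instead (off by default).
#' @return a non-negative scalar.
#' @examples dispersionIndex(c(1, 1, 1))  # 0
#' @export
dispersionIndex <- function(tau, sampleVariance = FALSE) {
  m <- mean(tau)
  if (m == 0) return(0)
  v <- if (sampleVariance) stats::var(tau) else mean((tau - m)^2)
  v / m
}

#' Simulate a two-population genealogy
#'
#' Looking backward in time, lineages coalesce only within their deme at
#' per-pair rate \code{thetaRef/theta_j} until time \code{tau}, when all
#' remaining lineages enter the ancestral deme (rate
#' \code{thetaRef/thetaA}).
#'
#' @param params a \code{\link{demographicParams}}.
#' @param scale a \code{\link{simScale}} fixing the time unit.
#' @return a \linkS4class{Genealogy}.
#' @examples
#' set.seed(1)
#' g <- simulateGenealogy(demographicParams(4, 4, 1000, .01, .01, .01, 2))
#' tmrca(g) >= 2
#' @export
simulateGenealogy <- function(params, scale = simScale()) {
  validObject(params)
  res <- .simGenealogyCpp(params@n1, params@n2, params@theta1,
                          params@theta2, params@thetaA, params@tau,
                          scale$thetaRef)
  new("Genealogy", parent = res$parent, nodeTime = res$nodeTime,
      n1 = params@n1, n2 = params@n2)
}

.modelKappa <- function(model, kappa) {
  model <- match.arg(model, c("JC", "HKY"))
  if (model == "JC") return(1)
  if (!is.numeric(kappa) || kappa <= 0)
    stop("HKY requires kappa > 0")
  kappa
}

#' Drop finite-sites mutations on a genealogy
#'
#' Mutation events are Poisson with per-site mean branch length times
#' \code{thetaRef/2}; substitutions follow JC or an HKY-style model with
#' transition/transversion ratio \code{kappa} and equal base frequencies
#' (\code{kappa = 1} reduces to JC).  Multiple hits per site are allowed.
#'
#' @param gen a \linkS4class{Genealogy}.
#' @param params the \code{\link{demographicParams}} (for the locus length).
#' @param scale a \code{\link{simScale}}.
#' @param model \code{"JC"} or \code{"HKY"}.
#' @param kappa transition/transversion rate ratio for HKY.
#' @return a \link[Biostrings]{DNAStringSet} of \code{n1 + n2} sequences
#'   named by the \code{taxon|side|sample} convention (side W then E).
#' @export
mutateAlignment <- function(gen, params, scale = simScale(), model = "JC",
                            kappa = 2) {
  kap <- .modelKappa(model, kappa)
  n <- gen@n1 + gen@n2
  m <- .mutateTreeCpp(gen@parent, gen@nodeTime, n, params@L,
                      scale$thetaRef, kap)
  seqs <- apply(m, 1L, function(r) paste(c("A", "C", "G", "T")[r + 1L],
                                         collapse = ""))
  side <- c(rep("W", gen@n1), rep("E", gen@n2))
  idx <- c(seq_len(gen@n1), seq_len(gen@n2))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("taxon|%s|s%02d", side, idx)
  out
}

#' Simulate alignments for a full taxon set
#'
#' Composes \code{\link{simulateGenealogy}} and
#' \code{\link{mutateAlignment}} across the taxa of a
#' \linkS4class{HyperDraw}.  When the draw carries per-taxon seeds each
#' taxon gets its own RNG stream, so alignments are stable under taxon
#' reordering.
#'
#' @param hyper a \linkS4class{HyperDraw} whose \code{params} include
#'   n1, n2 and L.
#' @param scale a \code{\link{simScale}}.
#' @param model,kappa mutation model, as in \code{\link{mutateAlignment}}.
#' @param taxa optional taxon names (default \code{taxon01}, ...).
#' @return list of \linkS4class{TaxonPairAlignment}.
#' @export
simulateTaxonSet <- function(hyper, scale = simScale(), model = "JC",
                             kappa = 2, taxa = NULL) {
  p <- hyper@params
  if (anyNA(p$n1) || anyNA(p$L))
    stop("hyper draw lacks a sampling design (n1, n2, L)")
  n <- nrow(p)
  if (is.null(taxa)) taxa <- sprintf("taxon%02d", seq_len(n))
  seeds <- hyper@taxonSeeds
  lapply(seq_len(n), function(i) {
    if (length(seeds) == n) set.seed(seeds[i])
    par <- demographicParams(p$n1[i], p$n2[i], p$L[i], p$theta1[i],
                             p$theta2[i], p$thetaA[i], p$tau[i])
    gen <- simulateGenealogy(par, scale)
    al <- mutateAlignment(gen, par, scale, model, kappa)
    names(al) <- sub("^taxon", taxa[i], names(al))
    taxonPairAlignment(taxa[i],
                       east = al[(p$n1[i] + 1L):(p$n1[i] + p$n2[i])],
                       west = al[seq_len(p$n1[i])])
  })
}

#' Simulate summary statistics for one taxon pair
#'
#' Fast path used by the ABC prior table: simulates the genealogy and the
#' mutations and returns the per-taxon statistic vector without
#' materialising sequences.
#'
#' @inheritParams simulateGenealogy
#' @inheritParams mutateAlignment
#' @return named numeric vector \code{pi_w1, pi_w2, pi_b, pi_net,
#'   theta_w, s}.
#' @export
simulateTaxonStats <- function(params, scale = simScale(), model = "JC",
                               kappa = 2) {
  validObject(params)
  kap <- .modelKappa(model, kappa)
  .simTaxonStatsCpp(params@n1, params@n2, params@L, params@theta1,
                    params@theta2, params@thetaA, params@tau,
                    scale$thetaRef, kap)
}
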