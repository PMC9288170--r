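# S4 classes for the core data objects.

#' Aligned sequences for one taxon pair
#'
#' Holds one taxon's aligned mtDNA sequences partitioned into the sample
#' sets east and west of the barrier.  All sequences must have the same
#' aligned length; multi-gene data are stored concatenated, with the
#' per-gene coordinate ranges kept in \code{geneRanges}.
#'
#' @slot taxon single taxon identifier.
#' @slot east,west \link[Biostrings]{DNAStringSet} of samples from each side.
#' @slot geneRanges data.frame with columns \code{gene}, \code{start},
#'   \code{end} (1-based, inclusive); zero rows for single-gene data.
#' @export
setClass("TaxonPairAlignment",
  representation(taxon = "character", east = "ANY", west = "ANY",
                 geneRanges = "data.frame"),
  prototype(geneRanges = data.frame(gene = character(), start = integer(),
                                    end = integer())))

setValidity("TaxonPairAlignment", function(object) {
  if (length(object@taxon) != 1L || is.na(object@taxon))
    return("'taxon' must be a single non-NA string")
  if (!is(object@east, "DNAStringSet") || !is(object@west, "DNAStringSet"))
    return("'east' and 'west' must be DNAStringSet objects")
  w <- c(Biostrings::width(object@east), Biostrings::width(object@west))
  if (length(w) == 0L) return("alignment has no sequences")
  if (length(unique(w)) != 1L)
    return("all sequences must have the same aligned length")
  TRUE
})

#' Construct a TaxonPairAlignment
#'
#' @param taxon taxon identifier.
#' @param east,west \link[Biostrings]{DNAStringSet} (or character vectors)
#'   of aligned sequences from each side of the barrier.
#' @param geneRanges optional data.frame of per-gene coordinates.
#' @return a \linkS4class{TaxonPairAlignment}.
#' @examples
#' taxonPairAlignment("frog1", c(a = "ACGT", b = "ACGA"),
#'                    c(c = "ACTT", d = "ACTT"))
#' @export
taxonPairAlignment <- function(taxon, east, west, geneRanges = NULL) {
  if (is.character(east)) east <- Biostrings::DNAStringSet(east)
  if (is.character(west)) west <- Biostrings::DNAStringSet(west)
  if (is.null(geneRanges))
    geneRanges <- data.frame(gene = character(), start = integer(),
                             end = integer())
  new("TaxonPairAlignment", taxon = taxon, east = east, west = west,
      geneRanges = geneRanges)
}

#' @describeIn taxonPairAlignment taxon identifier accessor
#' @param x a TaxonPairAlignment.
#' @export
taxonName <- function(x) x@taxon

#' @describeIn taxonPairAlignment eastern sample set accessor
#' @export
eastSeqs <- function(x) x@east

#' @describeIn taxonPairAlignment western sample set accessor
#' @export
westSeqs <- function(x) x@west

#' @describeIn taxonPairAlignment aligned length accessor
#' @export
alignedLength <- function(x) {
  w <- c(Biostrings::width(x@east), Biostrings::width(x@west))
  as.integer(w[1L])
}

setMethod("show", "TaxonPairAlignment", function(object) {
  cat("TaxonPairAlignment '", object@taxon, "': ",
      length(object@east), " east + ", length(object@west),
      " west sequences, ", alignedLength(object), " bp\n", sep = "")
})

#' Demographic parameters of the two-population isolation model
#'
#' One taxon pair: \code{n1}/\code{theta1} refer to the western deme,
#' \code{n2}/\code{theta2} to the eastern deme, \code{thetaA} to the
#' ancestral deme, and \code{tau} is the divergence time in coalescent
#' units (see \code{\link{simScale}} for the time convention).
#'
#' @slot n1,n2 haploid sample sizes per side.
#' @slot L locus length in bp.
#' @slot theta1,theta2,thetaA per-site population-mutation parameters.
#' @slot tau divergence time, coalescent units.
#' @export
setClass("DemographicParams",
  representation(n1 = "integer", n2 = "integer", L = "integer",
                 theta1 = "numeric", theta2 = "numeric", thetaA = "numeric",
                 tau = "numeric"))

setValidity("DemographicParams", function(object) {
  if (object@n1 < 1L || object@n2 < 1L) return("n1 and n2 must be >= 1")
  if (object@L < 1L) return("L must be >= 1")
  if (any(c(object@theta1, object@theta2, object@thetaA) <= 0))
    return("all theta values must be > 0")
  if (object@tau < 0) return("tau must be >= 0")
  TRUE
})

#' @rdname DemographicParams-class
#' @param n1,n2 haploid sample sizes (west, east).
#' @param L locus length (bp).
#' @param theta1,theta2,thetaA per-site thetas (west, east, ancestral).
#' @param tau divergence time in coalescent units.
#' @return a \linkS4class{DemographicParams}.
#' @export
demographicParams <- function(n1, n2, L, theta1, theta2, thetaA, tau) {
  new("DemographicParams", n1 = as.integer(n1), n2 = as.integer(n2),
      L = as.integer(L), theta1 = theta1, theta2 = theta2,
      thetaA = thetaA, tau = tau)
}

#' Simulation time-scale convention
#'
#' The coalescent time unit is fixed by a reference per-site theta
#' (\code{thetaRef}): the mutation rate per site per time unit is
#' \code{thetaRef/2} and the per-pair coalescence rate in a deme with
#' per-site theta \code{theta_j} is \code{thetaRef/theta_j}.  Under this
#' scaling the expected within-deme diversity is \code{theta_j} and the
#' expected net divergence is \code{thetaRef * tau + thetaA -
#' (theta1 + theta2)/2}, which makes the conversion
#' \code{t = tau * thetaAve / mu} (\code{\link{tauToYears}}) coherent.
#'
#' @param thetaRef positive per-site reference theta.  The default used
#'   throughout the package is the midpoint of the theta prior.
#' @return an object of class \code{SimScale}.
#' @examples simScale(0.01)
#' @export
simScale <- function(thetaRef = 0.01) {
  stopifnot(is.numeric(thetaRef), length(thetaRef) == 1L, thetaRef > 0)
  structure(list(thetaRef = thetaRef), class = "SimScale")
}

#' Hyperprior specification
#'
#' @param tauMax upper bound of the uniform pulse-time prior (coalescent
#'   units); in the motivating analyses this is set to the oldest mean
#'   split age observed for the taxon class.
#' @param thetaRange length-2 positive interval for the iid uniform priors
#'   on theta1, theta2, thetaA.
#' @return an object of class \code{PriorSpec}.
#' @examples priorSpec(5, c(0.005, 0.015))
#' @export
priorSpec <- function(tauMax, thetaRange = c(0.005, 0.015)) {
  if (!is.numeric(tauMax) || length(tauMax) != 1L || tauMax <= 0)
    stop("invalid prior: tauMax must be a single positive number")
  if (length(thetaRange) != 2L || any(thetaRange <= 0) ||
      thetaRange[2] < thetaRange[1])
    stop("invalid prior: thetaRange must be a positive increasing interval")
  structure(list(tauMax = tauMax, thetaRange = as.numeric(thetaRange)),
            class = "PriorSpec")
}

#' One draw from the divergence-pulse hyperprior
#'
#' @slot psi number of divergence pulses.
#' @slot pulseTimes pulse times (coalescent units), length \code{psi}.
#' @slot assignment taxon-to-pulse map (1-based), every pulse non-empty.
#' @slot tauVector per-taxon divergence times,
#'   \code{pulseTimes[assignment]}.
#' @slot omega dispersion index Var(tau)/E(tau) (population variance).
#' @slot eTau mean divergence time E(tau).
#' @slot params data.frame of per-taxon demographic parameters
#'   (n1, n2, L, theta1, theta2, thetaA, tau).
#' @slot taxonSeeds optional per-taxon RNG seeds, for reorder-stable
#'   simulation.
#' @export
setClass("HyperDraw",
  representation(psi = "integer", pulseTimes = "numeric",
                 assignment = "integer", tauVector = "numeric",
                 omega = "numeric", eTau = "numeric",
                 params = "data.frame", taxonSeeds = "integer"))

setValidity("HyperDraw", function(object) {
  n <- length(object@assignment)
  if (object@psi < 1L || object@psi > n)
    return("psi must lie in 1..taxon count")
  if (length(object@pulseTimes) != object@psi)
    return("pulseTimes must have length psi")
  if (any(object@pulseTimes <= 0)) return("pulse times must be positive")
  if (!setequal(unique(object@assignment), seq_len(object@psi)))
    return("every pulse must receive at least one taxon")
  if (!isTRUE(all.equal(object@tauVector,
                        object@pulseTimes[object@assignment])))
    return("tauVector must equal pulseTimes[assignment]")
  TRUE
})

setMethod("show", "HyperDraw", function(object) {
  cat("HyperDraw: Psi =", object@psi, "over", length(object@assignment),
      "taxa; Omega =", signif(object@omega, 4),
      "; E[tau] =", signif(object@eTau, 4), "\n")
})

#' ABC configuration
#'
#' @param nSims number of prior-predictive simulations (the motivating
#'   study used 1.5 million; the desk-scale default here is 100,000).
#' @param nAccept number of accepted draws (default 1,000).
#' @param omegaThresholds increasing positive Omega thresholds for the
#'   synchronous/asynchronous Bayes factors (default
#'   \code{c(0.01, 0.025, 0.05, 0.1)}).
#' @param adjust apply local-linear regression adjustment to the accepted
#'   Omega and E(tau) draws (default TRUE).
#' @param seed optional integer seed; if given, \code{\link{runHABC}} sets
#'   it before simulating.
#' @return an object of class \code{ABCConfig}.
#' @export
abcConfig <- function(nSims = 100000L, nAccept = 1000L,
                      omegaThresholds = c(0.01, 0.025, 0.05, 0.1),
                      adjust = TRUE, seed = NA_integer_) {
  nSims <- as.integer(nSims); nAccept <- as.integer(nAccept)
  if (nAccept > nSims) stop("nAccept must be <= nSims")
  if (any(omegaThresholds <= 0) || is.unsorted(omegaThresholds,
                                               strictly = TRUE))
    stop("omegaThresholds must be positive and strictly increasing")
  structure(list(nSims = nSims, nAccept = nAccept,
                 omegaThresholds = omegaThresholds, adjust = adjust,
                 seed = as.integer(seed)), class = "ABCConfig")
}

#' Prior-predictive simulation table
#'
#' One row per hyperprior draw: Psi, Omega, E(tau), the per-taxon tau
#' vector and pulse assignment, and the aggregate summary-statistic
#' vector simulated under the observed sampling design.
#'
#' @slot table data.frame of draws.
#' @slot nTaxa number of taxon pairs.
#' @slot design per-taxon data.frame (n1, n2, L).
#' @slot prior the \code{PriorSpec} used.
#' @slot thetaRef the reference theta fixing the time scale.
#' @slot statNames names of the statistic columns.
#' @export
setClass("PriorTable",
  representation(table = "data.frame", nTaxa = "integer",
                 design = "data.frame", prior = "list",
                 thetaRef = "numeric", statNames = "character"))

setMethod("show", "PriorTable", function(object) {
  cat("PriorTable:", nrow(object@table), "simulations,", object@nTaxa,
      "taxa, tauMax =", object@prior$tauMax, "\n")
})

#' @describeIn PriorTable-class number of simulated rows
#' @param x a PriorTable.
#' @export
nSimulations <- function(x) nrow(x@table)

#' Accepted (optionally regression-adjusted) hyperparameter draws
#'
#' @slot accepted data.frame of accepted rows, including acceptance
#'   distance and, when adjusted, \code{omegaAdj}/\code{eTauAdj}.
#' @slot psiFreq named posterior frequencies of Psi (sum to 1).
#' @slot nTaxa taxon-pair count.
#' @slot adjusted whether regression adjustment was applied.
#' @slot observed observed statistic vector (standardisation scale below).
#' @slot statNames,statSD statistic columns used for distances and their
#'   prior-table standard deviations.
#' @export
setClass("PosteriorSample",
  representation(accepted = "data.frame", psiFreq = "numeric",
                 nTaxa = "integer", adjusted = "logical",
                 observed = "numeric", statNames = "character",
                 statSD = "numeric"))

setValidity("PosteriorSample", function(object) {
  if (abs(sum(object@psiFreq) - 1) > 1e-8)
    return("psiFreq must sum to 1")
  TRUE
})

setMethod("show", "PosteriorSample", function(object) {
  s <- posteriorSummary(object)
  cat("PosteriorSample:", nrow(object@accepted), "accepted draws",
      if (object@adjusted) "(regression-adjusted)" else "(raw)", "\n")
  cat("  Psi mode:", psiMode(object), "\n")
  cat("  median Omega:", signif(s["omega", "median"], 4),
      " median E[tau]:", signif(s["eTau", "median"], 4), "\n")
})

#' Full hierarchical-ABC result
#'
#' @slot posterior a \linkS4class{PosteriorSample}.
#' @slot bf Bayes-factor table over the configured Omega thresholds.
#' @slot pulses pulse-grouping table (taxa per pulse at the posterior Psi
#'   mode, pulse-time medians and 95\% intervals).
#' @slot perTaxon per-taxon observed summary statistics.
#' @slot config the \code{ABCConfig} used.
#' @slot prior the \code{PriorSpec} used.
#' @slot thetaRef reference theta.
#' @slot seed the seed used (NA if none set).
#' @export
setClass("HABCResult",
  representation(posterior = "PosteriorSample", bf = "data.frame",
                 pulses = "data.frame", perTaxon = "data.frame",
                 config = "list", prior = "list", thetaRef = "numeric",
                 seed = "integer"))

setMethod("show", "HABCResult", function(object) {
  cat("HABCResult over", object@posterior@nTaxa, "taxon pairs\n")
  show(object@posterior)
  cat("Bayes factors (BF01, synchronous vs asynchronous):\n")
  print(object@bf[, c("threshold", "bf01", "label")], row.names = FALSE)
})

#' @describeIn HABCResult-class posterior sample accessor
#' @param x an HABCResult.
#' @export
posteriorSample <- function(x) x@posterior

#' @describeIn HABCResult-class Bayes-factor table accessor
#' @export
bayesFactorTable <- function(x) x@bf

#' @describeIn HABCResult-class pulse-grouping table accessor
#' @export
pulseTable <- function(x) x@pulses
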