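# Synthetic study inputs with known ground truth: multi-taxon alignments
# simulated under a known divergence-pulse history, plus a life-history
# table with a plantable thermoregulation effect.

#' Specification of a synthetic dataset
#'
#' @slot taxonCount number of taxon pairs (>= 2).
#' @slot samplesPerSide integer range (min, max) of haploid samples per
#'   side; the minimum must be >= 3, mirroring the minimum-sampling
#'   filter applied to real data.
#' @slot locusLength integer range (min, max) of locus lengths in bp.
#' @slot psiTrue true number of divergence pulses.
#' @slot pulseTimesTrue true pulse times (coalescent units), length
#'   \code{psiTrue}.
#' @slot thetaRange positive interval for the per-side thetas.
#' @slot model,kappa mutation model (JC, or HKY with ratio kappa).
#' @slot lhEffect ln-scale shift of divergence time for homeotherms in
#'   the life-history table (0 = no planted effect).
#' @slot nRate rate at which N characters are injected (default 0).
#' @slot seed master seed; identical seeds give byte-identical outputs.
#' @export
setClass("SyntheticSpec",
  representation(taxonCount = "integer", samplesPerSide = "integer",
                 locusLength = "integer", psiTrue = "integer",
                 pulseTimesTrue = "numeric", thetaRange = "numeric",
                 model = "character", kappa = "numeric",
                 lhEffect = "numeric", nRate = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (object@taxonCount < 2L) return("taxonCount must be >= 2")
  if (object@psiTrue < 1L || object@psiTrue > object@taxonCount)
    return("invalid spec: psiTrue must lie in 1..taxonCount")
  if (length(object@pulseTimesTrue) != object@psiTrue)
    return("pulseTimesTrue must have length psiTrue")
  if (any(object@pulseTimesTrue <= 0))
    return("pulse times must be positive")
  if (object@samplesPerSide[1] < 3L)
    return("samplesPerSide minimum must be >= 3")
  if (any(diff(object@samplesPerSide) < 0) ||
      any(diff(object@locusLength) < 0))
    return("ranges must be (min, max) with min <= max")
  if (any(object@thetaRange <= 0) ||
      object@thetaRange[2] < object@thetaRange[1])
    return("thetaRange must be a positive increasing interval")
  if (object@nRate < 0 || object@nRate >= 1)
    return("nRate must be in [0, 1)")
  TRUE
})

#' @rdname SyntheticSpec-class
#' @param taxonCount number of taxon pairs.
#' @param samplesPerSide length-2 integer range of samples per side.
#' @param locusLength length-2 integer range of locus lengths (bp).
#' @param psiTrue true pulse count.
#' @param pulseTimesTrue true pulse times (coalescent units).
#' @param thetaRange theta interval.
#' @param model,kappa mutation model.
#' @param lhEffect planted homeotherm ln-shift of divergence time.
#' @param nRate missing-data injection rate.
#' @param seed master seed.
#' @return a \linkS4class{SyntheticSpec}.
#' @examples syntheticSpec(8, psiTrue = 1, pulseTimesTrue = 1)
#' @export
syntheticSpec <- function(taxonCount, samplesPerSide = c(4L, 8L),
                          locusLength = c(500L, 1500L), psiTrue = 1L,
                          pulseTimesTrue = 1, thetaRange = c(0.005, 0.015),
                          model = "JC", kappa = 1, lhEffect = 0,
                          nRate = 0, seed = 1L) {
  new("SyntheticSpec", taxonCount = as.integer(taxonCount),
      samplesPerSide = as.integer(samplesPerSide),
      locusLength = as.integer(locusLength), psiTrue = as.integer(psiTrue),
      pulseTimesTrue = as.numeric(pulseTimesTrue),
      thetaRange = as.numeric(thetaRange), model = model, kappa = kappa,
      lhEffect = lhEffect, nRate = nRate, seed = as.integer(seed))
}

.injectN <- function(x, rate) {
  if (rate <= 0) return(x)
  chs <- strsplit(as.character(x), "")
  out <- vapply(chs, function(ch) {
    hit <- runif(length(ch)) < rate
    ch[hit] <- "N"
    paste(ch, collapse = "")
  }, character(1))
  res <- Biostrings::DNAStringSet(out)
  names(res) <- names(x)
  res
}

#' Generate a complete synthetic dataset with known truth
#'
#' Draws a per-taxon sampling design and thetas, assigns taxa to the true
#' pulses (uniform over surjections, so every pulse is realised), and
#' simulates one alignment per taxon under the two-population isolation
#' model.  The ancestral theta is the mean of the two daughter thetas,
#' which makes the expected net divergence exactly
#' \code{thetaRef * tau}.  Each taxon has its own RNG stream derived from
#' the master seed, so outputs are reproducible and stable under taxon
#' reordering.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param alignments simulate sequences (set FALSE to generate only the
#'   truth record, e.g. for life-history recovery studies).
#' @param scale optional \code{\link{simScale}}; defaults to the midpoint
#'   of \code{thetaRange}.
#' @return list with \code{alignments} (list of
#'   \linkS4class{TaxonPairAlignment}, or NULL), \code{truth} (psiTrue,
#'   tauTrue, assignment, omegaTrue, eTauTrue, thetas, design, seeds) and
#'   \code{hyper} (the ground-truth \linkS4class{HyperDraw}).
#' @examples
#' d <- generateDataset(syntheticSpec(4, psiTrue = 2,
#'                                    pulseTimesTrue = c(0.5, 2)))
#' d$truth$omegaTrue >= 0
#' @export
generateDataset <- function(spec, alignments = TRUE, scale = NULL) {
  validObject(spec)
  if (is.null(scale)) scale <- simScale(mean(spec@thetaRange))
  set.seed(spec@seed)
  n <- spec@taxonCount
  psi <- spec@psiTrue
  repeat {
    assign <- sample.int(psi, n, replace = TRUE)
    if (length(unique(assign)) == psi) break
  }
  tau <- spec@pulseTimesTrue[assign]
  rint <- function(r) r[1] + sample.int(r[2] - r[1] + 1L, n,
                                        replace = TRUE) - 1L
  nW <- rint(spec@samplesPerSide)
  nE <- rint(spec@samplesPerSide)
  L <- rint(spec@locusLength)
  th1 <- runif(n, spec@thetaRange[1], spec@thetaRange[2])
  th2 <- runif(n, spec@thetaRange[1], spec@thetaRange[2])
  thA <- (th1 + th2) / 2
  taxonSeeds <- sample.int(.Machine$integer.max - 1L, n)
  injectSeeds <- sample.int(.Machine$integer.max - 1L, n)
  lhSeed <- sample.int(.Machine$integer.max - 1L, 1L)
  taxa <- sprintf("taxon%02d", seq_len(n))
  params <- data.frame(n1 = nW, n2 = nE, L = L, theta1 = th1,
                       theta2 = th2, thetaA = thA, tau = tau)
  hyper <- new("HyperDraw", psi = psi,
               pulseTimes = spec@pulseTimesTrue,
               assignment = as.integer(assign), tauVector = tau,
               omega = dispersionIndex(tau), eTau = mean(tau),
               params = params, taxonSeeds = taxonSeeds)
  al <- NULL
  if (alignments) {
    al <- simulateTaxonSet(hyper, scale, spec@model, spec@kappa, taxa)
    if (spec@nRate > 0) {
      for (i in seq_len(n)) {
        set.seed(injectSeeds[i])
        al[[i]]@east <- .injectN(al[[i]]@east, spec@nRate)
        al[[i]]@west <- .injectN(al[[i]]@west, spec@nRate)
      }
    }
    names(al) <- taxa
  }
  truth <- list(taxa = taxa, psiTrue = psi,
                pulseTimesTrue = spec@pulseTimesTrue,
                assignment = assign, tauTrue = tau,
                omegaTrue = dispersionIndex(tau), eTauTrue = mean(tau),
                thetas = params[, c("theta1", "theta2", "thetaA")],
                design = params[, c("n1", "n2", "L")],
                thetaRef = scale$thetaRef, taxonSeeds = taxonSeeds,
                lhSeed = lhSeed, seed = spec@seed)
  list(alignments = al, truth = truth, hyper = hyper)
}

#' Generate a life-history table matched to a truth record
#'
#' One row per taxon with the six predictors used by the divergence-time
#' models.  Classes are assigned round-robin (amphibian, reptile, bird,
#' mammal); thermoregulation follows class (birds and mammals
#' homeothermic), locomotion is flying for birds and every third mammal
#' (bats); body length and geographic range are log-uniform and the
#' upper elevation limit uniform over documented ranges.  The divergence
#' time column is the true tau converted to Ma via
#' \code{\link{tauToYears}}, with multiplicative lognormal noise and an
#' optional ln-scale homeotherm shift \code{lhEffect}.
#'
#' @param spec the \code{\link{syntheticSpec}} used to generate
#'   \code{truth}.
#' @param truth the truth record from \code{\link{generateDataset}}.
#' @param tsCfg optional \code{\link{timescaleConfig}}; the default uses
#'   mu = 1e-8 per site per generation, a 1-year generation time and the
#'   truth's mean theta, so tau = 1 maps to roughly 1 Ma.
#' @param noiseSD lognormal noise standard deviation on the ln scale
#'   (default 0.4).
#' @return data.frame with taxon, class, body_length (mm), geo_range
#'   (km2), upper_elevation (m), locomotion, thermoregulation,
#'   mean_div_time (Ma).
#' @export
generateLifeHistory <- function(spec, truth, tsCfg = NULL, noiseSD = 0.4) {
  if (length(truth$tauTrue) != spec@taxonCount)
    stop("truth record does not match spec")
  if (is.null(tsCfg)) {
    thetaAve <- mean((truth$thetas$theta1 + truth$thetas$theta2) / 2)
    tsCfg <- timescaleConfig(mu = 1e-8, g = 1, thetaAve = thetaAve)
  }
  set.seed(truth$lhSeed)
  n <- spec@taxonCount
  cls <- rep(c("amphibian", "reptile", "bird", "mammal"), length.out = n)
  # thermoregulation is balanced but assigned independently of class, so
  # a planted effect identifies the thermoregulation term itself rather
  # than its taxonomic surrogate (real data confound the two)
  thermo <- sample(rep(c("homeotherm", "poikilotherm"), length.out = n))
  mam <- which(cls == "mammal")
  loco <- ifelse(cls == "bird", "flying", "non-flying")
  loco[mam[seq_along(mam) %% 3L == 0L]] <- "flying"
  ageMa <- tauToYears(truth$tauTrue, tsCfg) / 1e6
  shift <- ifelse(thermo == "homeotherm", spec@lhEffect, 0)
  ageMa <- exp(log(ageMa) + shift + rnorm(n, 0, noiseSD))
  data.frame(taxon = truth$taxa, class = cls,
             body_length = exp(runif(n, log(30), log(1000))),
             geo_range = exp(runif(n, log(1e4), log(1e7))),
             upper_elevation = runif(n, 200, 2000),
             locomotion = loco, thermoregulation = thermo,
             mean_div_time = ageMa)
}

#' Write a synthetic dataset to disk
#'
#' FASTA per taxon (\code{taxonID|side|sampleID} headers), a truth-record
#' JSON and a life-history TSV; byte-identical for identical specs.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param dir output directory.
#' @return named list of written paths, invisibly.
#' @export
writeSyntheticDataset <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- generateDataset(spec)
  fasta <- vapply(d$alignments, function(x) {
    p <- file.path(dir, paste0(x@taxon, ".fasta"))
    writeTaxonPairFasta(x, p)
    p
  }, character(1))
  truthPath <- file.path(dir, "truth.json")
  jsonlite::write_json(d$truth, truthPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  lh <- generateLifeHistory(spec, d$truth)
  lhPath <- file.path(dir, "life_history.tsv")
  utils::write.table(lh, lhPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta = fasta, truth = truthPath, lifeHistory = lhPath))
}
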