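# Conversion of coalescent divergence times to generations and calendar
# years, plus a moment-based dating stand-in for per-taxon node ages.

#' Time-scale configuration
#'
#' @param mu neutral mutation rate per site per generation.
#' @param g generation time in years.
#' @param thetaAve per-site theta averaged over taxa (the product of mu
#'   and the average effective population size); the package convention
#'   is the mean over taxa of \code{(theta1 + theta2)/2} as estimated by
#'   the ABC posterior, but any override can be supplied.  Whether this
#'   quantity is \code{mu*N} or \code{2*mu*N} for a haploid maternally
#'   inherited marker is a convention that the caller's value must carry.
#' @param lineageRate substitutions per site per lineage per million
#'   years, for \code{\link{momentSplitAge}}; e.g. 0.00955 for anuran
#'   mtDNA, or 0.01 for the avian "2\% total divergence per Myr" clock
#'   (per-lineage rate = half the total rate).
#' @return an object of class \code{TimescaleConfig}.
#' @examples timescaleConfig(mu = 1e-8, g = 1, thetaAve = 0.005)
#' @export
timescaleConfig <- function(mu, g = 1, thetaAve = NULL,
                            lineageRate = 0.01) {
  if (!is.numeric(mu) || mu <= 0) stop("mu must be positive")
  if (!is.numeric(g) || g <= 0) stop("g must be positive")
  if (!is.null(thetaAve) && thetaAve <= 0) stop("thetaAve must be positive")
  if (lineageRate <= 0) stop("lineageRate must be positive")
  structure(list(mu = mu, g = g, thetaAve = thetaAve,
                 lineageRate = lineageRate), class = "TimescaleConfig")
}

#' Convert a coalescent divergence time to years
#'
#' \code{t_generations = tau * thetaAve / mu}, returned as
#' \code{t_generations * g} years.  Linear and strictly monotone in tau.
#'
#' @param tau divergence time(s) in coalescent units, >= 0.
#' @param cfg a \code{\link{timescaleConfig}} with \code{thetaAve} set.
#' @return time in years.
#' @examples
#' cfg <- timescaleConfig(mu = 1e-8, g = 1, thetaAve = 0.005)
#' tauToYears(2, cfg)  # 1e6 years
#' @export
tauToYears <- function(tau, cfg) {
  stopifnot(inherits(cfg, "TimescaleConfig"))
  if (is.null(cfg$thetaAve)) stop("cfg$thetaAve is required")
  if (any(tau < 0)) stop("tau must be >= 0")
  tau * cfg$thetaAve / cfg$mu * cfg$g
}

#' @describeIn tauToYears inverse conversion, years to coalescent units
#' @param years time in years.
#' @export
yearsToTau <- function(years, cfg) {
  stopifnot(inherits(cfg, "TimescaleConfig"))
  years / cfg$g * cfg$mu / cfg$thetaAve
}

#' Moment-based split age from net divergence
#'
#' \code{age_Ma = pi_net / (2 * lineageRate)}: the standard strict-clock
#' moment estimator, used as a lightweight stand-in for relaxed-clock
#' node ages in synthetic runs.
#'
#' @param piNet net between-population divergence per site, >= 0.
#' @param cfg a \code{\link{timescaleConfig}} (uses \code{lineageRate}).
#' @return age in millions of years.
#' @examples
#' momentSplitAge(0.0191, timescaleConfig(1e-8, lineageRate = 0.00955)) # 1 Ma
#' @export
momentSplitAge <- function(piNet, cfg) {
  stopifnot(inherits(cfg, "TimescaleConfig"))
  if (any(piNet < 0)) stop("piNet must be >= 0")
  piNet / (2 * cfg$lineageRate)
}

#' Average theta from an ABC result
#'
#' The mean over taxa of the midpoint of the theta prior is not
#' informative; instead this uses the per-taxon observed within-side
#' diversities (whose expectations are theta1 and theta2 under the model)
#' averaged across sides and taxa.
#'
#' @param result an \linkS4class{HABCResult}.
#' @return a positive scalar usable as \code{thetaAve}.
#' @export
estimateThetaAve <- function(result) {
  pt <- result@perTaxon
  mean((pt$pi_w1 + pt$pi_w2) / 2)
}
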