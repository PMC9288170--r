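# Hierarchical ABC: prior-predictive table, rejection sampling,
# local-linear regression adjustment, Bayes factors, end-to-end driver.

.OMEGA_EPS <- 1e-6

#' Build the prior-predictive simulation table
#'
#' Simulates \code{cfg$nSims} datasets of the same size as the observed
#' data (the per-taxon sampling design) under the divergence-pulse
#' hyperprior and records, per row, the hyperparameters (Psi, Omega,
#' E(tau)), the per-taxon tau vector and pulse assignment, and the
#' aggregate summary-statistic vector.
#'
#' @param design per-taxon data.frame with columns \code{n1}, \code{n2}
#'   (haploid sample counts west, east) and \code{L} (bp).
#' @param prior a \code{\link{priorSpec}}.
#' @param cfg an \code{\link{abcConfig}}.
#' @param scale a \code{\link{simScale}}; defaults to the midpoint of the
#'   theta prior.
#' @param model,kappa mutation model (see \code{\link{mutateAlignment}}).
#' @return a \linkS4class{PriorTable}.
#' @export
buildPriorTable <- function(design, prior, cfg = abcConfig(),
                            scale = NULL, model = "JC", kappa = 2) {
  if (!inherits(prior, "PriorSpec")) stop("invalid prior")
  stopifnot(all(c("n1", "n2", "L") %in% names(design)))
  if (nrow(design) < 2L) stop("need >= 2 taxon pairs")
  if (is.null(scale)) scale <- simScale(mean(prior$thetaRange))
  kap <- .modelKappa(model, kappa)
  nt <- nrow(design)
  m <- .buildPriorTableCpp(as.integer(design$n1), as.integer(design$n2),
                           as.integer(design$L), prior$tauMax,
                           prior$thetaRange[1], prior$thetaRange[2],
                           cfg$nSims, scale$thetaRef, kap)
  colnames(m) <- c("psi", "omega", "eTau",
                   sprintf("tau_%d", seq_len(nt)),
                   sprintf("assign_%d", seq_len(nt)), .STAT_NAMES)
  new("PriorTable", table = as.data.frame(m), nTaxa = as.integer(nt),
      design = design, prior = unclass(prior), thetaRef = scale$thetaRef,
      statNames = .STAT_NAMES)
}

#' ABC rejection step
#'
#' Statistic columns are standardised by their prior-table standard
#' deviations (constant columns are dropped with a warning), distances
#' are Euclidean, and the \code{cfg$nAccept} nearest rows are accepted;
#' ties are broken by simulation index.
#'
#' @param prior a \linkS4class{PriorTable}.
#' @param observedStats named numeric vector matching the table's
#'   statistic columns (e.g. \code{summarizeDataset(x)$aggregate}).
#' @param cfg an \code{\link{abcConfig}}.
#' @return a \linkS4class{PosteriorSample} (unadjusted).
#' @export
rejectionSample <- function(prior, observedStats, cfg = abcConfig()) {
  stopifnot(is(prior, "PriorTable"))
  tab <- prior@table
  sn <- prior@statNames
  if (!all(sn %in% names(observedStats)))
    stop("observed statistics do not match the prior table's columns")
  obs <- observedStats[sn]
  sds <- vapply(tab[sn], sd, numeric(1))
  keep <- is.finite(sds) & sds > 0
  if (!all(keep)) {
    warning("dropping constant statistic column(s): ",
            paste(sn[!keep], collapse = ", "))
    sn <- sn[keep]; obs <- obs[keep]; sds <- sds[keep]
  }
  z <- scale(as.matrix(tab[sn]), center = obs, scale = sds)
  dist <- sqrt(rowSums(z^2))
  nAcc <- min(cfg$nAccept, nrow(tab))
  ord <- order(dist, seq_along(dist))[seq_len(nAcc)]
  acc <- tab[ord, , drop = FALSE]
  acc$index <- ord
  acc$distance <- dist[ord]
  psiFreq <- tabulate(acc$psi, nbins = prior@nTaxa) / nAcc
  names(psiFreq) <- seq_len(prior@nTaxa)
  new("PosteriorSample", accepted = acc, psiFreq = psiFreq,
      nTaxa = prior@nTaxa, adjusted = FALSE, observed = obs,
      statNames = sn, statSD = sds)
}

#' Local-linear regression adjustment of the accepted draws
#'
#' Weighted local-linear regression (Epanechnikov weights over the
#' acceptance distances) of the transformed hyperparameters on the
#' standardised statistics; each accepted value is replaced by the fit at
#' the observed statistics plus its residual.  Omega is adjusted on
#' \code{ln(Omega + 1e-6)} and E(tau) on the ln scale, and adjusted
#' values are clamped to be non-negative, keeping both supports valid.
#' Degenerate designs (no statistic spread, singular fit) fall back to
#' the unadjusted values with a warning.
#'
#' @param post a \linkS4class{PosteriorSample} with >= 10 accepted rows.
#' @return the input with \code{omegaAdj} and \code{eTauAdj} columns and
#'   \code{adjusted = TRUE}.
#' @export
regressionAdjust <- function(post) {
  stopifnot(is(post, "PosteriorSample"))
  acc <- post@accepted
  if (nrow(acc) < 10L) stop("need >= 10 accepted rows to adjust")
  X <- scale(as.matrix(acc[post@statNames]), center = post@observed,
             scale = post@statSD)
  dmax <- max(acc$distance)
  fallback <- function(msg) {
    warning("regression adjustment skipped: ", msg)
    acc$omegaAdj <- acc$omega
    acc$eTauAdj <- acc$eTau
    post@accepted <- acc
    post@adjusted <- TRUE
    post
  }
  if (dmax == 0 || any(!is.finite(X)))
    return(fallback("no spread in accepted statistics"))
  w <- 1 - (acc$distance / dmax)^2
  if (sum(w > 0) < ncol(X) + 2L)
    return(fallback("too few positively weighted rows"))
  adjustOne <- function(y) {
    fit <- tryCatch(stats::lm.wfit(cbind(1, X), y, w),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    b <- coef(fit)[-1]
    # aliased columns (exactly collinear statistics, e.g. the pi_net
    # identity linking the cross-taxon means) contribute nothing
    b[is.na(b)] <- 0
    if (all(b == 0) && is.na(coef(fit)[1])) return(NULL)
    y - as.vector(X %*% b)     # fit at observed (X = 0) + residual
  }
  yo <- adjustOne(log(acc$omega + .OMEGA_EPS))
  ye <- adjustOne(log(acc$eTau))
  if (is.null(yo) || is.null(ye)) return(fallback("singular design"))
  acc$omegaAdj <- pmax(exp(yo) - .OMEGA_EPS, 0)
  acc$eTauAdj <- exp(ye)
  post@accepted <- acc
  post@adjusted <- TRUE
  post
}

#' @describeIn rejectionSample posterior mode of Psi (smallest on ties)
#' @param post a PosteriorSample.
#' @export
psiMode <- function(post) {
  as.integer(names(post@psiFreq)[which.max(post@psiFreq)])
}

#' Posterior summaries of Omega and E(tau)
#'
#' @param post a \linkS4class{PosteriorSample}.
#' @param level credibility-interval mass (default 0.95).
#' @param adjusted use the regression-adjusted values when available.
#' @return data.frame with rows \code{omega} and \code{eTau} and columns
#'   median, lower, upper.
#' @export
posteriorSummary <- function(post, level = 0.95, adjusted = TRUE) {
  acc <- post@accepted
  useAdj <- adjusted && post@adjusted
  om <- if (useAdj) acc$omegaAdj else acc$omega
  et <- if (useAdj) acc$eTauAdj else acc$eTau
  a <- (1 - level) / 2
  f <- function(x) c(median = median(x),
                     lower = unname(quantile(x, a)),
                     upper = unname(quantile(x, 1 - a)))
  out <- rbind(omega = f(om), eTau = f(et))
  as.data.frame(out)
}

#' Threshold Bayes factor for synchronous divergence
#'
#' \code{BF01 = [p/(1-p)] / [q/(1-q)]} with \code{p} the posterior and
#' \code{q} the prior probability of \code{Omega <= threshold} (both
#' empirical; the prior tail is taken from the full prior table).  A
#' zero-count posterior tail is reported as a bound using \code{1/n}
#' (flagged in the \code{bound} column); a degenerate prior tail
#' (\code{q} of 0 or 1) yields an NA Bayes factor flagged as a bound.
#'
#' @param post a \linkS4class{PosteriorSample}.
#' @param prior the \linkS4class{PriorTable} the posterior came from.
#' @param threshold positive Omega threshold.
#' @param adjusted use adjusted Omega draws when available.
#' @return one-row data.frame: threshold, postP, priorP, bf01, bound
#'   (\code{""}, \code{"<"} or \code{">"}), label.
#' @examples
#' # p = 0.6, q = 0.5 gives BF01 = (0.6/0.4)/(0.5/0.5) = 1.5
#' @export
bayesFactor <- function(post, prior, threshold, adjusted = TRUE) {
  if (threshold <= 0) stop("threshold must be > 0")
  acc <- post@accepted
  om <- if (adjusted && post@adjusted) acc$omegaAdj else acc$omega
  n <- length(om)
  p <- mean(om <= threshold)
  q <- mean(prior@table$omega <= threshold)
  bound <- ""
  if (q %in% c(0, 1)) {
    return(data.frame(threshold = threshold, postP = p, priorP = q,
                      bf01 = NA_real_, bound = "prior-degenerate",
                      label = "undetermined (degenerate prior tail)"))
  }
  if (p == 0) { p <- 1 / n; bound <- "<" }
  if (p == 1) { p <- 1 - 1 / n; bound <- ">" }
  bf <- (p / (1 - p)) / (q / (1 - q))
  data.frame(threshold = threshold, postP = mean(om <= threshold),
             priorP = q, bf01 = bf, bound = bound,
             label = interpretBF(bf))
}

#' Qualitative label for a Bayes factor
#'
#' Jeffreys-style magnitudes on \code{max(bf, 1/bf)} with the direction
#' rule: BF01 > 1 favours the synchronous model M0, BF01 < 1 the
#' asynchronous model M1, and "strong" support requires a factor beyond
#' 100 (or below 1/100).
#'
#' @param bf non-negative Bayes factor BF01.
#' @return character label.
#' @examples
#' interpretBF(0.006)  # strong support for M1
#' interpretBF(150)    # strong support for M0
#' @export
interpretBF <- function(bf) {
  if (is.na(bf)) return(NA_character_)
  if (bf < 0) stop("bf must be >= 0")
  if (bf == 1) return("No evidence")
  m <- max(bf, 1 / bf)
  dir <- if (bf > 1) "M0" else "M1"
  grade <- if (m <= 3) "Anecdotal" else if (m <= 10) "Substantial"
           else if (m <= 100) "Moderate to very strong"
           else "Strong"
  paste0(grade, " support for ", dir)
}

# pulse grouping at the posterior Psi mode: pairwise co-assignment
# frequencies, average-linkage clustering into psiMode groups, pooled
# per-group tau medians and 95% intervals
.pulseGroups <- function(post, taxa = NULL, level = 0.95) {
  nt <- post@nTaxa
  if (is.null(taxa)) taxa <- sprintf("taxon%02d", seq_len(nt))
  m <- psiMode(post)
  acc <- post@accepted
  rows <- acc[acc$psi == m, , drop = FALSE]
  tauCols <- sprintf("tau_%d", seq_len(nt))
  asgCols <- sprintf("assign_%d", seq_len(nt))
  a <- (1 - level) / 2
  if (m == 1L || nrow(rows) < 2L) {
    tauAll <- unlist(rows[tauCols], use.names = FALSE)
    if (length(tauAll) == 0)
      tauAll <- unlist(acc[tauCols], use.names = FALSE)
    return(data.frame(pulse = 1L, taxa = paste(taxa, collapse = ","),
                      tauMedian = median(tauAll),
                      tauLower = unname(quantile(tauAll, a)),
                      tauUpper = unname(quantile(tauAll, 1 - a))))
  }
  asg <- as.matrix(rows[asgCols])
  co <- matrix(1, nt, nt)
  for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt)
    co[i, j] <- co[j, i] <- mean(asg[, i] == asg[, j])
  grp <- cutree(hclust(as.dist(1 - co), method = "average"), k = m)
  tauMat <- as.matrix(rows[tauCols])
  res <- lapply(seq_len(m), function(g) {
    tg <- as.vector(tauMat[, grp == g, drop = FALSE])
    data.frame(taxa = paste(taxa[grp == g], collapse = ","),
               tauMedian = median(tg),
               tauLower = unname(quantile(tg, a)),
               tauUpper = unname(quantile(tg, 1 - a)))
  })
  res <- do.call(rbind, res)
  res <- res[order(res$tauMedian), , drop = FALSE]
  cbind(pulse = seq_len(m), res, row.names = NULL)
}

#' Run the full hierarchical ABC analysis
#'
#' End-to-end driver: summarises the observed alignments, simulates the
#' prior-predictive table under the observed sampling design, applies the
#' rejection step and (optionally) the regression adjustment, and
#' computes the Bayes-factor table over the configured Omega thresholds
#' plus the pulse-grouping table at the posterior Psi mode.  If a
#' \code{\link{timescaleConfig}} is supplied, pulse times are also
#' reported in Ma.
#'
#' @param data list of \linkS4class{TaxonPairAlignment} (already
#'   filtered; see \code{\link{filterMissing}}).
#' @param prior a \code{\link{priorSpec}}.
#' @param cfg an \code{\link{abcConfig}}.
#' @param scale optional \code{\link{simScale}} (default: theta-prior
#'   midpoint).
#' @param timescale optional \code{\link{timescaleConfig}} for converting
#'   pulse times to Ma.
#' @param model,kappa mutation model for the simulations.
#' @return an \linkS4class{HABCResult}.
#' @export
runHABC <- function(data, prior, cfg = abcConfig(), scale = NULL,
                    timescale = NULL, model = "JC", kappa = 2) {
  if (!is.na(cfg$seed)) set.seed(cfg$seed)
  obs <- summarizeDataset(data)
  design <- obs$perTaxon[, c("n_west", "n_east", "L")]
  names(design) <- c("n1", "n2", "L")
  if (is.null(scale)) scale <- simScale(mean(prior$thetaRange))
  pt <- buildPriorTable(design, prior, cfg, scale, model, kappa)
  post <- rejectionSample(pt, obs$aggregate, cfg)
  if (cfg$adjust) post <- regressionAdjust(post)
  bf <- do.call(rbind, lapply(cfg$omegaThresholds, function(th)
    bayesFactor(post, pt, th)))
  pulses <- .pulseGroups(post, taxa = obs$perTaxon$taxon)
  if (!is.null(timescale)) {
    pulses$timeMa <- tauToYears(pulses$tauMedian, timescale) / 1e6
    pulses$timeLowerMa <- tauToYears(pulses$tauLower, timescale) / 1e6
    pulses$timeUpperMa <- tauToYears(pulses$tauUpper, timescale) / 1e6
  }
  new("HABCResult", posterior = post, bf = bf, pulses = pulses,
      perTaxon = obs$perTaxon, config = unclass(cfg),
      prior = unclass(prior), thetaRef = scale$thetaRef,
      seed = cfg$seed)
}
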