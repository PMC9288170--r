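# AICc-ranked general linear models of divergence time on life-history
# predictors, plus the descriptive group summaries and the per-class
# age / net-divergence correlations.

#' Validate and transform the life-history table for model fitting
#'
#' The response is \code{ln(mean_div_time)} and body length is
#' ln-transformed; geographic range and upper elevation limit stay on
#' their original scales.  Categorical predictors use treatment contrasts
#' with reference levels poikilotherm, non-flying and class amphibian, so
#' a negative thermoregulation coefficient means homeotherms diverge
#' more recently.
#'
#' @param table data.frame with columns \code{class} (amphibian, reptile,
#'   bird, mammal), \code{body_length} (mm), \code{geo_range} (km2),
#'   \code{upper_elevation} (m), \code{locomotion} (flying/non-flying),
#'   \code{thermoregulation} (homeotherm/poikilotherm),
#'   \code{mean_div_time} (Ma), optionally \code{pi_net}.
#' @return data.frame with \code{ln_div_time}, \code{ln_body} and
#'   releveled factors, ready for \code{\link{fitAndRank}}.
#' @export
prepareDesign <- function(table) {
  need <- c("class", "body_length", "geo_range", "upper_elevation",
            "locomotion", "thermoregulation", "mean_div_time")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(table$mean_div_time) | table$mean_div_time <= 0)
  if (length(bad)) stop("non-positive divergence time in row(s): ",
                        paste(bad, collapse = ", "))
  bad <- which(!is.finite(table$body_length) | table$body_length <= 0)
  if (length(bad)) stop("non-positive body length in row(s): ",
                        paste(bad, collapse = ", "))
  if (anyNA(table[need])) stop("missing predictor values are not allowed")
  d <- table
  d$ln_div_time <- log(d$mean_div_time)
  d$ln_body <- log(d$body_length)
  d$class <- factor(d$class,
                    levels = c("amphibian", "reptile", "bird", "mammal"))
  if (anyNA(d$class)) stop("unknown class label")
  d$locomotion <- factor(d$locomotion, levels = c("non-flying", "flying"))
  d$thermoregulation <- factor(d$thermoregulation,
                               levels = c("poikilotherm", "homeotherm"))
  if (anyNA(d$locomotion) || anyNA(d$thermoregulation))
    stop("unknown locomotion or thermoregulation label")
  d
}

#' Corrected Akaike information criterion
#'
#' \code{AICc = -2*loglik + 2k + 2k(k+1)/(n-k-1)}, where k counts all
#' estimated parameters including the residual variance.
#'
#' @param loglik model log-likelihood.
#' @param k number of estimated parameters (including sigma^2).
#' @param n sample size; must exceed \code{k + 1}.
#' @return the AICc value.
#' @examples aicc(-50, 3, 37)  # 100 + 24/33
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# the 13 a-priori model formulas (response: ln divergence time)
.GLM_MODELS <- list(
  "Temperature regulation" = ln_div_time ~ thermoregulation,
  "Upper elevation limit x Temperature regulation" =
    ln_div_time ~ upper_elevation * thermoregulation,
  "Upper elevation limit" = ln_div_time ~ upper_elevation,
  "Class" = ln_div_time ~ class,
  "Geographic range + Upper elevation limit" =
    ln_div_time ~ geo_range + upper_elevation,
  "Dispersal" = ln_div_time ~ locomotion,
  "Body size" = ln_div_time ~ ln_body,
  "Geographic range" = ln_div_time ~ geo_range,
  "Body size + Geographic range + Upper elevation limit" =
    ln_div_time ~ ln_body + geo_range + upper_elevation,
  "Body size + Geographic range" = ln_div_time ~ ln_body + geo_range,
  "Body size x Class" = ln_div_time ~ ln_body * class,
  "Upper elevation limit x Class" = ln_div_time ~ upper_elevation * class,
  "Geographic range x Class" = ln_div_time ~ geo_range * class)

#' Fit and AICc-rank the 13 a-priori divergence-time models
#'
#' Gaussian linear models of ln divergence time on one to three
#' life-history predictors (the fixed model set of the analysis), ranked
#' by AICc with delta-AICc relative to the best model.  Rank-deficient
#' fits are flagged but do not stop the remaining models.  No
#' multiple-testing correction is applied across models.
#'
#' @param table a life-history data.frame (raw; it is passed through
#'   \code{\link{prepareDesign}}).
#' @param models optional named list of formulas overriding the default
#'   13-model set.
#' @return list with \code{ranking} (model, k, n, loglik, AICc, dAICc,
#'   r2, adjR2, flagged) and \code{fits} (named list of \code{lm}
#'   objects in ranking order).
#' @export
fitAndRank <- function(table, models = .GLM_MODELS) {
  d <- prepareDesign(table)
  n <- nrow(d)
  rows <- lapply(names(models), function(nm) {
    fit <- lm(models[[nm]], data = d)
    k <- length(coef(fit)) + 1L        # + residual variance
    flagged <- anyNA(coef(fit))
    ll <- as.numeric(logLik(fit))
    sm <- summary(fit)
    data.frame(model = nm, k = k, n = n, loglik = ll,
               AICc = aicc(ll, k, n), r2 = sm$r.squared,
               adjR2 = sm$adj.r.squared, flagged = flagged)
  })
  ranking <- do.call(rbind, rows)
  ord <- order(ranking$AICc)
  ranking <- ranking[ord, , drop = FALSE]
  ranking$dAICc <- ranking$AICc - ranking$AICc[1]
  rownames(ranking) <- NULL
  fits <- lapply(names(models)[ord], function(nm) lm(models[[nm]], data = d))
  names(fits) <- ranking$model
  list(ranking = ranking, fits = fits)
}

#' Coefficient table of a fitted model
#'
#' @param fit an \code{lm} object (e.g. from \code{\link{fitAndRank}}).
#' @return data.frame with term, estimate, t and p columns.
#' @export
coefTable <- function(fit) {
  cf <- summary(fit)$coefficients
  data.frame(term = rownames(cf), estimate = cf[, 1], t = cf[, 3],
             p = cf[, 4], row.names = NULL)
}

#' Descriptive group summaries of divergence times
#'
#' Arithmetic means of the untransformed divergence time (Ma) by
#' thermoregulation mode, and medians by taxonomic class.  Empty groups
#' are omitted with a warning.
#'
#' @param table life-history data.frame with \code{mean_div_time},
#'   \code{thermoregulation} and \code{class}.
#' @return list with \code{thermoMeans} and \code{classMedians} (named
#'   numerics).
#' @export
groupSummaries <- function(table) {
  if (nrow(table) == 0L) stop("empty table")
  thermo <- c("homeotherm", "poikilotherm")
  tm <- vapply(thermo, function(g) {
    x <- table$mean_div_time[table$thermoregulation == g]
    if (length(x) == 0L) { warning("empty group: ", g); NA_real_ }
    else mean(x)
  }, numeric(1))
  cls <- c("amphibian", "reptile", "bird", "mammal")
  cm <- vapply(cls, function(g) {
    x <- table$mean_div_time[table$class == g]
    if (length(x) == 0L) { warning("empty class: ", g); NA_real_ }
    else median(x)
  }, numeric(1))
  list(thermoMeans = tm[!is.na(tm)], classMedians = cm[!is.na(cm)])
}

#' Per-class correlation of divergence time with net divergence
#'
#' Pearson correlation between \code{mean_div_time} and \code{pi_net}
#' within each taxonomic class; classes with fewer than 3 complete pairs
#' are skipped with a warning.
#'
#' @param table life-history data.frame with a \code{pi_net} column.
#' @return named numeric vector of per-class r.
#' @export
corrAgePinet <- function(table) {
  if (!"pi_net" %in% names(table)) stop("table lacks a pi_net column")
  out <- c()
  for (g in unique(as.character(table$class))) {
    sub <- table[table$class == g &
                 complete.cases(table[, c("mean_div_time", "pi_net")]), ]
    if (nrow(sub) < 3L) {
      warning("class '", g, "' has < 3 complete pairs; skipped")
      next
    }
    out[g] <- cor(sub$mean_div_time, sub$pi_net)
  }
  out
}
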