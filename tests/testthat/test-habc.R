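# Hierarchical ABC: prior table, rejection step, regression adjustment,
# Bayes factors, end-to-end determinism.

smallDesign <- function(nt = 4, n = 5, L = 400)
  data.frame(n1 = rep(n, nt), n2 = rep(n, nt), L = rep(L, nt))

# hand-built PriorTable around given omega / stat values
toyPriorTable <- function(stats, omega = NULL, psi = NULL) {
  n <- nrow(stats)
  nt <- 2L
  if (is.null(omega)) omega <- runif(n)
  if (is.null(psi)) psi <- sample(1:nt, n, replace = TRUE)
  tab <- data.frame(psi = psi, omega = omega, eTau = runif(n) + 0.5,
                    tau_1 = runif(n), tau_2 = runif(n),
                    assign_1 = 1, assign_2 = 1)
  tab <- cbind(tab, stats)
  new("PriorTable", table = tab, nTaxa = nt,
      design = smallDesign(2), prior = unclass(priorSpec(5)),
      thetaRef = 0.01, statNames = colnames(stats))
}

test_that("prior table has the right shape and is seed-deterministic", {
  cfg <- abcConfig(nSims = 400, nAccept = 50)
  set.seed(1); p1 <- buildPriorTable(smallDesign(), priorSpec(5), cfg)
  set.seed(1); p2 <- buildPriorTable(smallDesign(), priorSpec(5), cfg)
  expect_equal(nrow(p1@table), 400)
  expect_identical(p1@table, p2@table)
  expect_true(all(p1@table$psi %in% 1:4))
  expect_true(all(p1@table$omega >= 0))
  expect_true(all(p1@table$omega[p1@table$psi == 1] == 0))
})

test_that("marginal Psi frequencies are uniform under the prior", {
  set.seed(2)
  pt <- buildPriorTable(smallDesign(nt = 5, n = 3, L = 100), priorSpec(5),
                        abcConfig(nSims = 20000, nAccept = 10))
  freq <- tabulate(pt@table$psi, 5) / 20000
  se <- sqrt(0.2 * 0.8 / 20000)
  expect_true(all(abs(freq - 0.2) < 3 * se))
})

test_that("rejection accepts exactly the nearest rows", {
  set.seed(3)
  stats <- as.data.frame(matrix(runif(5 * 3), 5,
                                dimnames = list(NULL, c("a", "b", "c"))))
  pt <- toyPriorTable(stats)
  obs <- unlist(stats[3, ])
  post <- rejectionSample(pt, obs, abcConfig(nSims = 5, nAccept = 1))
  expect_equal(post@accepted$index, 3L)     # zero-distance row accepted
  expect_equal(post@accepted$distance, 0)
  all5 <- rejectionSample(pt, obs, abcConfig(nSims = 5, nAccept = 5))
  expect_setequal(all5@accepted$index, 1:5)
  # hand-computed standardized distances give the same ranking
  sds <- vapply(stats, sd, numeric(1))
  d <- sqrt(colSums(((t(as.matrix(stats)) - obs) / sds)^2))
  for (k in 1:5) {
    pk <- rejectionSample(pt, obs, abcConfig(nSims = 5, nAccept = k))
    expect_equal(sort(pk@accepted$index), sort(order(d)[1:k]))
  }
  # Psi frequencies always sum to one
  expect_equal(sum(post@psiFreq), 1)
})

test_that("constant statistic columns are dropped with a warning", {
  set.seed(4)
  stats <- data.frame(a = runif(8), b = rep(0.5, 8), c = runif(8))
  pt <- toyPriorTable(stats)
  obs <- c(a = 0.5, b = 0.5, c = 0.5)
  expect_warning(post <- rejectionSample(pt, obs,
                                         abcConfig(nSims = 8, nAccept = 3)),
                 "constant")
  expect_equal(post@statNames, c("a", "c"))
})

test_that("regression adjustment handles degenerate and exact cases", {
  set.seed(5)
  # all accepted stats equal to the observed: fall back to raw values
  stats <- data.frame(a = rep(0.3, 12), b = rep(0.1, 12))
  pt <- toyPriorTable(stats)
  suppressWarnings({
    post <- rejectionSample(pt, c(a = 0.3, b = 0.1),
                            abcConfig(nSims = 12, nAccept = 12))
    adj <- regressionAdjust(post)
  })
  expect_equal(adj@accepted$omegaAdj, adj@accepted$omega)
  # parameters exactly linear in the statistics (on the ln scale used by
  # the adjustment): every adjusted value equals the fit at the observed
  set.seed(6)
  a <- runif(30); b <- runif(30)
  omega <- exp(1 + 2 * a - b) - 1e-6
  stats <- data.frame(a = a, b = b)
  pt2 <- toyPriorTable(stats, omega = omega)
  obs <- c(a = 0.5, b = 0.5)
  post2 <- rejectionSample(pt2, obs, abcConfig(nSims = 30, nAccept = 30))
  adj2 <- regressionAdjust(post2)
  expect_equal(adj2@accepted$omegaAdj,
               rep(exp(1 + 2 * 0.5 - 0.5) - 1e-6, 30), tolerance = 1e-8)
})

test_that("regression adjustment tends to sharpen E[tau] recovery", {
  # prior-predictive recovery: adjusted posterior median closer to the
  # truth than the raw one in a clear majority of seeded runs
  wins <- 0; n <- 30
  for (seed in seq_len(n)) {
    set.seed(seed + 700)
    sp <- syntheticSpec(4, samplesPerSide = c(5L, 5L),
                        locusLength = c(500L, 500L), psiTrue = 2,
                        pulseTimesTrue = c(0.5, 2.5), seed = seed + 700)
    d <- generateDataset(sp)
    obs <- summarizeDataset(d$alignments)
    pt <- buildPriorTable(smallDesign(4, 5, 500), priorSpec(5),
                          abcConfig(nSims = 1500, nAccept = 100))
    post <- rejectionSample(pt, obs$aggregate,
                            abcConfig(nSims = 1500, nAccept = 100))
    adj <- regressionAdjust(post)
    truthE <- d$truth$eTauTrue
    rawErr <- abs(median(post@accepted$eTau) - truthE)
    adjErr <- abs(median(adj@accepted$eTauAdj) - truthE)
    if (adjErr < rawErr) wins <- wins + 1
  }
  expect_gte(wins / n, 0.6)
})

test_that("Bayes factors follow the posterior/prior odds arithmetic", {
  set.seed(7)
  # engineered tails: 10 posterior omegas, 6 <= 0.5; prior half below
  stats <- data.frame(a = runif(10), b = runif(10))
  omegaPrior <- c(seq(0.05, 0.45, length.out = 5),
                  seq(0.55, 0.95, length.out = 5))
  pt <- toyPriorTable(stats, omega = omegaPrior)
  post <- rejectionSample(pt, c(a = 0.5, b = 0.5),
                          abcConfig(nSims = 10, nAccept = 10))
  post@accepted$omega <- c(rep(0.4, 6), rep(0.6, 4))
  bf <- bayesFactor(post, pt, 0.5)
  expect_equal(bf$bf01, (0.6 / 0.4) / (0.5 / 0.5))  # 1.5
  # p = q gives BF01 = 1
  post@accepted$omega <- omegaPrior
  expect_equal(bayesFactor(post, pt, 0.5)$bf01, 1)
  # hand-counted tails on another threshold
  bf2 <- bayesFactor(post, pt, 0.3)
  p <- mean(omegaPrior <= 0.3)
  expect_equal(bf2$bf01, (p / (1 - p)) / (p / (1 - p)))
  # empty posterior tail is reported as a bound
  post@accepted$omega <- rep(0.9, 10)
  bf3 <- bayesFactor(post, pt, 0.05)
  expect_equal(bf3$bound, "<")
  expect_equal(bf3$postP, 0)
})

test_that("Bayes-factor labels follow the >100 strong rule", {
  expect_match(interpretBF(0.006), "Strong support for M1")
  expect_match(interpretBF(150), "Strong support for M0")
  expect_equal(interpretBF(1), "No evidence")
  expect_match(interpretBF(2), "Anecdotal support for M0")
  expect_match(interpretBF(0.2), "Substantial support for M1")
})

test_that("posterior tail probability is non-decreasing in the threshold", {
  set.seed(8)
  sp <- syntheticSpec(4, samplesPerSide = c(5L, 5L),
                      locusLength = c(400L, 400L), psiTrue = 2,
                      pulseTimesTrue = c(0.4, 2), seed = 31)
  d <- generateDataset(sp)
  res <- runHABC(d$alignments, priorSpec(5),
                 abcConfig(nSims = 3000, nAccept = 200, seed = 31))
  ps <- vapply(c(0.01, 0.05, 0.2, 1), function(th)
    mean(res@posterior@accepted$omegaAdj <= th), numeric(1))
  expect_true(all(diff(ps) >= 0))
})

test_that("the full analysis is reproducible from its seed", {
  sp <- syntheticSpec(4, samplesPerSide = c(4L, 4L),
                      locusLength = c(300L, 300L), psiTrue = 1,
                      pulseTimesTrue = 1, seed = 9)
  d <- generateDataset(sp)
  cfg <- abcConfig(nSims = 1000, nAccept = 80, seed = 17)
  r1 <- runHABC(d$alignments, priorSpec(4), cfg)
  r2 <- runHABC(d$alignments, priorSpec(4), cfg)
  expect_identical(r1@posterior@accepted, r2@posterior@accepted)
  expect_identical(r1@bf, r2@bf)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  writeReport(r1, d1); writeReport(r2, d2)
  expect_identical(readBin(file.path(d1, "report.json"), "raw", 1e6),
                   readBin(file.path(d2, "report.json"), "raw", 1e6))
})
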