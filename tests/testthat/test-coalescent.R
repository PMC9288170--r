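# Coalescent simulator: hyperprior law, genealogy expectations,
# mutation-model behaviour.

test_that("hyperprior draws respect the pulse structure", {
  set.seed(11)
  pr <- priorSpec(10)
  d1 <- drawHyperparams(6, pr, psi = 1)
  expect_equal(d1@omega, 0)
  expect_equal(length(unique(d1@tauVector)), 1L)
  for (i in 1:500) {
    d <- drawHyperparams(6, pr)
    expect_true(d@psi >= 1 && d@psi <= 6)
    expect_setequal(unique(d@assignment), seq_len(d@psi))
    expect_equal(d@tauVector, d@pulseTimes[d@assignment])
    expect_gte(d@omega, 0)
  }
  expect_error(priorSpec(-1), "invalid prior")
  expect_error(drawHyperparams(1, pr), ">= 2")
})

test_that("prior Pr(Omega <= 0.05) matches an independent sampler", {
  nDraw <- 20000
  set.seed(21)
  mine <- vapply(seq_len(nDraw), function(i)
    drawHyperparams(8, priorSpec(10))@omega, numeric(1))
  set.seed(22)
  ora <- bruteOmegaPrior(nDraw, 8, 10)
  p1 <- mean(mine <= 0.05); p2 <- mean(ora <= 0.05)
  se <- sqrt(p2 * (1 - p2) / nDraw) * sqrt(2)
  expect_lt(abs(p1 - p2), 3 * se + 1e-12)
})

test_that("isolation holds before tau and Kingman limits after", {
  set.seed(31)
  # a single lineage per side cannot coalesce before tau
  t2 <- replicate(400, tmrca(simulateGenealogy(
    demographicParams(1, 1, 100, .01, .01, .01, 3))))
  expect_true(all(t2 >= 3))
  # tau = 0 with equal thetas collapses to one Kingman population
  tm <- replicate(3000, tmrca(simulateGenealogy(
    demographicParams(4, 4, 100, .01, .01, .01, 0))))
  expected <- 2 * (1 - 1 / 8)
  expect_lt(abs(mean(tm) - expected), 3 * sd(tm) / sqrt(3000))
})

test_that("genealogies are binary, ultrametric and correctly sized", {
  set.seed(32)
  for (i in 1:50) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    g <- simulateGenealogy(demographicParams(n1, n2, 100, .01, .02,
                                             .015, runif(1, 0, 3)))
    n <- n1 + n2
    expect_length(g@parent, 2L * n - 1L)
    expect_equal(sum(is.na(g@parent)), 1L)          # one root
    expect_true(all(g@nodeTime[seq_len(n)] == 0))   # tips at present
    # every internal node has exactly two children
    expect_true(all(tabulate(g@parent[!is.na(g@parent)],
                             2L * n - 1L)[(n + 1L):(2L * n - 1L)] == 2L))
  }
})

test_that("mean pi_net matches the closed-form finite-sites expectation", {
  # For a JC finite-sites pair separated for time T the expected
  # p-distance is 3/4 (1 - E[exp(-a T)]) with a = 4/3 thetaRef.  A
  # within-deme pair coalesces at rate lambda_j = thetaRef/theta_j until
  # tau and at rate lambda_A afterwards (censoring), so
  #   E[exp(-aT)] = lambda_j/(lambda_j+a) (1 - exp(-(lambda_j+a) tau))
  #                 + exp(-(lambda_j+a) tau) lambda_A/(lambda_A+a);
  # a cross-side pair cannot coalesce before tau, so
  #   E[exp(-aT)] = exp(-a tau) lambda_A/(lambda_A+a).
  # (first-order, with equal thetas: E[pi_w] = theta and
  #  E[pi_net] = thetaRef * tau)
  set.seed(41)
  tau <- 1.5; thr <- 0.01; th1 <- 0.012; th2 <- 0.008; thA <- 0.01
  st <- replicate(3000, simulateTaxonStats(
    demographicParams(6, 6, 1000, th1, th2, thA, tau), simScale(thr)))
  a <- 4 / 3 * thr
  lamA <- thr / thA
  ew <- function(th) {
    lam <- thr / th
    0.75 * (1 - lam / (lam + a) * (1 - exp(-(lam + a) * tau)) -
              exp(-(lam + a) * tau) * lamA / (lamA + a))
  }
  eb <- 0.75 * (1 - exp(-a * tau) * lamA / (lamA + a))
  pn <- st["pi_net", ]
  expect_lt(abs(mean(pn) - (eb - (ew(th1) + ew(th2)) / 2)),
            3 * sd(pn) / sqrt(length(pn)))
  pw <- st["pi_w1", ]
  expect_lt(abs(mean(pw) - ew(th1)), 3 * sd(pw) / sqrt(length(pw)))
  # and the first-order reading: pi_net tracks thetaRef * tau to ~5%
  expect_lt(abs(mean(pn) - thr * tau) / (thr * tau), 0.05)
})

test_that("segregating sites follow the Watterson expectation", {
  set.seed(42)
  st <- replicate(2500, simulateTaxonStats(
    demographicParams(4, 4, 1000, .01, .01, .01, 0), simScale(0.01)))
  s <- st["s", ]
  expected <- 0.01 * 1000 * sum(1 / (1:7))
  expect_lt(abs(mean(s) - expected), 3 * sd(s) / sqrt(length(s)))
})

test_that("mutation model behaves at its edges", {
  # zero branch lengths: all sequences identical
  g0 <- new("Genealogy", parent = c(3L, 3L, NA), nodeTime = c(0, 0, 0),
            n1 = 1L, n2 = 1L)
  par <- demographicParams(1, 1, 200, .01, .01, .01, 0)
  al <- mutateAlignment(g0, par)
  expect_equal(as.character(al[[1]]), as.character(al[[2]]))
  # HKY with kappa = 1 is JC: identical output under the same seed
  p2 <- demographicParams(3, 3, 500, .01, .01, .01, 1)
  set.seed(51); g <- simulateGenealogy(p2)
  set.seed(52); a1 <- mutateAlignment(g, p2, model = "JC")
  set.seed(52); a2 <- mutateAlignment(g, p2, model = "HKY", kappa = 1)
  expect_equal(as.character(a1), as.character(a2))
  # large kappa: transition differences dominate pairwise comparisons
  set.seed(53)
  ts <- 0; tv <- 0
  for (i in 1:40) {
    gg <- simulateGenealogy(p2)
    aa <- as.matrix(mutateAlignment(gg, p2, model = "HKY", kappa = 50))
    d <- aa[1, ] != aa[2, ]
    pair <- paste0(pmin(aa[1, d], aa[2, d]), pmax(aa[1, d], aa[2, d]))
    ts <- ts + sum(pair %in% c("AG", "CT"))
    tv <- tv + sum(!(pair %in% c("AG", "CT")))
  }
  expect_gt(ts, 5 * tv)
})

test_that("expected net divergence is monotone in tau", {
  taus <- c(0.25, 1, 2.5)
  means <- vapply(seq_along(taus), function(i) {
    set.seed(61)   # common random numbers across the tau grid
    mean(replicate(800, simulateTaxonStats(
      demographicParams(5, 5, 800, .01, .01, .01, taus[i]),
      simScale(0.01))[["pi_net"]]))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("per-taxon seeds make alignments stable under reordering", {
  set.seed(71)
  pr <- priorSpec(3)
  hyper <- drawHyperparams(4, pr,
                           design = data.frame(n1 = 4, n2 = 4, L = 300))
  hyper@taxonSeeds <- sample.int(1e6, 4)
  al <- simulateTaxonSet(hyper, simScale(0.01))
  perm <- c(3, 1, 4, 2)
  hp <- hyper
  hp@params <- hyper@params[perm, ]
  hp@assignment <- hyper@assignment[perm]
  hp@tauVector <- hyper@tauVector[perm]
  hp@taxonSeeds <- hyper@taxonSeeds[perm]
  al2 <- simulateTaxonSet(hp, simScale(0.01))
  for (k in seq_along(perm))
    expect_equal(unname(as.character(eastSeqs(al2[[k]]))),
                 unname(as.character(eastSeqs(al[[perm[k]]]))))
})
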