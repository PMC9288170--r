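# Summary statistics: closed-form toys and brute-force enumeration.

test_that("withinDiversity matches simple closed forms", {
  s <- c(paste(rep("A", 100), collapse = ""),
         paste(c(rep("A", 98), "C", "G"), collapse = ""))
  expect_equal(withinDiversity(s), 0.02)
  expect_equal(withinDiversity(c("ACGT", "ACGT", "ACGT")), 0)
  expect_error(withinDiversity("ACGT"), "insufficient")
})

test_that("betweenAndNet satisfies the net-divergence identity", {
  # construct pi_b = 0.05, pi_w1 = pi_w2 = 0.02 exactly on 100 sites:
  # within each side two sequences differing at 2 sites
  base <- rep("A", 100)
  e1 <- base; e2 <- base; e2[1:2] <- "C"
  w1 <- base; w1[50:54] <- "T"
  w2 <- w1; w2[60:61] <- "G"
  # compute expected by hand below via brute force instead of arithmetic
  me <- rbind(e1, e2); mw <- rbind(w1, w2)
  got <- betweenAndNet(me, mw)
  pib <- bruteBetween(me, mw)
  expect_equal(unname(got["pi_b"]), pib)
  expect_equal(unname(got["pi_net"]),
               pib - (brutePi(me) + brutePi(mw)) / 2)
  # identical monomorphic pools on both sides: net divergence is zero
  same <- c("ACGTACGT", "ACGTACGT")
  got2 <- betweenAndNet(same, same)
  expect_equal(unname(got2["pi_net"]), 0)
  # duplicating a polymorphic pool across sides gives exactly -pi_w/2:
  # the cross-side mean includes the zero self-distances
  poly <- c("ACGTACGT", "ACCTACGA")
  got3 <- betweenAndNet(poly, poly)
  expect_equal(unname(got3["pi_net"]), -withinDiversity(poly) / 2)
  expect_error(betweenAndNet(character(0), "ACGT"), "insufficient")
})

test_that("wattersonTheta matches its closed form", {
  # 4 sequences, 100 sites, 5 polymorphic columns, no missing data
  m <- matrix("A", 4, 100)
  m[1, 1:5] <- "C"
  got <- wattersonTheta(m)
  expect_equal(unname(got["s"]), 5)
  expect_equal(unname(got["theta_w"]), 5 / (100 * (1 + 1/2 + 1/3)))
  expect_equal(unname(wattersonTheta(matrix("G", 3, 40))),
               c(0, 0), ignore_attr = TRUE)
})

test_that("estimators agree exactly with brute-force enumeration", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(2:6, 1); L <- sample(5:50, 1)
    m <- randomToy(n, L)
    bp <- brutePi(m)
    if (!is.na(bp)) expect_equal(withinDiversity(m), bp)
    bw <- bruteWatterson(m)
    expect_equal(wattersonTheta(m), bw)
    if (n >= 4) {
      k <- if (n == 4L) 2L else sample(2:(n - 2), 1)
      me <- m[seq_len(k), , drop = FALSE]
      mw <- m[(k + 1):n, , drop = FALSE]
      got <- betweenAndNet(me, mw)
      expect_equal(unname(got["pi_b"]), bruteBetween(me, mw))
    }
  }
})

test_that("statistics are invariant to column and sequence order", {
  set.seed(5)
  m <- randomToy(5, 30)
  pc <- sample(ncol(m)); pr <- sample(nrow(m))
  expect_equal(withinDiversity(m), withinDiversity(m[pr, pc]))
  expect_equal(wattersonTheta(m), wattersonTheta(m[, pc]))
})

test_that("summarizeDataset aggregates are permutation invariant", {
  set.seed(8)
  d <- generateDataset(syntheticSpec(4, psiTrue = 2,
                                     pulseTimesTrue = c(0.5, 2),
                                     locusLength = c(300L, 400L)))
  s1 <- summarizeDataset(d$alignments)
  s2 <- summarizeDataset(rev(d$alignments))
  expect_equal(s1$aggregate, s2$aggregate)
  expect_equal(s1$perTaxon$taxon, rev(s2$perTaxon$taxon))
  # hand-check the aggregate means on two taxa
  two <- d$alignments[1:2]
  st <- summarizeDataset(two)
  expect_equal(unname(st$aggregate["mean_pinet"]),
               mean(st$perTaxon$pi_net))
  # single taxon: all variance terms zero
  one <- summarizeDataset(d$alignments[1])
  expect_equal(unname(one$aggregate[c("var_pib", "var_piw", "var_pinet",
                                      "var_thw")]),
               rep(0, 4))
})

test_that("fast simulated statistics agree with the sequence pathway", {
  # the ABC fast path and sequences + R estimators are two routes to the
  # same distribution; their means must agree to Monte-Carlo error
  par <- demographicParams(5, 5, 400, 0.01, 0.01, 0.01, 1)
  hyper <- new("HyperDraw", psi = 1L, pulseTimes = 1,
               assignment = rep(1L, 2), tauVector = c(1, 1),
               omega = 0, eTau = 1,
               params = data.frame(n1 = 5L, n2 = 5L, L = 400L,
                                   theta1 = 0.01, theta2 = 0.01,
                                   thetaA = 0.01, tau = 1)[c(1, 1), ],
               taxonSeeds = integer(0))
  set.seed(301)
  fast <- replicate(250, simulateTaxonStats(par, simScale(0.01)))
  set.seed(302)
  slow <- replicate(125, {
    al <- simulateTaxonSet(hyper, simScale(0.01))
    s <- summarizeDataset(al)$perTaxon
    c(pi_net = mean(s$pi_net), s = mean(s$s))
  })
  seDiff <- sqrt(sd(fast["pi_net", ])^2 / 250 + sd(slow["pi_net", ])^2 / 125)
  expect_lt(abs(mean(fast["pi_net", ]) - mean(slow["pi_net", ])),
            4 * seDiff)
  seS <- sqrt(sd(fast["s", ])^2 / 250 + sd(slow["s", ])^2 / 125)
  expect_lt(abs(mean(fast["s", ]) - mean(slow["s", ])), 4 * seS)
})
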