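# divPulse

Hierarchical approximate Bayesian computation (hABC) for comparative
phylogeography: did co-distributed taxon pairs split by a shared
barrier diverge in one synchronous pulse, or asynchronously?

`divPulse` is for phylogeographers with per-taxon mtDNA alignments
whose samples fall on two sides of a barrier (e.g. east and west of a
mountain chain).  It simulates two-population isolation coalescent
genealogies under a divergence-pulse hyperprior, compares simulated and
observed population-genetic summary statistics by ABC rejection with
local-linear regression adjustment, and reports the posterior of the
hyperparameters together with threshold Bayes factors.  Supporting
stages cover gene-tree screening, data-hygiene filters, conversion of
coalescent times to years, and AICc-ranked general linear models of
divergence time on life-history predictors.

## The model in brief

For `n` taxon pairs the hyperprior draws

- **Ψ** — the number of divergence pulses, uniform on `{1..n}`
  (Ψ = 1 is strict synchronous vicariance);
- pulse times τ ~ Uniform(0, τ_max], with each taxon assigned to a
  pulse (uniform over surjections);
- per-taxon θ₁, θ₂, θ_A (west, east, ancestral demes) iid uniform.

Dispersion of divergence times is summarised by
**Ω = Var(τ)/E(τ)** (population variance); Ω = 0 iff Ψ = 1.  Each
taxon evolves under a two-population isolation coalescent with
finite-sites JC/HKY mutation.  Observed and simulated data are reduced
to the cross-taxon mean and variance of (π_b, π_w1 + π_w2, π_net,
θ_W), where π_net = π_b − (π_w1 + π_w2)/2 is Nei's net divergence.
Synchronous vs asynchronous divergence is compared with
**BF₀₁ = [p/(1−p)] / [q/(1−q)]**, `p` and `q` the posterior and prior
probabilities of Ω ≤ threshold (thresholds 0.01, 0.025, 0.05, 0.1).
Coalescent divergence times convert to calendar time via
**t = τ·θ_Ave/μ** generations (`tauToYears()`), and
π_net/(2·rate) gives a strict-clock moment age (`momentSplitAge()`).

## Worked example

Generate a synthetic eight-taxon dataset whose true history has two
pulses (τ = 0.5 and 2.5, true Ω = 0.667), then try to recover it:

```r
library(divPulse)

sp <- syntheticSpec(taxonCount = 8, samplesPerSide = c(8L, 8L),
                    locusLength = c(1000L, 1000L),
                    psiTrue = 2, pulseTimesTrue = c(0.5, 2.5), seed = 7)
d <- generateDataset(sp)

res <- runHABC(d$alignments, priorSpec(5),
               abcConfig(nSims = 20000, nAccept = 200, seed = 7))
res
```

```
HABCResult over 8 taxon pairs
PosteriorSample: 200 accepted draws (regression-adjusted)
  Psi mode: 6
  median Omega: 1.332  median E[tau]: 1.75
Bayes factors (BF01, synchronous vs asynchronous):
 threshold       bf01                                  label
     0.010 0.03038802 Moderate to very strong support for M1
     0.025 0.02730119 Moderate to very strong support for M1
     0.050 0.02391312 Moderate to very strong support for M1
     0.100 0.03943803 Moderate to very strong support for M1
```

The Bayes factors at every Ω threshold are far below 1, rejecting the
synchronous model M0 — correct, since the truth was asynchronous.  The
posterior mode of Ψ overestimates the true pulse count (6 vs 2), which
is typical for single-locus data: the Ψ posterior is diffuse and the
thresholded Ω test is the calibrated quantity.  The posterior median
E[τ] of 1.75 sits near the true mean divergence time, and
`pulseTable(res)` lists which taxa co-diverge at the posterior Ψ mode
with pulse-time medians and 95% intervals.

Screening a gene tree before analysis, and converting a coalescent time:

```r
tr <- ape::read.tree(text = "(E1,(E2,(W1,W2)));")
classifyTopology(tr, c(E1 = "E", E2 = "E", W1 = "W", W2 = "W"))
#> [1] "paraphyly"

tauToYears(2, timescaleConfig(mu = 1e-8, g = 1, thetaAve = 0.005))
#> [1] 1e+06
```

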