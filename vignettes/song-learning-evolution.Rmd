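---
title: "Models and methods for song-learning-window evolution"
author: "songphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for song-learning-window evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`songphylo` implements a phylogenetic comparative pipeline for studying
how the song-learning window — whether a songbird crystallizes its song
around maturity or keeps modifying it as an adult — evolves, and how it
interacts with song characteristics and mating behavior. This vignette
documents the models, the tunable parameters, the numerical choices, and
the limits of what the package's simulation-based tests can show.

## Trait codings

The learning window is coded three ways, at increasing resolution:

* **binary** — `stable` vs `plastic`: a species is song-plastic when
  males modify their syllable repertoires after the first breeding season
  ends;
* **ternary** — `early` (stabilizes before the first breeding season),
  `delayed` (modifies during but not after it), `plastic`;
* **continuous** — years of plasticity on [0, 2]: early species carry
  their reported stabilization age (1.0, flagged, when no age is
  reported), delayed species 1.33 (the end of the first breeding season),
  plastic species 2.0 (observations beyond the second season are too
  scarce to extend the scale). Species with delayed plumage maturation
  that stop modifying before their second breeding season are coded
  song-stable with 2.0 years.

Seven song traits are analyzed on the natural-log scale: syllable
repertoire, song repertoire, syllables per song, song duration (s),
inter-song interval (s), and the derived performance metrics
`rate = 60/(duration + interval)` (songs/min) and
`continuity = duration/(duration + interval)`. Multiple literature
estimates per species are aggregated by their median (min and max are
sensitivity modes); a missing syllable repertoire is imputed from
syllables per song when the song repertoire is exactly one song. Mating
behavior is binarized at 5% of males with more than one social mate
(polygyny) and at 10% extra-pair young or nests (high EPP). An optional
override recodes a designated "open-ended improviser" species as
song-stable for sensitivity analysis.

## Discrete-trait models

Learning states evolve under a continuous-time Markov (Mk) model with
generator $Q$; the likelihood of tip states is computed by Felsenstein
pruning (the inner loop is C++, with one eigendecomposition of $Q$ per
evaluation and a scaling-and-squaring fallback for ill-conditioned
eigenbases). The equal-rates (ER) model has one transition rate; the
all-rates-different (ARD) model one per ordered state pair; they are
compared by a likelihood-ratio test with df equal to the difference in
free rates (1 for a binary trait). Rates are optimized on the log scale
with multi-start (default 10 restarts drawn log-uniformly over
$[10^{-4}, 10^2]$ per unit tree depth); the root prior is uniform by
default and can be set to the fitted stationary distribution.

Stochastic character maps are drawn exactly: node states by
forward-backward sampling from their joint conditional distribution given
the tips, then branch paths conditioned on endpoint states by
uniformization (number of latent jumps from its exact conditional
distribution, jump chain sampled with powers of the uniformized kernel,
jump times as uniform order statistics; a bounded retry falls back to
resampling the map's node states). The minimum total transition count
over an ensemble is reported as the most parsimonious history; it is
bounded below by the Fitch small-parsimony count, which the sampler
attains on clear-signal data.

A known small-sample property worth flagging: the ER-vs-ARD
likelihood-ratio test is mildly anticonservative at realistic tree sizes
(empirical size roughly 6–12% at a nominal 5% across 80–500 tips; the
statistics agree with independent reference implementations to numerical
precision, so this is the method, not the optimizer). Interpret marginal
ER/ARD p-values accordingly.

## Continuous-trait models

Under Brownian motion the tip covariance is $\sigma^2 C$ with $C$ the
shared root-to-tip path lengths. The single-rate ML fit is closed-form
(GLS phylogenetic mean; $\hat\sigma^2$ with the ML $1/n$ denominator).
The state-dependent ("Brownie") model replaces $\sigma^2 C$ with
$\sum_r \sigma_r^2 C_r$, where $C_r$ accumulates shared branch length
painted in regime $r$ by a stochastic map; the first regime's rate and
the root are profiled analytically and the remaining log rate-ratios
optimized (Brent for two regimes, Nelder-Mead above). Because the painting
is itself uncertain, the test fits the multi-rate model on every map of an
ensemble (1,300 at paper scale; 100 in the fast profile) and refers
$2(\overline{LL}_{multi} - LL_{one})$ to $\chi^2(k-1)$, where the
single-rate likelihood does not depend on the painting. Regime groupings
support stable/plastic, early/delayed/plastic, and shorter/longer
learning (early vs delayed+plastic); a regime with zero mapped branch
length is dropped with a warning.

The phylogenetic ANOVA keeps the classical F statistic but simulates its
null distribution: Brownian datasets on the study tree at the fitted rate,
p computed with the add-one estimator $(1 + \#\{F_{sim} \ge F_{obs}\}) /
(n_{sim} + 1)$ (default $n_{sim} = 1000$), so p is never exactly zero.
Post-hoc pairwise comparisons use Welch-style t statistics against the
same simulated null, Holm-adjusted within the post-hoc family.

PGLS with Pagel's lambda multiplies the off-diagonal elements of the
phylogenetic covariance by $\lambda$ and profiles $\lambda$ by ML over
$[0, \lambda_{max}]$, where $\lambda_{max}$ is the largest value keeping
the matrix positive definite — deliberately not clamped at 1, since
real fits can sit slightly above it. The profile uses a 64-point grid
refined by golden-section search; whether the optimum is interior or at a
boundary is reported. The slope test is $t = \hat\beta/SE$ with $n - 2$
df, with the SE on the unbiased residual-variance scale (this matches
`nlme::gls` with a fixed `corPagel` structure under ML).

The Holm-Bonferroni correction orders the $m$ p-values of a test family
and compares rank $i$ against $\alpha/(m - i + 1)$ (for seven traits at
$\alpha = 0.05$: 0.0071, 0.0083, 0.01, 0.0125, 0.0167, 0.025, 0.05).
The pipeline applies the seven-trait ladder identically across the
binary, ternary and continuous schemes, even when fewer than seven traits
have enough data in a scheme — the published ternary tables use the
seven-test thresholds for three tests, and the package follows that
declared-family convention (the `family_size` argument of `holm()` makes
it explicit).

The sister-pair rate scan is a deliberately simple check that trait
magnitude does not itself drive evolutionary rate: for every cherry the
local rate is proxied by the squared contrast standardized by the summed
branch lengths, $(x_1 - x_2)^2/(t_1 + t_2)$, the size by the pair mean,
and a Spearman correlation across pairs is permutation-tested. The
statistic is this package's interpretation of a one-sentence procedure;
other contrasts-based formulations are possible.

## Correlated evolution and the threshold sweep

Pagel's test compares two models for a pair of binary traits on the
combined state space $\{00, 01, 10, 11\}$: a dependent model with 8 free
transition rates (each trait's gain and loss may depend on the other
trait's state; simultaneous changes of both traits are structural zeros)
and an independent model with 4 (nested by four equality constraints,
so its likelihood factorizes into two 2-state chains). The LR statistic
is referred to $\chi^2(4)$. Each "run" is one random-restart ML attempt
for both models; the dependent optimization additionally starts from the
fitted independent rates, which enforces the nesting inequality on every
run, and the run-to-run scatter of p-values emulates the optimizer
multimodality that repeated runs of the standard tools show. Only the
maximum-likelihood mode is implemented.

Continuous traits enter through the threshold sweep: every unique
observed trait value becomes the threshold splitting species into low and
high (strictly greater = high, so an observed threshold never empties the
low class; a threshold that empties a class is skipped, not an error),
and the test is repeated a configured number of times per threshold
(paper scale 100) with restart seeds derived from threshold and run
indices — never from row order, so permuting the input table changes
nothing. Thresholds are then binned by position among the sorted unique
values into 2–5 contiguous bins (default 3; remainders go to the lower
bins), and each bin reports the mean of each of the 8 rates with a
percentile-bootstrap 95% CI (1,000 resamples; the CI method of the
original figures is unstated) and the mean per-threshold percentage of
runs significant at p < 0.05. Extreme thresholds leave some combined
states unobserved, making some rates unidentifiable (the likelihood is
flat upward in them); fitted rates are therefore capped at $10^3$ per
unit branch length so bin averages stay interpretable — arrows that hit
the cap mean "fast", not a measured value.

## The synthetic-data generator

The generator is a pure function of a configuration and its seed, and its
defaults define the conditions every calibration and planted-structure
test runs under:

* a Yule tree with 67 tips rescaled to unit depth, cut at the shallowest
  level yielding at least 24 clades to assign family labels;
* a binary learning state under a 2-state ER process at rate 1.0 per unit
  depth — about 15 true transitions on the default tree, the scale of
  the published parsimony count (14); stable species are subdivided into
  early (1/3) and delayed (2/3) independently of phylogeny, with a 12%
  chance of lacking the ternary coding (leaving ≈ 59 of 67 codable);
  continuous years are drawn uniform on [0.5, 1.0] for early, fixed at
  1.33 and 2.0 for delayed and plastic;
* five raw song traits under Brownian motion on the log scale with
  $\sigma^2 = 1.0$ per unit depth in both states, plus a state-dependent
  *drift* planting the published group-mean targets (ln syllable
  repertoire ≈ 1.88 stable vs 3.95 plastic, and the corresponding pairs
  for the other traits). The drift accrues per unit time spent in each
  state, so the group difference builds gradually along song-plastic
  lineages — directional evolution — rather than jumping at the tips;
  since state mixing along a unit path attenuates the realized contrast,
  drift levels are the inverse of the analytic mixing matrix
  ($f(q) = 1/2 + (1 - e^{-2q})/(4q)$ is the expected fraction of a
  tip's path spent in its current state) applied to the targets. A
  tip-jump offset mode also exists (`state_offsets`) but is not used by
  the dataset generator: a jump at recently-transitioned tips reads as
  regime-dependent *rate* to the Brownie test, which would contradict the
  planted equal-rates design. With these defaults the realized
  within-group SD is ≈ 1.2, the order implied by the published F and
  group means, and the planted pattern — phylogenetic ANOVA significant
  for repertoires, Brownie non-significant — holds in the large majority
  of generated datasets (27–28 of 30 in the design scan);
* per-study raw values (1 or 3 studies) whose median reproduces the
  planted value exactly; duration and interval columns regenerate rate
  and continuity through their defining formulas;
* a (polygyny, high-EPP) pair under a moderately dependent 4-state chain,
  emitted as fractions consistent with the 5%/10% classification
  thresholds, with 15% / 40% missingness.

What the generator does *not* emulate: real family taxonomy or tree
shape, literature measurement error structure, correlated missingness,
or any feedback from trait values onto the learning-state process (the
dependence the sweep detects is the correlation induced by
state-dependent drift, not an explicit trait-dependent generator). A
passing suite therefore shows the pipeline's statistics behave correctly
under their own model assumptions — not that those assumptions hold for
any particular empirical dataset.

## Orchestration, seeds, and problem sizes

`run_full_analysis()` executes the configured stages from one master
seed; every stage derives its own stream by hashing a stable stage
identifier with the seed, so adding a stage never perturbs the others and
identical configurations reproduce outputs bit for bit. The fast profile
(100 maps, 200 ANOVA simulations, 10 runs per threshold, 50 mating runs)
exists for interactive use and the test suite; the full profile matches
the published settings (10,000 maps for transition counting, 1,300
Brownie maps, 1,000 simulations, 100 runs per threshold, 1,000 mating
runs). The jackknife driver re-runs scoped analyses with each family of
at least four species (or each designated species) left out, re-derives
unique sweep thresholds within each subset, runs sweeps at 20 runs per
threshold, and flags significance flips; a leave-out that empties a
learning group is marked inapplicable rather than failing.

The test suite's simulation studies use reduced problem sizes chosen to
keep the full suite in the tens of minutes on one core: calibration at
50–64 tips with 200–300 replicates and 50-map ensembles, recovery at
200–300 tips with 50 replicates, and planted-structure checks on the
67-species default dataset with 2 runs per threshold. The statistical
properties asserted (size within ±0.03 of 5%, ratio recovery within
[2, 8], profile-CI coverage ≥ 90%) are scale-free claims; the sizes only
control Monte-Carlo noise.

## Known limitations

* The ER/ARD likelihood-ratio test's mild anticonservativeness (above).
* The Brownie ensemble test treats the map ensemble as fixed when
  averaging log-likelihoods; uncertainty in the fitted Mk rates is not
  propagated.
* Lambda-PGLS profiles a single lambda for the residuals; no
  measurement-error term is modelled.
* The threshold sweep's run-to-run variability is an optimizer-restart
  emulation of the repeated-runs protocol of the standard tools; it is
  not a posterior over rates.
* No Ornstein–Uhlenbeck or trend models for continuous traits, no hidden
  rates or Bayesian MCMC for discrete ones, and no tree inference — the
  phylogeny is taken as given, without rescaling, and need not be
  ultrametric.
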