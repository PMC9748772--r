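---
title: "Models and methods in ratchetphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ratchetphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ratchetphy implements the comparative-phylogenetics toolchain used to ask
whether a discrete foraging niche — diving, in waterbirds — evolves
repeatedly and irreversibly, whether it changes diversification, and
whether it drags a continuous trait (log10 body mass) toward new optima.
This vignette is the package's own account of the models, the defaults, the
numerical choices, and what the synthetic-data tests do and do not show.

## Discrete niche evolution: constrained Mk models

A niche with `k` states evolves along the tree as a continuous-time Markov
chain with rate matrix `Q` (rates per Myr; branch lengths are Myr
everywhere, no unit conversion anywhere else). Model variants are encoded
as integer *patterns* on the off-diagonal of `Q`: entries fixed at zero,
and classes of entries sharing one free rate. The two-state battery is
`ER`, `ARD`, `NR`; the four-state battery is `ER`, `SYM`, `ARD`,
`NR-ER`, `NR-SYM`, `NR-ARD`, `NR-ALL`, with free-parameter counts
1, 6, 12, 1, 6, 9, 3. The `NR` ("no reversion") family fixes every
diving-to-non-diving rate at zero — the irreversibility hypothesis as a
likelihood constraint; `NR-ALL` additionally forbids transitions between
diving modes, so the only free rates are the three acquisition rates.

The likelihood is Felsenstein pruning with per-branch transition
probabilities `P(t) = exp(Qt)`. The matrix exponential uses
scaling-and-squaring (Armadillo's `expmat`) rather than eigendecomposition
because no-reversion matrices have zero rows and are defective-prone.
Fitting maximizes over log rates with box bounds `[1e-9, 1e3]` per Myr,
using `nlminb` from one data-informed start (roughly `k` changes over the
whole tree length) plus log-uniform restarts (default 10); constrained Mk
surfaces are multimodal often enough that single-start fits are not
trustworthy. The root prior defaults to equal (`1/k`) — the common default
of discrete-trait fitters — with stationary and fixed options exposed; for
an absorbing no-reversion process the stationary prior puts all mass on
diving states, which is rarely what one wants at the root, and this is why
equal is the default rather than stationary.

Degenerate input: a constant tip trait drives every rate to the lower
bound and the fit is returned flagged (`diagnostics$constant_trait`), with
`logL = log(pi_root)`.

## Stochastic character mapping

Mapping is empirical Bayes: `Q` is fixed at its MLE (the workflow fits,
then simulates), and histories are drawn from `P(history | tips, Q)`.
A backward pruning pass stores per-node partial likelihoods; node states
are then sampled root-down from their conditional distributions; branch
interiors are endpoint-conditioned CTMC paths, sampled by forward
rejection (30 attempts) with an exact uniformization fallback, so no
branch is ever silently dropped. Virtual jumps from uniformization are
merged before segments are recorded, so adjacent segments always differ in
state.

Summaries over `n` maps (default 100) report the per-ordered-pair mean
transition count, a 95% highest-posterior-density set of the integer count
distribution — built by greedy inclusion of the highest-frequency counts
until 95% mass, ties included, then forced to cover the sample median —
and node posterior state frequencies (the pie charts of ancestral-state
figures). "Independent transitions" is the total number of state-change
events per history, averaged; the unrounded mean is reported and rounding
is left to presentation.

## Tip speciation rates and phylogenetic ANOVA

`DR_i` is the inverse of the equal-splits measure
`ES_i = sum_j l_j (1/2)^(j-1)`, with `j = 1` the tip's own branch; a root
edge present in a file is excluded (paths end at the root node). The
implementation is a single preorder pass whose contract is identical to
the per-tip path definition (tested against it). DR values are analyzed
untransformed; a log-transform flag is deliberately absent from the
ANOVA's defaults because group means and medians of raw DR are the
quantities of interest here.

The phylogenetic ANOVA simulates its null: `nsim` (default 1000) Brownian
datasets on the tree, rate set to the mean squared phylogenetically
independent contrast of the data (polytomies are resolved with zero-length
branches for the contrasts), F computed for each, and
`p = (1 + #{F_sim >= F_obs}) / (nsim + 1)` — the +1/+1 correction keeps
Monte-Carlo p values off exact zero. Pairwise t statistics are treated
identically and Holm-corrected across all pairs. On a star tree the BM
null is iid and the simulation p agrees with the F-distribution p up to
Monte-Carlo error — one of the calibration tests.

## State-dependent diversification

The BiSSE/HiSSE family is implemented over *compound states* (observed
state 0/1 crossed with hidden classes A, B, ...). Along every branch the
standard D/E ordinary differential equations are integrated tipward to
rootward with an adaptive Cash-Karp Runge-Kutta (defaults rtol `1e-8`,
atol `1e-10`; fits use `1e-7`/`1e-9`), daughters combine with the
regime's speciation rate, and per-branch rescaling guards underflow. The
root applies survival conditioning (`lambda (1 - E)^2`) and, by default,
weights each regime by its conditional likelihood (the common default of
hidden-state SSE implementations); equal weights and a fixed prior are
exposed, and the test suite exploits the fact that *linear* root
weightings make the likelihood factorize exactly into (birth-death) x
(Mk) when rates are state-independent.

The seven scenarios and their diversification regime counts: dull null
(1), BiSSE (2), BiSSE null / CID-2 (2), HiSSE full (4), hidden state on
non-diving only (3), on diving only (3), HiSSE null / CID-4 (4). Each
regime is parameterized by turnover `tau = lambda + mu` and extinction
fraction `eps = mu / lambda`, both per regime; optimization is over
`log tau`, `log eps` and log transition rates with 8 restarts by default.
Observed-state transitions get one free rate per direction *shared across
hidden classes*, hidden-state flips share a single symmetric rate, and
dual (simultaneous observed + hidden) transitions are disallowed: with
hidden-state transitions constrained to be equal, sharing the observed
rates across classes is the minimal structure that keeps CID-4
identifiable at desk scale. In the three-regime models the unhidden
observed state exchanges with both hidden classes of the other state at
the per-direction rate. Tip regime-assignment probabilities clamp one tip
at a time to each compatible compound state and renormalize the resulting
full-tree likelihoods.

## Continuous traits on painted trees

The model family is BM1, OU1, EB, Trend (regime-independent) and BMS,
OUM, OUMA, OUMV, OUMVA (regime-dependent on a painted tree), with the
usual sharing structure: OUM shares `alpha` and `sigma^2` across regimes,
OUMA shares `sigma^2`, OUMV shares `alpha`, OUMVA shares nothing.
Parameter counts follow that structure (e.g. 3m for OUMVA with m
regimes). The Gaussian structure is assembled segment-by-segment along
every root-to-tip path in one preorder pass: integrated selection
`A = int alpha dt`, accumulated variance with attenuation, Hansen-type
optimum weights, and the root-value coefficient. Covariances are
`V[mrca] * exp(-(A_i - A_mrca) - (A_j - A_mrca))`, which reduces to the
familiar forms for single-regime OU and BM and handles per-regime `alpha`
(OUMA/OUMVA) without special cases. `expm1` is used for `1 - e^(-x)`
so the OU likelihood converges cleanly to BM as `alpha -> 0` (tested at
`alpha = 1e-12`).

Fitting profiles everything linear: optima (and root value / trend drift)
by generalized least squares, the overall variance scale analytically;
only `alpha` values, relative variance weights and the EB exponent are
optimized numerically. The root value for OU models is set to the root
regime's optimum (a stationarity-flavoured assumption, and the common
default of multi-regime OU fitters); a free root value is available via
`params$x0`. EB's exponent is constrained negative with magnitude at most
`10 / tree depth`; Trend on an ultrametric tree is flagged as weakly
identified (warning, not error — the drift column is collinear with the
intercept and GLS handles the rank deficiency). Half-life is
`log(2)/alpha`, infinite at `alpha = 0`; unrounded values are reported.

The 14-model protocol fits the four regime-independent models once and
the five regime-dependent models on each of the two-state and four-state
paintings; a painting with flightless taxa as a third regime adds five
more rows when supplied. Regime-dependent fits default to a single
painting (`m = 1`): the sampled history whose node states score highest
against the marginal node posteriors, a maximum-a-posteriori-flavoured
representative. Fitting on each of several sampled paintings and
averaging is supported simply by calling `fitCont` per painting; the
default stays at one because averaging conventions differ between studies
and hiding one behind a default would be less transparent than exposing
the choice.

## Model selection

Every battery is ranked by `AIC = -2 log L + 2K`, delta-AIC against the
best model, and Akaike weights computed from delta values (never raw
AICs; at 727 tips AICs are in the thousands and exponentiating them
overflows). Support bands: substantial (delta < 2), minimal (2-7), none
(> 7). No small-sample correction is applied anywhere — plain AIC is the
protocol. Ties are broken by fewer parameters, then name.

## Synthetic data and the waterbird fixture

The generators exist so that every stage is testable with known truths
and no downloads. `simulateTree` grows a constant-rate birth-death tree
forward from a crown pair and stops when the living lineage count first
reaches the target, extending all tips by the exponential sojourn at that
count ("simple sampling" stop). This is the classic quick conditioning
scheme; it has a slight known bias relative to sampling uniformly over
the sojourn interval, which is irrelevant at the tolerance of every test
that uses it but worth naming. Crown death or wrong final counts are
rejected. `simulateDiscrete` runs the forward CTMC and keeps the full
true painting; `simulateSse` grows tree and binary state jointly with
state-dependent rates; `simulateContinuous` samples segment-wise exact
Gaussian transitions.

The fixture emulates the study system: 727 tips (birth 0.1, death 0.02
per Myr, giving crown ages near 70 Myr), a four-state niche evolved under
`NR-ALL` at the published acquisition-rate estimates, log10 mass under
OUMVA at the published optima, selection strengths and variances, and
diet / IUCN / flightless columns from fixed plausible marginals (about
22% threatened; flightless concentrated in wing divers). Tip class sizes
are conditioned to exactly 491/130/61/45: histories are resampled until
every diving class lands between half its target and the target, then
under-sized classes are topped up by adding one late acquisition (within
the last 5 Myr) on the terminal branch of a random non-diving tip. Under
a no-reversion process a non-diving tip's entire root path is non-diving,
so the edit is always legal and the resulting history has positive
probability under the generating `Q` — the recorded truth remains a valid
draw, though the conditioning does enrich recent acquisitions relative to
an unconditioned draw (visible as acquisition-rate estimates on the
fixture exceeding the generating rates).

What passing tests show, and what they do not: the generators reproduce
the *statistical structure* the methods assume (ultrametric trees,
Markovian niche change, Gaussian trait dynamics, state-dependent
branching). Real waterbird data add everything the generators omit —
topology error, non-ultrametricity, taxonomy mismatches, correlated diet
and mass, sampling artefacts in mass compilations — so green tests here
certify the machinery, not any empirical claim about birds.

## Problem sizes, tolerances, reproducibility

The test suite runs the exact arithmetic checks instantly; oracle
equivalences on trees of 4-30 tips (pruning vs full enumeration at
`1e-8`, SSE factorization at `1e-4`, OU-to-BM at `1e-5`); recovery
studies at 500 tips x 20 replicates (two-state no-reversion rate within
50% of truth) and 300 tips x 10 replicates (OUM optima within 0.3);
irreversibility over 20 x 100 maps; ANOVA calibration over 200 star-tree
replicates (Kolmogorov-Smirnov at alpha 0.01); and the full fixture
contract at 727 tips. These sizes were chosen as the smallest at which
each property is statistically decisive. Every stochastic component takes
an explicit seed; the pipeline derives per-stage sub-seeds from one
global seed so stages can be rerun independently, and records them in the
manifest.

## Known limitations

* Mk: no hidden-rate (covarion) variants; ambiguous tips are uniform
  vectors only.
* SSE: binary observed states only (no MuSSE/GeoSSE), no time-varying
  rates, complete sampling assumed.
* Continuous: single trait, no measurement error, no reversible-jump
  regime detection.
* The mapping stage fixes `Q` at its MLE; uncertainty in `Q` is not
  propagated into transition-count intervals.
* The birth-death simulator's stopping rule is the simple-sampling
  scheme, not the general sampling algorithm.
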