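---
title: "Small-area disease mapping and cluster detection with sirscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area disease mapping and cluster detection with sirscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirscan)
```

# The problem

Registry case counts aggregated to small areas (urban neighbourhoods,
census tracts) are Poisson-noisy: an area with 4,000 women at risk and an
expected count of 8 can easily show a doubled or halved rate by chance
alone. `sirscan` implements the standard chain of methods for this
setting — raw standardized incidence ratios, two smoothing approaches
(spatial empirical Bayes and the Besag–York–Mollié hierarchical model),
a global autocorrelation test, and a spatial scan statistic for cluster
detection — together with a synthetic-data generator that makes every
stage testable when the underlying registry data cannot be shared.

# Models and procedures

## Internal standardization and the raw SIR

Counts are modelled as `O_i ~ Poisson(E_i θ_i)` where `θ_i` is the
area's relative risk. Expected counts use internal standardization,

$$E_i = n_i \frac{\sum_j O_j}{\sum_j n_j},$$

so the study is its own reference, $\sum_i E_i = \sum_i O_i$ holds exactly,
and the E-weighted mean of the raw SIRs `O_i/E_i` is 1. This is a crude
(not age-standardized) rate model: it assumes the age structure is
comparable across areas. When two census population columns are supplied
the population at risk is their arithmetic mean, a common convention for a
study window that spans the intercensal period; areas with zero population
are dropped with a warning because their SIR is undefined.

## Moran's I

Global spatial autocorrelation of a per-area variable $x$ over binary
contiguity weights $W$:

$$I = \frac{N}{S_0}\,\frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2},
\qquad z = x - \bar x,\; S_0 = \sum_{ij} w_{ij}.$$

Inference is by random permutation of values over areas (999 replicates by
default); the two-sided p-value counts permuted statistics at least as far
from the closed-form null expectation $E[I] = -1/(N-1)$ as the observed
one, with the usual $(r+1)/(R+1)$ correction, so
$p \in [1/(R+1), 1]$. Binary weights are the default, with a
row-standardization flag, and the statistic is invariant to positive
affine transforms of $x$. The input variable is the user's choice (counts,
rates or SIRs); counts are the default.

## Spatial empirical Bayes (Marshall) smoothing

Each area's SIR shrinks toward the mean of a local reference window
$R_i = \{i\} \cup \text{neighbours}(i)$ — second-order queen contiguity
with lower orders included is the conventional window. With $E$ as the
exposure:

$$m_i = \frac{\sum_{j \in R_i} O_j}{\sum_{j \in R_i} E_j},\qquad
s_i^2 = \frac{\sum_{j \in R_i} E_j (\text{sir}_j - m_i)^2}{\sum_{j\in R_i} E_j}
 - \frac{m_i}{\sum_{j\in R_i} E_j / |R_i|},$$

truncated at zero, and the smoothed value is
$m_i + C_i(\text{sir}_i - m_i)$ with $C_i = s_i^2/(s_i^2 + m_i/E_i)$.
The output always lies between the raw SIR and the local mean. Two design
choices deserve note:

* Smoothing operates **on the SIR scale with `E_i` as exposure**, rather
  than on crude rates with `n_i`, so the smoothed values are directly
  comparable to the raw SIR and to the BYM posterior medians. Because
  `E_i` is proportional to `n_i` under internal standardization, the two
  parameterizations give identical shrinkage weights here.
* A negative moment estimate $s_i^2$ truncates to zero — full shrinkage
  to the local mean, the standard convention. An island's self-inclusive
  window degenerates to the area itself, whose moment estimate truncates
  to zero and returns the raw SIR unchanged; a weights matrix linking all
  pairs recovers global (aspatial) empirical Bayes as a degenerate case.

## The BYM convolution model

$$O_i \sim \text{Poisson}(E_i \theta_i),\qquad
\log \theta_i = \alpha + u_i + v_i,$$

with exchangeable heterogeneity $u_i \sim N(0, 1/\tau_u)$ and an intrinsic
CAR spatial field: $v_i$ given its neighbours is normal with mean the
neighbour average and variance $1/(\tau_v m_i)$, $m_i$ the neighbour
count. Both precisions carry gamma priors; the defaults
$\tau_v \sim G(0.5, 0.005)$ (prior mean 100) and $\tau_u \sim G(0.5, 0.5)$
(prior mean 1) are the values commonly used in disease-mapping practice
for these two components. The disease-mapping literature sometimes writes
the CAR conditional variance with an ambiguous precision/variance symbol;
`sirscan` uses the standard intrinsic CAR parameterization above — the one
the classical BUGS `car.normal` implementation fits — with the gamma prior
on the precision.

**Sampler.** Fitting is Metropolis-within-Gibbs:

* $\alpha$ carries an improper flat prior and moves by random-walk
  Metropolis.
* All $u_i$ are conditionally independent given $(\alpha, v)$, so they
  update as a single vectorized Metropolis block.
* The $v_i$ update in graph-colouring blocks: a greedy vertex colouring
  partitions areas so that no two neighbours share a colour, making the
  CAR full conditionals within a colour class mutually independent — a
  valid blocked update that keeps full-scale runs fast.
* $\tau_u \mid u \sim G(a_u + I/2,\; b_u + \sum u_i^2/2)$ and
  $\tau_v \mid v \sim G(a_v + (I-k)/2,\; b_v + \tfrac12\sum_{i\sim j}(v_i-v_j)^2)$
  are conjugate draws; $k$ is the number of connected components of the
  contiguity graph (the rank deficiency of the intrinsic CAR).
* **Ridge moves.** Single-site updates cross the (field scale, precision)
  ridge slowly: chains can linger in a field-active regime
  (small $\tau$) or a field-flat regime (large $\tau$). Each sweep
  therefore also proposes $(u, \tau_u) \to (c\,u, \tau_u/c^2)$ and
  $(v, \tau_v) \to (c\,v, \tau_v/c^2)$ with log-normal $c$. The ICAR
  kernel and the Jacobian cancel exactly on the sum-to-zero subspace,
  leaving the likelihood ratio times the gamma-prior ratio — a cheap,
  exact Metropolis–Hastings move that restores mixing of the precisions.
* **Identifiability.** The intrinsic CAR is improper (invariant to
  per-component shifts), so after each sweep $v$ is recentred to sum to
  zero per component, with the removed area-weighted mean absorbed into
  $\alpha$. On a connected graph this absorption is exact (the
  likelihood is unchanged); on disconnected graphs it is approximate and
  a connected adjacency is recommended. Islands are rejected outright —
  the CAR conditional is undefined for them.
* Step sizes adapt in batches of 50 during burn-in only (targeting ~0.44
  acceptance for scalar updates), frozen afterwards to preserve the
  Markov property. Chains start from overdispersed $N(0, 2^2)$ values
  for $\alpha$, $u$, $v$ with per-chain seeds.

Convergence is monitored by the Brooks–Gelman–Rubin statistic
$\hat R = \sqrt{((n-1)/n \cdot W + B/n)/W}$ for $\alpha$, both precisions
and a deterministic subset of the $\theta_i$. The full-scale default
protocol is 100,000 iterations, 5,000 burn-in, two chains (with storage
thinning 10 to keep the draw arrays moderate); the package's own test and
validation runs use 5,000 iterations with 1,000 burn-in on 200–374-area
problems, which the ridge moves make sufficient for $\hat R < 1.1$.

Reported per-area summaries are posterior medians and central 95%
intervals of $\theta_i$; medians are strictly positive, so BYM (unlike the
raw SIR) never reports a zero rate.

## The purely spatial Poisson scan statistic

Circular windows are grown around every area centroid over the
distance-nearest areas (ties broken by ascending area id — deterministic
and documented), emitting every cumulative set whose population does not
exceed a fraction `max_frac` of the study population, deduplicated by
member set. Each window scores

$$\text{llr} = c \log\frac{c}{E[c]} + (C-c)\log\frac{C-c}{C-E[c]},$$

with $0\log 0 = 0$, the log of the Poisson likelihood-ratio statistic
comparing the rate inside and outside, and is classed *high* or *low* by
the sign of $c - E[c]$ (the underlying test is two-sided:
$\theta_\text{in} \ne \theta_\text{out}$). High- and low-rate clusters are
ranked separately, each against its own Monte Carlo maximum distribution —
the package's default reading of two-sided scanning; a single combined
two-sided maximum would be a trivial variant.

Inference conditions on the observed total $C$: each replicate
redistributes $C$ cases multinomially with probabilities $E_i/\sum E$,
rescans the identical window set, and records the maximum llr per
direction. A window's p-value is $(R_\text{beat}+1)/(R+1)$, which is
bounded below by $1/(R+1)$ — with 999 replicates the smallest reportable
p-value is exactly 0.001, and that exact value is what the package
reports. Significant windows are kept greedily in decreasing llr order
subject to sharing no area with an already-kept window, giving the most
likely, secondary, tertiary, ... clusters.

**Gini-based maximum-size selection.** Scanning at a single generous
maximum size tends to return overly large, diluted clusters. The package
therefore scans a ladder of candidate maximum population fractions
(default 0.01–0.05 by 0.01, then 0.06, 0.08, 0.10, 0.12, 0.15, 0.20,
0.25, 0.30, 0.40, 0.50 — the conventional ladder), collects each
candidate's significant non-overlapping high-rate clusters, and computes a
Gini coefficient from the Lorenz-type curve of cumulative expected-case
fraction against cumulative observed-case fraction (clusters ordered by
decreasing O/E, the non-cluster remainder as the final segment); the
coefficient is twice the area between the curve and the diagonal, zero
when no clusters exist. The optimal maximum size is the candidate with the
largest Gini, ties resolved toward the smaller fraction. All candidates
share one set of Monte Carlo replicates (windows are enumerated once at
the largest candidate and masked per candidate), which keeps the ladder
scan within a constant factor of a single scan.

Reported cluster arithmetic follows the conventional table layout:
O/E, the relative risk contrasting inside with outside
$\text{RR} = (c/E[c]) / ((C-c)/(C-E[c]))$, and an annual rate per 100,000
at risk, rounded for display to 2, 2 and 1 decimals respectively.

# The synthetic-data generator

`simulation_spec()` defines a study profile; generation is a pure function
of the spec (identical spec and seed give identical data). The default
profile emulates a dense-city neighbourhood registry:

* a 22 × 17 unit lattice (374 areas) with queen (8-neighbour) adjacency;
* populations at risk drawn log-normal with median 8,000 and log-scale
  dispersion 0.6 — heterogeneous but realistic neighbourhood sizes, about
  3.2 million at risk in total;
* about 3,080 cases over a 3-year window, produced by using the BYM model
  generatively: an exact intrinsic CAR draw for $v$ (via the
  eigendecomposition of the component Laplacian restricted to the
  sum-to-zero subspace — no MCMC at generation time), iid $u$, and a
  baseline rate calibrated so the expected total equals the target;
* generative precisions $\tau_u = 8$, $\tau_v = 4$ by default — mild,
  spatially dominated risk variation producing a positive Moran's I of
  the same order as is typical for urban cancer incidence;
* one implanted high-rate circular cluster (RR ≈ 3.9 over the 15 areas
  nearest the centre, ~4% of the population) and one extreme low-rate
  cluster (RR = 0.05), mirroring the magnitudes reported for primary
  high- and low-rate clusters in urban breast-cancer mapping. Implants
  multiply the Poisson means and all counts are redrawn; ground-truth
  membership is returned for power evaluation.

For parameter-recovery experiments `simulate_bym_counts()` accepts an
explicit `exposure` vector instead of the calibrated-total mode: the
calibration deliberately absorbs $\alpha$ into the baseline rate (to hit
the case total), so only the exposure mode preserves the generative
meaning of $\alpha$.

**What the generator does not emulate:** real geography (areas are a
regular lattice with equal-size cells), age structure and age-specific
rates, geocoding failure/missingness, and edge effects from neighbouring
regions outside the study area. Passing tests on synthetic data therefore
demonstrate the correctness and calibration of the estimators under the
model's own assumptions, not robustness to those real-data features.

# Validation design and problem sizes

The test suite checks every estimator against an independent route:
hand-evaluated small examples (a 3-area Marshall window, a 4-area Moran
path, CAR conditionals, the $\hat R$ formula), brute-force oracles
(BFS contiguity, double-loop distances, an independently coded Marshall
estimator, exhaustive window enumeration on 15-area instances), closed
forms (the single-area Poisson-gamma posterior that the sampler must
reproduce when the spatial term is disabled; the gamma full-conditional
log-densities), and stochastic calibration runs: 95% credible-interval
coverage of a known $\alpha$ over 20 seeded 200-area fits, scan power
(Jaccard ≥ 0.6 against an implanted RR = 4 cluster in ≥ 18/20 seeds), and
type-I error of the scan near the nominal 0.05 over 200 null datasets with
199 replicates each. These sizes — 200–374 areas, 5,000 iterations, 199–999
replicates — are the package's validation protocol; they run in a few
minutes and the stochastic checks use fixed seeds so results are
reproducible.

# Known limitations

* Crude internal standardization only; no age-standardized expected
  counts or covariate (ecological regression) terms.
* Circular windows only; no elliptic or irregular shapes, no space-time
  scanning, and only the Poisson model (no Bernoulli/exponential scan).
* Planar Euclidean distances; coordinates are assumed projected.
* The intrinsic CAR absorption of the recentring mean into $\alpha$ is
  exact only for connected adjacency graphs.
* The BYM model's behaviour with very unequal area sizes and shapes
  inherits the usual caveats of CAR smoothing on irregular lattices.
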