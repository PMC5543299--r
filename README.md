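# sirscan

Small-area disease mapping and spatial cluster detection for registry
incidence counts.

`sirscan` is written for epidemiologists analysing case counts aggregated to
many small administrative areas (neighbourhoods, census tracts) — the
setting where raw rates are dominated by Poisson noise and the questions are
*where is incidence elevated?* and *are the elevated areas clustered?* It
implements the standard analysis chain end to end:

* **Standardized incidence ratios.** With internal standardization the
  expected count in area *i* is `E_i = n_i * (sum(O) / sum(n))`, so
  `sum(E) = sum(O)` and `SIR_i = O_i / E_i`.
* **Moran's I** with permutation inference for global spatial
  autocorrelation over a contiguity weights matrix.
* **Spatial empirical Bayes smoothing** (Marshall's local estimator): each
  SIR shrinks toward the mean of its contiguity window (typically
  second-order queen), with method-of-moments prior estimates and shrinkage
  factor `C_i = s²_i / (s²_i + m_i / E_i)`.
* **The Besag–York–Mollié model** `O_i ~ Poisson(E_i θ_i)`,
  `log θ_i = α + u_i + v_i`, with exchangeable `u_i ~ N(0, 1/τ_u)`, an
  intrinsic CAR prior on `v_i` (conditional mean = neighbour average,
  conditional variance `1/(τ_v m_i)`), and gamma hyperpriors
  `τ_v ~ G(0.5, 0.005)`, `τ_u ~ G(0.5, 0.5)`. Fitted by
  Metropolis-within-Gibbs with Brooks–Gelman–Rubin diagnostics.
* **A purely spatial Poisson scan statistic**: circular windows grown over
  centroid-nearest areas, log likelihood ratio
  `llr = c·log(c/E) + (C−c)·log((C−c)/(C−E))`, conditional Monte Carlo
  p-values `(R_beat + 1)/(R + 1)`, greedy non-overlapping high/low cluster
  ranking, and Gini-coefficient selection of the maximum window size.
* **A synthetic-data generator** (lattices, log-normal populations,
  BYM-generated risks, implanted circular clusters) so the whole pipeline is
  testable without restricted registry data.

## Worked example

A synthetic study emulating a dense urban registry (374 neighbourhoods,
~3,080 cases over 3 years, one implanted high-rate and one low-rate
cluster):

```r
library(sirscan)

st  <- simulate_study(simulation_spec(seed = 1))
sir <- compute_raw_sir(compute_expected(st$areas))
w1  <- build_weights(st$edges, sir$id)

morans_i(sir$cases, w1, n_perm = 999, seed = 5)
#> Moran's I = 0.1345 (E[I] = -0.0027), permutation p = 0.001 (999 perms)

w2  <- build_weights(st$edges, sir$id, order = 2, include_lower = TRUE)
seb <- seb_smooth(sir, w2)
c(raw_zeros = sum(sir$sir == 0), smoothed_zeros = sum(seb$sir_seb == 0))
#> raw_zeros smoothed_zeros
#>        25              0

fit <- fit_bym(sir, w1, config = mcmc_config(5000, 1000, 2, seed = 3, thin = 1))
round(fit$rhat[1:3], 3)
#> alpha tau_u tau_v
#> 1.000 1.002 1.005

gs <- gini_select(sir, R = 999, seed = 2)
gs$clusters[gs$clusters$rank == 1, c("direction", "n_areas", "cases",
                                     "expected", "oe", "rr", "p")]
#>   direction n_areas cases  expected   oe   rr     p
#> 1      high      15   341 106.18624 3.21 3.68 0.001
#> 6       low      15     2 154.83632 0.01 0.01 0.001
```

The Moran test rejects spatial randomness; smoothing removes all
noise-driven zero SIRs; the BYM chains mix (R̂ ≈ 1); and the scan recovers
both implanted clusters as the primary high- and low-rate clusters
(p = 0.001, the minimum attainable with 999 replicates). `run_pipeline()`
chains all stages and writes `sir.csv`, `sir_seb.csv`, `sir_bym.csv`,
`clusters.csv`, `moran.json` and `diagnostics.json` to an output directory.

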