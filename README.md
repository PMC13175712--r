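# cmrpower

Robust-design capture–recapture estimation and monitoring-design power
analysis for small populations of hard-to-detect animals — the motivating
case is long-term monitoring of the Brook Floater mussel (*Alasmidonta
varicosa*), surveyed by a few snorkel passes per summer over consecutive
years.

## What it does

**Demographic estimation.** A full-likelihood Pollock robust design:
primary periods (years) open to mortality and temporary emigration,
secondary occasions (survey passes) within each year during which the
population is closed. Parameters: annual survival φ (logit), first-capture
probability c with optional additive year / occasion / shell-length effects
(logit), recapture probability r shared with c or separately constant,
temporary-emigration probabilities γ′, γ″ (none / random / Markovian), and
f0, the number of animals present but never captured (log link), so that
total abundance is N̂ = M + f̂0 for M observed individuals. Per-year
abundance is derived from the closed component of each year,
n̂ₜ = Mₜ + f̂0ₜ (Horvitz–Thompson form Σ 1/p\*ᵢ(t)), with log-normal
intervals on f0ₜ. Candidate models follow a declarative grammar and are
ranked by AICc with Akaike weights:

AICc = −2logL + 2K + 2K(K+1)/(ess − K − 1),  Wᵢ = exp(−Δᵢ/2) / Σⱼ exp(−Δⱼ/2).

**Closed-population estimators.** The Lincoln–Petersen index
N̂ = n₁n₂/m₂ and its Chapman correction
N̂ = (n₁+1)(n₂+1)/(m₂+1) − 1, plus the closed M0 maximum-likelihood
estimator — the "two passes, one year" alternatives to a multi-year robust
design.

**Simulation and power.** A truth-known simulator (all animals present in
year 1, survival φ between years, Bernoulli(p) detections while alive,
never-detected animals removed) and a power pipeline: for a population
that declined d% before a 3-year study, the decline is detected when the
year-3 abundance interval's upper bound falls below the implied
pre-decline level R = n_true(year 3)/(1 − d/100). Power is the detection
proportion over (by default) 1000 simulated studies per design cell.

I/O: Program MARK `.inp` encounter histories (with frequency and
shell-length covariate columns) and long-format CSV. A thin command-line
wrapper ships in `inst/cli/cmrpower` (subcommands `simulate`, `fit`,
`rank`, `lp`, `power`, `compare`).

## Worked example

```r
library(cmrpower)

cfg <- sim_config(150, phi = 0.9, p = 0.3, design = study_design(3, 3),
                  seed = 7)
h   <- simulate_captures(simulate_alive(cfg), cfg)
fit <- rd_fit(h)
abundance(fit)
#>   primary M_t    n_hat       se   ci_low  ci_high boundary
#> 1       1 104 152.6223 9.826049 136.8499 175.9674    FALSE
#> 2       2  90 132.0770 8.978789 117.8243 153.6303    FALSE
#> 3       3  93 136.4795 9.162745 121.8968 158.4213    FALSE
plogis(coef(fit)[c("phi", "c")])
#>       phi         c
#> 0.9197802 0.3170235
```

A simulated population of 150 (declining at φ = 0.9) yields year-by-year
abundance estimates with intervals; survival and capture probability land
near their generating values (0.9, 0.3).

```r
g <- run_power_grid(n_initial = 150, n_secondary = 2:3,
                    decline_pct = c(0, 10, 20, 30), n_reps = 200, seed = 5)
as.data.frame(g)[, 1:4]
#>   n_initial n_secondary decline_pct       power
#> 1       150           2           0 0.005181347
#> 2       150           2          10 0.098445596
#> 3       150           2          20 0.512953368
#> 4       150           2          30 0.948186528
#> 5       150           3           0 0.020000000
#> 6       150           3          10 0.210000000
#> 7       150           3          20 0.760000000
#> 8       150           3          30 0.995000000
```

Each row is one design cell: the probability that a 3-year study of a
150-animal post-decline population detects the stated decline, for two
versus three survey passes per year. The third pass buys substantial
power at intermediate declines.

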