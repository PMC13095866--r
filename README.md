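# bearhr

Does sex or body size drive home-range size in brown bears? `bearhr` is an R
package implementing the full analysis chain for answering that question in a
single GPS-collared population: quality control of raw collar fixes,
equal-area projection, home-range estimation by 95% minimum convex polygon
(MCP95) and kernel utilisation distribution (KUD95, href bandwidth, volume
isopleths), a five-criterion usability screen for kernel estimates,
correlation-matrix PCA of capture morphometrics, and a log-scale
information-theoretic inference layer. It is written for movement ecologists
and spatial biostatisticians who want the entire pipeline reproducible and
testable end to end.

## The model at the core

Per-bear home-range area `A` is analysed on the natural-log scale:

```
log(A_i) = beta_0 + beta_sex * I(male_i) + [log mass, size, effort terms] + eps_i
```

Candidate models (Sex; Sex + log Mass; Sex × log Mass; log Mass; Null) are
compared by AICc with K counting intercept, slopes and residual variance;
support is summarised by ΔAICc, Akaike weights `w_i = exp(-Δ_i/2)/Σ exp(-Δ_j/2)`
and evidence ratios, with model-averaged estimates and unconditional SEs.
The sex contrast back-transforms to a male:female area ratio `exp(beta_sex)`.
Distributional differences are probed with the Fligner–Killeen test, a
permutation energy-distance test, and quantile regressions at
τ = 0.25/0.50/0.75 (for the binary sex design the check-loss minimiser is the
pair of group τ-quantiles).

A built-in synthetic generator simulates populations as Ornstein–Uhlenbeck
tracks whose stationary 95% region has the closed-form area
`5.991 · π · σ²`, plus correlated sexually dimorphic morphometrics and
realistic GPS defects with ground-truth flags — so every stage of the
pipeline is validated against known truth.

## Worked example

Simulate a population under the default study conditions (46 males, 23
females, true sex contrast 0.65 log-units, hourly fixes), run QC and
home-range estimation, and compare the candidate models:

```r
library(bearhr)

pop <- run_pipeline(population_spec(seed = 42),
                    movement_params(n_fixes = 500),
                    error_model(), compute_kud = FALSE)
aicc_table(pop$bears, candidate_models())
#>         model K n_used AICc delta_AICc weight evidence_ratio
#> 1         Sex 3     64  156       0.00 0.6323           1.00
#> 2    Additive 4     64  158       2.27 0.2028           3.12
#> 3 Interaction 5     64  160       4.43 0.0689           9.17
#> 4        Mass 3     64  161       4.81 0.0570          11.09
#> 5        Null 2     64  162       5.58 0.0389          16.27

fit <- fit_lm(pop$bears, model_spec("Sex", "sex"))
round(fit$coefficients, 3)
#>             Estimate Std. Error t value Pr(>|t|)
#> (Intercept)    3.644      0.169  21.597    0.000
#> sexM           0.439      0.207   2.127    0.037

backtransform_ratio(0.439, 0.207)$ratio
#> male:female MCP95 ratio 1.55 (95% CI 1.04-2.33)
```

The sex-only model is top-ranked (weight 0.63); adding mass or a sex × mass
interaction costs more AICc than it buys, exactly the pattern the generator
encodes (mass is dimorphic but independent of range area given sex). The
fitted sex coefficient 0.439 is this realisation's estimate of the generating
contrast 0.65; averaged over 100 seeded populations the pipeline recovers
0.653. Distributional checks on the same table:

```r
quantile_fits(pop$bears, seed = 1)
#>    tau intercept  beta ci_low ci_high ratio
#> 1 0.25     3.319 0.390 -0.376   0.865 1.477
#> 2 0.50     3.632 0.401 -0.081   0.729 1.494
#> 3 0.75     4.110 0.465 -0.044   0.960 1.592

energy_perm_test(pop$bears$log_mcp[pop$bears$sex == "F"],
                 pop$bears$log_mcp[pop$bears$sex == "M"],
                 n_perm = 10000, seed = 1)
#> energy E = 0.156, p = 0.0394
```

Real collar data enters through `parse_fixes()` (CSV with columns
`AnimalID, timestamp, lon, lat, fix_type, hdop, altitude_m`), then
`qc_trajectories()`, `estimate_home_ranges()`, `assess_usability()`,
`fit_pca()` and `assemble_table()` — the same functions the simulation runs
through. `reproduce_deposited_median(fixes_csv)` computes the population
median MCP95 from a deposited telemetry file.

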