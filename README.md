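# ricmodel

Tools for analysing cancer–infection comorbidity as an *immuno-competition*
problem: a pre-cancerous clone (the running example is a *JAK2*-mutated
hematopoietic clone) and a chronic or severe infection are both held in
check by — and compete for — a shared pool of naive T-cells. The package is
aimed at modellers and quantitative hematologists who want to explore how
immuno-aging (the decline of naive T-cell output, `alpha`) turns a dormant,
screening-detectable clone into overt disease, and to confront that
mechanism with screening-cohort statistics.

## The model

After a quasi-steady-state reduction of the immune compartments, the two
normalized burdens `X` (cancer) and `Y` (infection) follow

    X' = X(1 − X) − A1·X² / [(A2·X + A3·Y + 1)(A4·X + 1)]
    Y' = B0·Y(1 − Y) − B1·Y² / [(A2·X + A3·Y + 1)(B4·Y + 1)]

where the seven dimensionless clusters collapse fourteen physiological
rates, and the immune-response strengths `A1, B1` are both proportional to
the naive T-cell production rate `alpha`. The shared denominator is the
competition: each disease dilutes the immune pressure on the other.

What the package computes on top of the equations:

* steady states, stability, dormant/fatal/threshold roles
  (`find_steady_states()`), nullclines, phase portraits;
* the separatrix (stable manifold of the threshold saddle) and basins of
  attraction (`compute_separatrix()`, `classify_basin()`);
* saddle-node bifurcation scans over `alpha` and over age
  (`scan_alpha()`, `diagram_vs_age()`), the escape-distance/probability
  curve (`escape_curve()`);
* H/D/F/R virtual-patient subtyping (`classify_subtype()`);
* on–off naive T-cell therapy with event-based switching
  (`simulate_treated()`);
* screening-cohort flow statistics and the prevalence-versus-age slope
  (`cohort_flow()`, `fit_prevalence_slope()`,
  `compare_model_to_epidemiology()`);
* synthetic virtual-patient populations, screening cohorts and prevalence
  tables so the whole pipeline is testable without individual-level data
  (`sample_population()`, `generate_screening_cohort()`,
  `generate_prevalence_table()`).

**Default parameters are calibrated, not measured.** The packaged
defaults are the frozen output of `calibrate_default_params()`: a
parameter set constructed so that the `alpha`-scan reproduces the
published bifurcation anatomy of the *JAK2*-mutated MPN / infection case —
saddle-nodes at `alpha ≈ 16` and `alpha ≈ 99` bounding the bistable
window, with three interior equilibria inside it. Checks of the
bifurcation anchors against these values are therefore
calibration-verification checks, not independent reproductions from
measured physiological constants.

## Worked example

```r
library(ricmodel)

params <- default_params()          # calibrated virtual patient, alpha = 50
classify_subtype(params)
#> [1] R
#> Levels: H D F R

find_steady_states(cluster_params(params))
#> # A tibble: 8 × 8
#>          X       Y stability role      eig1_re eig1_im eig2_re eig2_im
#>      <dbl>   <dbl> <chr>     <chr>       <dbl>   <dbl>   <dbl>   <dbl>
#> 1 0        0       unstable  healthy     1.5         0   1           0
#> 2 0.000665 0       saddle    mono_x      1.5         0  -0.908       0
#> 3 0        0.00105 saddle    mono_y     -1.29        0   1           0
#> 4 0        0.254   unstable  mono_y      1           0   0.623       0
#> 5 0        0.717   saddle    mono_y      1           0  -0.668       0
#> 6 0.000722 0.00111 stable    dormant    -1.29        0  -0.892       0
#> 7 0.0388   0.190   saddle    threshold   0.749       0  -0.303       0
#> 8 0.818    0.879   stable    fatal      -1.24        0  -0.719       0
```

The patient is bistable ("R" for risk): a dormant state with a cancer
burden of about 0.07 % of carrying capacity coexists with a fatal state
above 80 %, separated by the threshold saddle. Scanning `alpha` locates
the saddle-node bifurcations that bound this regime:

```r
bd <- scan_alpha(params, seq(1, 120, by = 2.5))
bd$sn_points
#> # A tibble: 2 × 5
#>   alpha type                    X      Y  eig_min
#>   <dbl> <chr>               <dbl>  <dbl>    <dbl>
#> 1  16.2 dormant-threshold 0.00650 0.0126 1.39e-16
#> 2  99.2 fatal-threshold   0.387   0.587  1.11e-16
autoplot(bd)
```

Below `alpha ≈ 16` only the fatal state survives (elderly immune
systems); above `alpha ≈ 99` only the dormant state does. With the
default linear age map (`alpha` = 100 at age 20, 16 at age 80) the
protective gap between the dormant state and the threshold shrinks with
age, and its inverse — the escape propensity — grows roughly linearly in
the interior of the window:

```r
esc <- escape_curve(params)
esc
#> <ric_escape> 59 ages, slope 0.1063 a.u./year (R^2 = 0.925)
```

Screening-cohort arithmetic works on printed counts or on full tables.
On the published Copenhagen flow (49,488 screened, 63 positive, 52
re-invited, 26 undiagnosed at re-examination, 18 diagnosed then, 5/3
increase/decrease among the rest):

```r
flow <- cohort_flow(copenhagen_counts())
flow[, c("n_stable", "pct_nonprogressing_of_undiagnosed",
         "pct_equilibrium_of_reinvited")]
#> # A tibble: 1 × 3
#>   n_stable pct_nonprogressing_of_undiagnosed pct_equilibrium_of_reinvited
#>      <dbl>                             <dbl>                        <dbl>
#> 1        8                                38                           15
```

8 of the 52 re-invited citizens (15 %) sat in a temporary dormant
equilibrium, and 3 of those 8 (38 %) showed a decreasing allele burden —
the pattern the bistable dormant state predicts.

## Package layout

| file | contents |
| --- | --- |
| `R/params.R` | parameter objects, cluster mapping, JSON/YAML I/O, calibration |
| `R/model.R` | dimensional and dimensionless right-hand sides, Jacobian, simulation, eradication check |
| `R/steady_states.R` | equilibrium location (vectorized Newton + axis cubics) and classification |
| `R/separatrix.R` | separatrix tracing, basin classification, basin grids |
| `R/subtype.R` | H/D/F/R subtype rules |
| `R/bifurcation.R` | alpha scans, saddle-node refinement, age maps, escape curve |
| `R/treatment.R` | on–off therapy simulation, state perturbation |
| `R/cohort.R` | cohort flow, VAF-change rules, prevalence slope, model-vs-epidemiology report |
| `R/synthetic.R` | virtual patients, screening cohorts, prevalence tables |
| `R/plots.R` | phase portraits and autoplot methods |

The methods vignette (`vignettes/immuno-competition-methods.Rmd`) explains
the model, the calibration, the numerical choices and the limits of the
synthetic generators.
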