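---
title: "Methods: immuno-competition dynamics of cancer-infection comorbidity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immuno-competition dynamics of cancer-infection comorbidity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricmodel)
```

## The model

The package analyses a conceptual two-disease system: a pre-cancerous clone
(burden $x$, e.g. a *JAK2*-mutated hematopoietic clone) and a chronic or
severe infection (burden $y$) that both provoke, and compete for, a shared
pool of naive T-cells. After a quasi-steady-state reduction of the immune
compartments, each disease follows logistic growth opposed by an
effector-cell kill term, and the only coupling between the two diseases is
the shared naive T-cell supply in the kill terms' denominator:

$$
x' = a_x x\Big(1-\frac{x}{K_x}\Big)
     - \frac{\alpha r_x p_x \beta_x}{d_x \varepsilon}\,
       \frac{x^2}{\big(\tfrac{\beta_x}{\varepsilon}x +
       \tfrac{\beta_y}{\varepsilon}y + 1\big)
       \big(\tfrac{r_x(1-p_x)}{d_x}x + 1\big)},
$$

with the analogous equation for $y$. Normalizing ($X = x/K_x$, $Y = y/K_y$,
$T = a_x t$) collapses the fourteen physiological rates into seven
dimensionless clusters:

$$
X' = X(1-X) - \frac{A_1 X^2}{(A_2X + A_3Y + 1)(A_4X+1)},\qquad
Y' = B_0\,Y(1-Y) - \frac{B_1 Y^2}{(A_2X + A_3Y + 1)(B_4Y+1)},
$$

where $A_2 = \beta_xK_x/\varepsilon$, $A_3 = \beta_yK_y/\varepsilon$,
$A_4 = r_xK_x(1-p_x)/d_x$, $B_4 = r_yK_y(1-p_y)/d_y$, $B_0 = a_y/a_x$, and
the immune-response strengths $A_1 = \alpha r_x p_x A_2/(a_x d_x)$,
$B_1 = \alpha r_y p_y A_3/(a_x d_y)$ are both proportional to the naive
T-cell baseline production $\alpha$. Raising either burden dilutes the
shared pool (the $A_2X + A_3Y + 1$ factor), so each disease *weakens* the
immune pressure on the other: the off-diagonal Jacobian entries are
non-negative, which is the mathematical signature of comorbidity risk in
this model.

The unit square is an attracting trapping region: solutions started
non-negative stay non-negative, trajectories started outside enter in
finite time and never leave. Both properties are asserted numerically in
the test suite over random parameter sets.

## Default parameters: a calibrated virtual patient

The defaults shipped as `default_params()` are not independently measured
physiological rates; they are the frozen output of
`calibrate_default_params()`, which constructs a parameter set whose
$\alpha$-scan reproduces the reported qualitative anatomy of the
comorbidity phase plane:

* a *bistable window* in $\alpha$ containing $[17, 99]$ and contained in
  $[16, 100]$, with saddle-node bifurcations at its edges (the calibration
  targets are $\alpha = 16.2$ and $99.2$, satisfying every reported regime
  boundary simultaneously);
* inside the window, exactly three interior equilibria — a low-burden
  **dormant** state, a high-burden **fatal** state, and a **threshold**
  saddle between them;
* monostable-fatal below the window, monostable-dormant above it;
* a safe-immune-response ("healthy") regime only at extreme $\alpha$
  (around 950 for the default set), so ordinary scans never classify the
  virtual patient as H.

The calibration has exactly two degrees of freedom that matter for this
anatomy: a common cluster magnitude $A$ (shared by $A_2, A_3, A_4, B_4$),
which controls the *ratio* of the two saddle-node values, and the
proportionality coefficient between $A_1 = B_1$ and $\alpha$, which slides
the window without deforming it. The routine bisects on $A$ to match the
edge ratio $99.2/16.2$, then rescales the coefficient so the lower edge
lands at $16.2$. Mapping the clusters back to the fourteen dimensional
parameters has leftover freedom that the dynamics cannot see; it is fixed
by unit choices ($a_x = \varepsilon = d_x = d_y = 1$, time in units of the
cancer growth rate), a growth-rate ratio $B_0 = 1.5$ (the infection grows
faster than the clone), and an apoptosis probability $p = 0.995$, which
sets the carrying capacity ($K \approx 3.1\times10^4$ cells) and thereby
pushes the eradication threshold far above the scanned $\alpha$ range. The
default $\alpha = 50$ sits mid-window: a bistable, at-risk virtual patient.

A test re-runs the calibration and checks that it reproduces the frozen
set.

## Steady states, separatrix, basins

Interior equilibria are roots of the reduced system obtained by dividing
the right-hand sides by $X$ resp. $Y$, which removes the axis roots. The
solver is a damped Newton iteration run simultaneously from a lattice of
seeds (plus log-spaced seeds near the origin, where the dormant state sits
when the immune response is strong), deduplicated at $10^{-6}$. Axis
equilibria are roots of cubic polynomials and are obtained directly with
`polyroot()`. Stability comes from the analytic Jacobian; interior stable
states are ranked dormant/fatal by total burden $X+Y$ (ties, which do not
occur generically, would break by $X$).

An independent check exploits that the reduced equations are *linear* in
the opposite variable, so the cancer nullcline is an explicit curve
$Y_f(X)$: restricting the infection equation to that curve reduces
equilibrium-finding to one-dimensional sign-change scanning plus
`uniroot()`. The test suite compares both routes.

The separatrix is traced by integrating the time-reversed flow from
$\pm10^{-6}$ displacements along the saddle's stable eigenvector
(`lsodar`, rtol $10^{-10}$), truncated at the boundary of the unit square.
Basins are classified by forward integration until a trajectory comes
within $10^{-5}$ of a stable state; an extinction floor of $10^{-9}$
defines "eradicated", since the smooth system never reaches zero in finite
time. For grids and random samples the package integrates all points as
one batched ODE system with an explicit adaptive method, dropping points
as they converge — the dynamics inside the unit square are not stiff, and
this makes 500-point basin classification essentially instantaneous.
Classification is insensitive to integrator tolerances except within a
thin band around the separatrix, which is asserted by comparing basin
areas at rtol $10^{-8}$ vs $10^{-10}$.

## Bifurcation scan and aging

`scan_alpha()` recomputes $A_1, B_1 \propto \alpha$ along a grid, counts
interior stable states, brackets any change, refines by bisection to
$10^{-3}$, and then polishes each saddle-node on the extended system
$(f, g, \det J) = 0$ in $(X, Y, \alpha)$ with a Newton iteration. The
polish pins the merge point to machine precision, so the zero-eigenvalue
condition at each reported saddle-node holds to $\sim10^{-15}$ rather than
the $\sqrt{\Delta\alpha}$ accuracy bisection alone would give.
Bisection-plus-polish was chosen over pseudo-arclength continuation
because the system is two-dimensional and root-finding is cheap;
robustness beats elegance here.

Immuno-aging enters through `age_map()`: $\alpha(\text{age})$ declines
linearly, by default from $100$ at age 20 to $16$ at age 80 (no slope is
reported for this decline; the default places the dormant-to-risk and
risk-to-fatal transitions at plausible screening-cohort ages and is fully
configurable). Composing the scan with the age map gives the
bifurcation-versus-age diagram and the transition ages; the transition
$\alpha$ values themselves are properties of the scan and invariant to the
age map, which a test asserts by comparing two different maps.

## Escape distance and probability

Inside the bistable window, the protection of the dormant state is the
vertical (infection-axis) gap between the threshold branch and the dormant
branch, $d(\alpha) = Y_{\text{thr}} - Y_{\text{dorm}}$ — the quantity the
bifurcation diagrams display. (Interpolating the separatrix polyline
vertically above the dormant state's $X$ gives the same number near the
lower saddle-node but is undefined for roughly $\alpha > 70$, where the
separatrix leaves the unit square through the top edge before reaching the
dormant state's abscissa; the branch gap is defined on the whole window.)
The escape probability under a continuous infection load is modelled as
$c/d$. The constant $c$ is a unit choice the analysis cannot pin down;
by default the curve is reported in arbitrary units and
`compare_model_to_epidemiology()` only forms the escape-to-prevalence
slope ratio when the user supplies a calibrated $c$.

The distance shrinks strictly with age across the window (asserted), and
$1/d$ grows approximately linearly — but only in the window's interior:
near the lower saddle-node $d \sim \sqrt{\alpha - \alpha_{SN}}$, so $1/d$
diverges as an inverse square root and no linear description survives the
last years before the risk-to-fatal transition. The default linear fit
therefore covers ages 21–60, stopping 20 years short of the transition;
there $R^2 > 0.9$. Fitting through age 79 drops $R^2$ to about 0.5.

## Treatment simulation

`simulate_treated()` integrates the non-autonomous system with
$\alpha(t)$ following exponential laws — decay toward a floor of $0.15$ at
rate $4$ between treatments, saturation toward a ceiling of $100$ at rate
$3$ during treatment (rates per dimensionless time; no units are printed
for them, and a per-year reading is available by rescaling) — under a
hysteresis controller on the cancer burden: treatment switches on when $X$
rises through `threshold_on` (default $0.5$) and off when it falls through
`threshold_off` (default $0.1$). The controller thresholds are not
reported anywhere; the defaults produce the characteristic relapse cycle
and are exposed in the schedule object. Switching is event-based (the
integrator stops exactly at each crossing and restarts), so toggle times
are sharp, the flag changes at most once per crossing, and $\alpha$
provably stays inside $[\text{floor}, \text{ceiling}]$.

Two scenario properties are asserted: with $\alpha$ held above the window
the system is monostable-dormant and any interior state is cured; after
stopping treatment from the dormant basin, relapse begins only after
$\alpha$ has fallen below the lower saddle-node — the decay of $\alpha$
(sub-unit time scale) strictly precedes the disease's regrowth.

## Cohort statistics and the synthetic generators

`cohort_flow()` reduces a screening cohort to the published flow counts
and two headline percentages, rounded to whole percent: the share of the
final undiagnosed group with decreasing allele burden (strict-diagonal
rule; $3/8 \to 38\%$) and the equilibrium share of the re-invited
($8/52 \to 15\%$). The strict diagonal is the default because the figure
caption counts subjects *under* the diagonal; a symmetric noise-band rule
is available but not default. `fit_prevalence_slope()` is ordinary least
squares of prevalence on age-bin midpoints, by default neglecting the
first and last bins, reporting the slope per year and per decade with
binomial standard errors per bin.

The synthetic generators exist so every pipeline stage is testable without
the (unavailable) individual-level screening data:

* `sample_population()` draws virtual patients log-normally around the
  default set (medians equal the defaults; apoptosis probabilities
  resampled into $(0,1)$), with $\alpha$ assigned through the age map.
* `generate_screening_cohort()` draws the flow hierarchically with the
  published proportions as default rates (positivity $63/49{,}488$, death
  before follow-up $11/63$, equilibrium $8/52$ of survivors, interim
  diagnosis $26/44$ of progressing survivors) and fills in allele burdens
  from the model: equilibrium subjects sit at their dormant state,
  progressors follow a trajectory from just beyond the threshold state
  toward the fatal branch across the follow-up interval (model time read
  as years), both mapped to percent VAF by a configurable linear scale
  (default $100X$, capped) plus truncated Gaussian measurement noise. An
  optional 2% allele-burden gate on positivity is available but off by
  default, because the mapping from normalized burden to VAF is a unit
  choice.
* `generate_prevalence_table()` draws binomial positives around a linear
  prevalence-age law (default slope $0.1\%$/year on decade bins 30–90);
  an exact mode returns expected counts for noiseless-limit tests.

What the generators deliberately do **not** emulate: clonal genetics
beyond a single clone, competing-risk mortality, age-dependent death,
assay-specific VAF error structure, or any correlation between parameter
dispersion and age. Passing recovery tests therefore show that the
*pipeline* is unbiased at realistic sample sizes — not that the model fits
real screening data.

## Numerical choices, reproducibility, limitations

Integration uses adaptive solvers at rtol $10^{-8}$ / atol $10^{-10}$
(trajectories hug the axes where dynamics are slow; the dormant state of
the default set lies at $X \approx 7\times10^{-4}$). Steady-state residual
tolerance is $10^{-8}$; duplicate roots merge at $10^{-6}$; saddle-node
bisection tolerance is $10^{-3}$ in $\alpha$ before polishing. All
generators are pure functions of (spec, seed) and restore the caller's RNG
state. Problem sizes in the tests — 100 random parameter sets for the
invariants, 500 points for flow-versus-separatrix agreement, a 40×40
basin grid for the tolerance-robustness check, 100 replicates for the
recovery oracles — were chosen to make the checks statistically meaningful
while keeping the whole suite comfortably fast on one core.

Known limitations: no limit-cycle search is attempted beyond long-horizon
integration (none is expected in the monostable regimes, and none was
observed); basin geometry is classified numerically, not certified;
two-parameter bifurcation surfaces and scans in parameters other than
$\alpha$ have no calibrated anchors; and the escape-probability constant
$c$ is irreducibly a unit choice, so only slope *ratios* are meaningful.
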