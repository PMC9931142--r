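---
title: "A steady-state model of contact-area-dependent neural induction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A steady-state model of contact-area-dependent neural induction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otxinduction)
```

## The model

At the 32-cell stage of the ascidian embryo, four pairs of anterior (a-line)
ectoderm cells choose between neural and epidermal fate. The inducing signal
is FGF from the mesendoderm, antagonized by ephrin presented by neighbouring
ectoderm cells. The cells are assumed identical in every respect except
geometry: what differs between a6.5, a6.6, a6.7 and a6.8 is the fraction of
the cell surface contacting FGF-expressing mesendoderm ($S_1$) and the
fraction contacting ephrin-expressing ectoderm ($S_2$). Ligand
concentrations are uniform; receptor densities are uniform; so the number of
*engageable* receptors scales with contact area. In the embryo the two
fractions are tightly anti-correlated; the package carries the measured
linear law

$$S_2 = -1.13\,S_1 + 0.91,$$

clamped at zero where the line would go negative (`s2_from_s1()`). With the
tie in place, a single number per cell type — $S_1$ — drives the whole
pipeline.

Signal transduction is a chain of three steady states:

1. **Receptor occupancy.** Bound receptor counts follow equilibrium binding:
   $R_b = R_T S_1 \frac{[\mathrm{FGF}]}{[\mathrm{FGF}] + K_d}$, and
   analogously $Q_b$ for Eph receptors with $S_2$, $[\mathrm{ephrin}]$,
   $K_e$. For posterior (b-line) cells, which face both A-line mesendoderm
   and four B-line cells expressing different FGF levels, the FGF-bound
   count is the sum over the two receptor populations
   (`bline_bound_receptors()`), with per-interface concentrations defaulting
   to 5, 0.7, 0.08, 0.7 relative units at the B6.1–B6.4 interfaces.

2. **Ras-GTPase cycle.** The fraction $T$ of Ras in the GTP state balances
   SOS-mediated loading (activated by FGF-bound receptors) against
   p120RasGAP-mediated hydrolysis (activated by ephrin-bound Eph) plus a
   basal, contact-independent GAP rate $K_b$:
   $$V_s \tfrac{R_b}{K_s + R_b}\tfrac{1-T}{K_1 + 1 - T} =
     V_{rg} \tfrac{Q_b}{K_{rg} + Q_b}\tfrac{T}{K_2 + T} + K_b T.$$
   The left side decreases and the right side increases in $T$, so the root
   in $[0,1]$ is unique. ERK activity is a Hill readout of $T$,
   $\mathrm{Erk}^* = T^n/(T^n + K_{erk}^n)$ with $n = 2$, $K_{erk} = 0.5$,
   collapsing the Raf/MEK/ERK cascade into one function.

3. **Otx transcription.** ERK phosphorylates the Ets1/2 activator (activating
   it) and the ERF2 repressor (inactivating it). Each is a
   Goldbeter–Koshland covalent-modification cycle; with Michaelis constants
   of 0.05 both cycles operate near saturation, i.e. in the zero-order
   ultrasensitive regime, making the active fractions $A_p(\mathrm{Erk}^*)$
   and $I(\mathrm{Erk}^*)$ switch-like even though every kinetic term is
   Michaelian. The repressor competes for the same ETS sites as the
   activator, inflating its effective half-saturation constant to
   $K_a(1 + I/K_i)$, so steady-state expression is
   $$O = \bigl(v_b + v_o\,\tfrac{A_p}{K_a(1+I/K_i) + A_p}\bigr)/k .$$
   A cooperative variant (`coop = TRUE`) squares both the occupancy and the
   effective constant — two tandem ETS sites — and can substitute for
   zero-order kinetics when the Michaelis constants are larger
   (the cooperative analyses use $K_{MMi} = 0.3$, $k_{MM1} = k_{MM3} = 14$;
   the flag deliberately does *not* change those constants behind your
   back).

Everything is solved at steady state; there are no dynamics in the package,
and no fitting of the kinetic parameters — `default_parameters()` *is* the
calibrated set, with all units arbitrary but mutually consistent.

The dual control is the scientific heart: ERK activation is graded across
the four cell types (about 0.0021, 0.0078, 0.055 and 0.18 of maximum in
a6.8, a6.6, a6.7, a6.5), yet Otx output is bimodal — ON in a6.5, OFF
elsewhere — because activator and repressor respond sharply and in opposite
directions to the same input.

## Perturbation scenarios

Experimental manipulations enter as parameter overrides
(`apply_scenario()`):

| scenario | override | interpretation |
|---|---|---|
| `dnFGFR` | $R_T = 100$ | dominant-negative FGF receptor (20-fold fewer functional receptors) |
| `Eph3dC` | $Q_T = 10$ | dominant-negative Eph3 receptor |
| `RGdGAP` | $V_{rg} = 0.01$ | dominant-negative p120RasGAP |
| `NVP` | $[\mathrm{ephrin}] = 0.001$ | pharmacological Eph inhibition |
| `U0126_low` | $K_{erk} = 0.6$ | moderate MEK inhibition |
| `ERF2_MO` | $I \equiv 0.01$ | morpholino against the repressor (clamps the state variable, not a rate) |

Scenarios compose (`c("NVP", "U0126_low")`), are idempotent, and never
mutate their input. The model reproduces the characteristic shifts: dnFGFR
collapses expression to the basal floor everywhere; any Eph-pathway
inhibition ectopically switches a6.7 ON; adding moderate MEK inhibition on
top restores it below threshold. The a6.7 cell sits on the steep part of
the expression curve, which is why it is the bellwether in every
perturbation — and why its expression is the most variable.

## Readout calibration

Model outputs live on normalized scales; measurements are dpERK
immunofluorescence intensities and smFISH spot counts. Both maps are
linear: $\mathrm{IF} = A\,\mathrm{Erk}^* + B$ and
$\mathrm{spots} = C\,O + D$. Each staining batch has its own constants, so
`fit_calibration()` re-derives them per experiment: the backgrounds $B$ and
$D$ are pinned to the mean of the least-responsive cell type (a6.8), their
uncertainties to that type's standard deviation, and the slopes are
through-origin least squares on the background-subtracted values. "Best
fit" is not further specified by the source experiments; ordinary least
squares is the simplest reproducible reading and is what the package does.
Note the pinning convention means $D$ absorbs the basal expression floor
$C\,v_b/k$; recovery of the generating constants is exact only when the
background type truly sits at zero response (the test suite constructs that
case explicitly with $v_b = 0$ and $S_1 = 0$). Uncertainties propagate in
quadrature (`mean_if_uncertainty()`, `ratio_with_uncertainty()`); published
per-panel constants ship as data in `figure_calibrations()`.

## Hill-coefficient estimation

Steepness is quantified two ways, and they are different estimators:

* `fit_hill()` — Levenberg–Marquardt least squares of
  $y = a\,x^{n}/(x^{n} + K^{n})$. The package's default fixes the baseline
  at zero because every model sweep starts from zero response; decreasing
  curves are reflected into the drop from their top and fit with the same
  increasing family. A free intercept is available (`baseline = "free"`)
  but adds a degree of freedom the curves do not need, and with it the
  decreasing fits drift noticeably. Initialization: $n = 1$, $K$ at the
  half-amplitude point, amplitude from the data extremes; $n$ bounded to
  $[0.1, 50]$.
* `hill_from_potency()` — the potency formula
  $n_H = \log 81 / \log(x_{90}/x_{10})$, with $x_{10}$, $x_{90}$ the inputs
  giving 10% and 90% of maximal response. "Maximal response" is the
  supremum over the evaluated domain after subtracting the low-end
  response; the closed-form identity with the Hill exponent therefore holds
  when the domain spans saturation. It is exact on ideal Hill data,
  invariant to affine rescaling, and the right tool for the Otx curves,
  whose shape a Hill function fits poorly (on the repressor-free
  $O(\mathrm{Erk}^*)$ curve the two estimators disagree by ~27%, with the
  repressor by ~12% — both behaviors are asserted in the tests).

Sweep domains matter and are fixed as package defaults: tied-$S_1$ sweeps
run over $[0, 0.91/1.13]$, where the empirical relation keeps $S_2 \ge 0$
(this choice also reproduces the published per-cell fit of 2.41 for the
same curve); ligand sweeps run over $[0, 100]$ — four times $K_d$, which
spans receptor saturation; grids default to 201 points (2001 for potency
estimates, whose quantiles sit on steep switches). With these conventions
the package reproduces the full published table of coefficients within
±0.15: Erk\*($S_1$) 2.40 vs 2.39, Erk\*([FGF]) 1.54 vs 1.47, Erk\*($S_2$)
1.67 vs 1.57, Erk\*([ephrin]) 1.20 vs 1.17, the ephrin-free variants 1.83
vs 1.85 and 1.45 vs 1.42, the independent-surface pair 2.00/1.03 vs
1.99/1.04, the symmetric-pathway 2.08 vs 2.13, and the potency values
6.35/2.55/13.85 vs 6.3/2.6/14.2. `hill_difference_heatmap()` scans any
parameter and tabulates the difference between two curves' coefficients,
the device used to show that ERK responds more steeply to contact area than
to ligand concentration across wide parameter ranges.

## Sensitivity analyses

`sensitivity_oat()` perturbs one parameter at a time by ±20% and reports
perturbed/default ratios of Erk\* and $O$ per cell type, with each type at
its mean $S_1$. The surfaces are treated as independent inputs here ($S_1$
perturbed with $S_2$ held, and vice versa); perturbing the *slope* of the
$S_2(S_1)$ relation re-anchors the intercept so the line still passes
through the centroid of the per-type means — the analogue of refitting the
intercept to the data. `sensitivity_random()` draws all parameters of a
subset (FGF leg, ephrin leg, or all) independently and uniformly within
±20% — uniform being the minimal reading of "random" absent a stated
distribution — with a recorded seed and a default of 1000 draws. The
robust findings: the cell-type ordering a6.5 > a6.7 > a6.6 > a6.8 of both
ERK and Otx survives every tested perturbation; FGF-leg parameters spread
ERK activity far more than ephrin-leg parameters; per-type means barely
move.

## The synthetic-data generator

`generate_geometry()` emulates the *structure* of the measured per-cell
data: four clusters of $S_1$ (25 cells per type), the linear $S_2$ relation
with small residual scatter, clipping to $[0,1]$.
`generate_readouts()` pushes each synthetic cell through the pipeline and
adds measurement noise — Gaussian on IF, Poisson on spot counts (a stand-in;
the real count dispersion is uncharacterized).

Two generator defaults deserve justification:

* **Per-type $S_1$ means** (0.400, 0.2226, 0.0834, 0.0324 for a6.5, a6.7,
  a6.6, a6.8). The measured per-cell values are not redistributable, and
  their means are not published — but the per-type *mean ERK activities*
  are. Each default mean is therefore obtained by moment matching: it is
  the value $m$ for which the average of $\mathrm{Erk}^*(S_1)$ over
  $S_1 \sim \mathcal{N}(m, 0.04)$, clipped, equals the reported mean
  activity. Because $\mathrm{Erk}^*$ is convex over most of this range, the
  population mean exceeds the value at the mean, so moment matching gives
  slightly lower means than direct inversion would — a distinction that
  matters for a6.7, which the model places just below the expression
  threshold in unperturbed embryos, consistent with its observed behavior.
* **Residual scatter of $S_2$** (0.015): chosen so the synthetic regression
  reproduces the reported $R^2 \approx 0.99$ of the linear fit given the
  overall spread of $S_1$.

What passing tests on synthetic data do show: the calibration fit recovers
its generating constants, the pipeline reproduces the orderings and the
graded-ERK/bimodal-Otx contrast, and all of this is a pure function of
(config, seed). What they cannot show: anything about cell-to-cell
heterogeneity beyond contact area (real IF scatter is visibly larger than
the model predicts), segmentation error, or embryo-to-embryo covariance —
none of which the generator attempts to emulate.

## Numerical choices

* Ras-GTP root: bracketed `uniroot` on $[0,1]$ followed by Newton polishing
  with the analytic derivative; residuals at the returned root are below
  $10^{-12}$ and the solver agrees with long-time ODE integration (the test
  oracle, via deSolve) to $10^{-8}$ across random ±20% parameter draws.
  Boundary cases return exactly 0 (no bound FGF receptors) or 1 (no
  hydrolysis at all).
* Goldbeter–Koshland cycles: closed-form quadratic with the stable
  root-selection form, a residual check, and bisection fallback for
  numerically marginal discriminants. Zero drive on either leg returns the
  corresponding boundary (0 or 1) exactly.
* Potency quantiles: located by root finding on a monotone (Hyman) spline
  through the cumulative-maximum of the curve; non-monotone inputs warn.
* Degenerate inputs fail fast with named errors: flat curves, calibrations
  with zero slope, empty background groups, out-of-range fractions (with
  row numbers), unknown scenario names or parameter keys.

## Problem sizes

Default grids are 201 points (2001 for potency estimates); the ODE-oracle
comparison uses 100 random draws; random sensitivity sampling uses 1000
draws per subset. These sizes were chosen so every quantity is
grid-converged — halving or doubling them moves no reported coefficient at
the precision quoted above — while the whole suite remains a desk-scale
computation.

## Known limitations

* Steady state only; transient ERK dynamics and timing are out of scope.
* The Raf/MEK/ERK cascade is one Hill function; no explicit cascade species.
* Receptor dimerization (heparan-sulfate dependent) is not modeled.
* Otx activation by factors other than Ets1/2/ERF2 (e.g. Gata.a) is absent,
  which is the likely reason measured ERF2-morpholino embryos need a larger
  background term than the model predicts.
* The empirical $S_2(S_1)$ law is a-line specific; b-line cells require
  measured $S_2$.
* At ERK activities that balance the activator cycle exactly
  ($k_{MM3}\mathrm{Erk}^* \approx v_{MM4}$), expression sits on a knife
  edge; small geometry changes flip the a6.7 cell, which is a prediction,
  not an artifact.
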