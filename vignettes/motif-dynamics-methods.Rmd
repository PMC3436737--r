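---
title: "Models and methods: heterogeneous differentiation from a two-regulator motif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: heterogeneous differentiation from a two-regulator motif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetdiff)
```

## The model

CD4+ T-cell subsets (Th1, Th2, Th17, iTreg) are marked by high expression of
one lineage-defining master regulator (T-bet, GATA3, RORγt, Foxp3). In the
two-regulator paradigm a cell carries a pair of regulators X and Y; a naive
cell expresses neither, and differentiation produces X-single-positive (XSP),
Y-single-positive (YSP) or double-positive (DP) phenotypes. `hetdiff` models
the regulators' activities $X_i \in [0,1]$ with phenomenological
influence-network ODEs

$$\frac{dX_i}{dt} = \gamma_i\left(F(\sigma_i W_i) - X_i\right),\qquad
F(u) = \frac{1}{1+e^{-u}},\qquad
W_i = \omega_{i0} + \sum_j \omega_{j\to i}X_j + \sum_s \omega_{s\to i}S_s,$$

where $W_i$ is the effective drive of node $i$: a basal weight, weighted
influences from the other regulators (negative for inhibition, positive for
auto-activation), and weighted exogenous signal levels $S_s$. All quantities
are dimensionless; one model-time unit corresponds to 1.5 days. The weights
are influence strengths, not biochemical rate constants — the model captures
soft-threshold regulatory logic, not mechanism.

The motif shared by all shipped models wires a *primary* signal (S1, e.g.
TCR stimulation) to both regulators, and two *polarizing* signals to one
regulator each; the regulators inhibit each other and (in the auto-activation
variants) activate themselves. Because the drive enters through a sigmoid,
trajectories started in the unit box stay there: at $X_i = 0$ the rate is
$\gamma_i F > 0$ and at $X_i = 1$ it is $\gamma_i(F-1) < 0$.

A state's phenotype is called by a strict threshold of 0.5 units per
regulator (a regulator exactly at 0.5 counts as not expressed): `naive`,
`XSP`, `YSP` or `DP`.

## Steady states and branches

`find_steady_states()` refines a regular multistart grid over the unit box
(default 7 points per dimension) with Newton's method on the fixed-point map,
merges solutions closer than $10^{-5}$ in max-norm, classifies stability from
the analytic Jacobian
$J_{ij} = \gamma_i\sigma_i F'(\sigma_i W_i)\omega_{j\to i} - \gamma_i\delta_{ij}$,
and orders the result lexicographically so output is reproducible.
Eigenvalues with $|\mathrm{Re}| < 10^{-9}$ are treated as marginal; such a
state is labelled `unstable` with a warning, since only the stable/unstable
distinction is meaningful here. Newton starts that do not converge are
counted and reported, never fatal.

`trace_branch()` follows a fixed-point branch in one signal with
pseudo-arclength continuation: a unit tangent from the bordered Jacobian, a
predictor step, and a Newton corrector orthogonal to the tangent. The step
adapts between $10^{-6}$ and 1/25 of the range (initial $10^{-2}$); steps
whose corrector lands far from the predictor, or that bend the tangent by
more than 60 degrees, are rejected and halved — both symptoms of jumping onto
a coexisting branch near a fold. Folds are flagged by a sign change of
$\det J$ (equivalently of the tangent's parameter component) and refined by
Newton iteration on the augmented system $\{f = 0, \det J = 0\}$, which is
quadratically convergent, so refined locations are sharp to far below the
$10^{-6}$ reporting requirement.

On mirror-symmetric networks (swapping X↔Y and the two polarizing signals
leaves all parameters unchanged — `is_symmetric_network()`), the symmetric
branch $X = Y$ can lose stability through a *pitchfork* instead: the
swap-antisymmetric eigenvalue $\lambda_a$ of $J$ crosses zero. The tracer
monitors $\lambda_a$ on symmetry-invariant branch segments and refines
detected crossings on the two-unknown system $\{f_{sym} = 0, \lambda_a = 0\}$.
In asymmetric models only folds are reported; a broken-symmetry "pitchfork"
is then represented by the fold it unfolds into, which is how
`continue_pitchfork_pair()` continues pitchfork loci to positive polarizing
signal.

### Pitchfork criticality

`classify_pitchfork()` reduces the dynamics near a symmetric-branch
pitchfork to the antisymmetric amplitude $d = (X-Y)/2$ with the symmetric
mode $s = (X+Y)/2$ slaved (solved from the mean equation). The reduced
residual is odd, $r(d) = \lambda d + C d^3 + O(d^5)$, and the sign of the
cubic coefficient decides the case: $C<0$ supercritical (stable bifurcating
branches on the destabilised side only), $C>0$ subcritical (unstable
branches folding back with flanking saddle-nodes), $|C|$ below $10^{-5}$
indeterminate. $C$ is estimated by Richardson-extrapolated central
differences of $r$. A slower independent route (`method = "count"`) counts
fixed points just outside the pitchfork — five fixed points on the
doubly-stable side indicate the folded-back subcritical branches — and the
two routes are cross-checked in the test suite.

For the symmetric motif with mutual inhibition $-w$, auto-activation
$\omega_{aa}$ and common steepness $\sigma$, the slaving can be done in
closed form. Writing $c = \omega_{aa} + w$, $p = \omega_{aa} - w$ and using
the logistic identities $F'' = F'(1-2F)$, $F''' = F'(1-6F+6F^2)$ at the
pitchfork (where $\sigma c\, x(1-x) = 1$ fixes the state $x$):

$$C = \frac{F'''\,(\sigma c)^3}{6}
      \;-\; \frac{\sigma^4 c^3 p\,(F'')^2}{2\,(F'\sigma p - 1)}.$$

The first term is the direct cubic of the sigmoid; the second is the
feedback of the $d^2$-induced shift of the symmetric mode. Both depend only
on $(\sigma, w, \omega_{aa})$, which is what makes the criticality-transition
calibration below a one-dimensional root find.

### Two-parameter loci, cusps and region maps

`continue_fold_locus()` advances a fold point in a second signal by
natural-parameter continuation with a secant predictor and adaptive step
halving, stopping at the range boundary or when the singularity can no
longer be tracked. `continue_pitchfork_pair()` seeds the two folds that a
symmetric branch's pitchfork pair unfolds into at a small polarizing level,
advances both in lockstep with steps shrinking as the loci approach, and
estimates the coalescence (cusp) ordinate by extrapolating the two-thirds
power of the loci separation — near a cusp the fold separation scales as
$(q_c - q)^{3/2}$ — from the final approach points.

`count_attractors_map()` is deliberately continuation-free: at every point
of a two-signal grid it reruns the multistart Newton solver (batched across
the whole grid for speed) and stores the number of stable states and their
phenotype *signature* (the set of stable phenotypes in a canonical, fixed
label order, e.g. `"XSP+YSP"`). It therefore cross-checks the continuation
loci: the boundary of the multistable region must bracket them to grid
resolution, which the test suite asserts. `assemble_bidirectional()` stacks
two maps sharing the primary-signal axis — the first polarizing signal
plotted upward, the second downward — and `region_table()` partitions the
combined plane into maximal 4-connected constant-signature regions. A grid
point lying numerically on a locus takes whatever signature the solver
returns there; no smoothing is applied.

## Calibration of the shipped models

The generic and prototype models are shipped as `provenance = "calibrated"`
parameter sets, fit to the motif's published bifurcation points and
qualitative outcome tables rather than copied from a parameter listing.
The calibration is deliberately a small exact reduction rather than a
black-box fit:

* **Generic model 1** (symmetric core, no auto-activation). On the
  symmetric branch, a pitchfork requires $\sigma w\,x(1-x) = 1$, which fixes
  the two pitchfork states $x_\pm$ once the steepness $\sigma$ and
  inhibition magnitude $w$ are chosen; the branch equation
  $aS_1 + \omega_0 = \mathrm{logit}(x)/\sigma + wx$ then determines the
  primary-signal weight $a$ and basal weight $\omega_0$ *linearly and
  exactly* from the two target pitchfork locations ($S_1 = 0.704$ and
  $2.396$). The polarizing weight $b$ enters the drive only as $b\,S_2$, so
  it rescales the cusp ordinate exactly: $b = q_c/0.357$, with the cusp
  drive $q_c$ measured by a scan-based estimator (`cusp_drive_scan()`,
  independent of the continuation code) that tracks the shrinking bistable
  window and extrapolates its width$^{2/3}$. The design constants
  $\sigma = 2$, $w = 4$, $\gamma = 5$ were chosen once for a deep naive
  state ($X \approx 0.01$ at zero signal), clear expression margins in the
  single-positive states, and the motif's stated relaxation rate; they were
  not tuned against any test outcome. `calibrate_generic1()` reproduces the
  registry constants at run time and reports its residuals.
* **Generic model 2** (broken symmetry) perturbs generic model 1 with a
  basal bias toward X and a primary-signal bias toward Y (±8% on the signal
  weights, ±0.25 on the basal weights), a representative asymmetry that
  makes the two regulators upregulate at different thresholds and detaches
  the bistable region's cusps from the axis.
* **Generic model 3** (auto-activation motif). The criticality transition
  is pinned first: with the inhibition fixed at $w = 1$ (weak enough that
  $\sigma w < 4$, i.e. mutual inhibition alone cannot create bistability),
  the steepness solves $C(\sigma, 1, 1.8) = 0$ by bisection of the closed-form
  cubic coefficient above, so the pitchfork is supercritical below
  auto-activation weight 1.8 and subcritical above. The weights $a$ and
  $\omega_0$ then follow linearly from placing the weight-1.5 pitchforks at
  $S_1 = 1.7$ and $2.4$. The polarizing weight (2) was chosen so that at
  auto-activation weight 3.2 all eleven stability regions fall inside the
  default $S_{2,3} \in [0,1]$ window.
* **Prototype models 1–3** are hand-calibrated against their qualitative
  outcome tables (the compositions induced by each documented signal
  condition), keeping the motif topology of their influence diagrams. Two
  structural choices matter. In the Th1/Th2 model the GATA3 loop is the
  stronger auto-activation (2.6 vs 2.2), so committed Th2 cells hold GATA3
  under Th1-polarizing reprogramming (DP outcomes) and deleting the loop
  (the IL-4-feedback knockout, weight ×0.1) abolishes Th2 altogether. In
  the Th1/Th17 model the RORγt auto-activation is deep (3.2, well past the
  bistability threshold $\sigma\omega_{aa} = 4$) with weak T-bet→RORγt
  inhibition (−0.6), which gives the co-expression switch a wide bistable
  window: TCR + IL-23/IL-1 then yields robust XSP/DP mixtures while either
  polarizing signal alone leaves most cells naive. The iTreg/Th17 model
  uses strong symmetric auto-activation (3.0) with mildly asymmetric
  inhibition (−1.2 / −1.0) and primary weights (0.52 / 0.62), so the
  primary signal first splits cells iTreg/Th17, then opens the DP state
  (three-phenotype mixtures near 1.9 units), and at 2.5 units retires the
  Foxp3-single-positive state.

Two prototype-2 *prediction* rows are knowingly not reproduced at the
shipped parameters: a low dose (≈0.4 units) of TGF-β+IL-6 gives an
essentially homogeneous T-bet+ population rather than a Th1/Th17 mixture,
and lowering TCR after DP induction reprograms DP cells towards RORγt+
rather than T-bet+ (RORγt is held by its own deep auto-activation, T-bet by
TCR). Within this additive-influence motif the documented observations and
those predictions pull the same weights in opposite directions; the
observations won. Relatedly, a strong IL-23/IL-1 signal *alone* can switch
RORγt on in a minority of cells — the price of a deep RORγt loop — though
the population remains ≥90% naive.

## The population simulator

`sample_population()` models cell-to-cell variability as parametric
variation: every parameter of every cell is drawn independently from a
normal distribution centred on the basal ("average cell") value with
standard deviation $\mathrm{CV}\times|\mathrm{basal}|$, CV = 0.05 by
default. Parameters whose basal value is zero encode absent influences and
are never perturbed; steepness and relaxation rates are redrawn while
nonpositive. Defaults are 200 cells and composition grids of 40×40 signal
combinations; grids resample a fresh population per grid point, with
per-point seeds spawned deterministically from the master seed (the
alternative — one population reused across all points — is available as
`resample = FALSE`).

A simulation run is: equilibrate every cell from small initial activities
(0.01 per node) at zero signal to its own naive steady state (a cell that
does not rest in the naive phenotype is reported as a model error), then
apply a staged `signal_protocol()`, each stage integrating to rest
(max $|dX/dt| < 10^{-9}$, capped at 1000 time units) with states carried
over between stages. Carry-over is what produces hysteresis: a polarizing
pulse below the reprogramming threshold leaves every committed cell in
place, a supra-threshold pulse flips cells irreversibly. In
polarizing-first protocols the second stage specifies the full signal set,
i.e. the polarizing signal persists when the primary signal is added.

Population integration uses a fixed-step classical Runge–Kutta scheme
(dt = 0.02, an order of magnitude inside its stability region for every
shipped model) vectorised across cells, with the rest criterion checked in
half-time-unit blocks; single-cell work uses the adaptive livermore solver
with root-triggered termination, and the two are cross-checked against a
step-halved reference in the tests.

The generator emulates static parametric diversity only. Real
differentiating populations also have stochastic gene expression, cell
division and death, and cytokine-mediated cell-to-cell communication; all
are out of scope (the models describe the initial phase of differentiation
with compositions assumed frozen thereafter). Passing population tests
therefore demonstrate properties of the deterministic motif under
parameter spread, not of T-cell biology at large.

## Numerical choices and degenerate inputs

* Newton tolerance $10^{-12}$ on the fixed-point map; every reported steady
  state satisfies max $|dX/dt| < 10^{-8}$.
* Steady-state deduplication at $10^{-5}$ max-norm; lexicographic ordering.
* Rest criterion $10^{-9}$ on max $|dX/dt|$; stage cap 1000 time units,
  both configurable and reported.
* Continuation: initial step $10^{-2}$, bounds $[10^{-6}, \mathrm{range}/25]$,
  corrector tolerance $10^{-11}$; special points refined by Newton on their
  defining systems.
* Cusp coalescence declared at loci separation $10^{-4}$, ordinate by
  width$^{2/3}$ extrapolation.
* Signal saturation is off by default; the optional per-signal hook uses a
  Michaelis–Menten form $s \mapsto s_{max} s/(K+s)$. The saturating form
  itself is an implementation choice (the motif literature shows only that
  saturation can prevent the DP state), so it is exposed as configuration,
  never silently applied.
* Branch continuation takes signal names as free parameters; sweeping a
  structural weight (e.g. the generic-3 auto-activation) is done by
  re-instantiating the network per weight, which the exposed
  `auto_weight` override makes one line.
* Starting states outside the unit box are clipped with a warning; empty
  result sets write header-only CSVs; CSV numerics carry 12 significant
  digits so reruns from a manifest's seeds are byte-identical.

## Problem sizes

The test suite runs region maps at 101×101 (the full default), population
grids at 20×20 with 50 cells, single-condition compositions at 100–200
cells, and 20 master seeds for the across-seed symmetry check; these sizes
give every assertion comfortable statistical margin while keeping the suite
fast. The 40×40×200 defaults match the documented study conditions and are
what `composition_grid()` and the CLI produce out of the box.

## Known limitations

* Pitchfork machinery assumes the two-regulator mirror symmetry; larger
  symmetric networks would need a generalised invariant-subspace test.
* No Hopf/limit-cycle machinery: the motif's dynamics are gradient-like,
  and the random-network test generators stay in the monotone class where
  basin mapping is well posed.
* The criticality classifier returns `indeterminate` at (near-)degenerate
  pitchforks rather than guessing.
* Weight asymmetries larger than the calibrated prototypes' have not been
  validated against the acceptance oracles; the registry models are the
  supported parameter sets.
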