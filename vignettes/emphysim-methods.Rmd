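---
title: "Methods: the emphysim model of emphysema onset and progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the emphysim model of emphysema onset and progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emphysim)
```

`emphysim` couples three model layers — a well-mixed immune/remodeling ODE
system, a grid-based agent model, and a plane-stress finite-element model —
to simulate how smoke-particle exposure destroys alveolar tissue and how
that destruction appears on CT as falling mean lung density. This vignette
explains each layer, the parameters that matter, the numerical choices, and
what the accompanying tests do and do not demonstrate.

## The well-mixed immune model

The molecular layer tracks thirteen state variables: undifferentiated
macrophages (`Mun`), pro-inflammatory `M1` and repair-type `M2` macrophages,
the cytokines IL-10, TNFα, IL-1, TGFβ, IL-8, fibroblasts `F`, collagen `C`,
matrix metalloproteinase `MMP`, neutrophils `N` and elastase `El`. The
structure is classical wound-healing dynamics:

* Monocytes are recruited at the cubic rate
  M(Tα) = 0.335 Tα³ − 6.309 Tα² + 32.281 Tα + 57.302 cells/day, a fit to
  chemotaxis data. At Tα = 0 the resting influx (57.302 cells/day) balances
  emigration (μ = 0.2/day), giving the baseline pool
  Mun\* = 286.51 cells used as the default initial condition.
* Polarization is Hill-mediated: IL-1 and TNFα activate M1, IL-10 activates
  M2, each saturating as x/(x+c) with promotion constants of 10, 10 and
  5 pg/ml. M1↔M2 transitions are reversible (k_m12 = 0.075, k_m21 =
  0.05/day).
* IL-10 inhibits cytokine production through the complementary factor
  c/(x+c). Two distinct constants exist: IL-10 self-inhibition uses
  c₁ = 100 pg/ml, while IL-10's inhibition of TNFα/IL-1 secretion uses its
  own constant c = 25 pg/ml. The published equations reuse one symbol but
  the parameter table lists both roles separately; we follow the table and
  keep them as independent configuration entries, so setting `c = c1`
  recovers the single-constant variant.
* TGFβ (from M2 and fibroblasts) drives fibroblast proliferation through a
  second cubic, F_g(Tβ) = 0.05 Tβ³ − 0.98 Tβ² + 6.54 Tβ + 7.11. As printed
  this growth law is exponential whenever k₁₀·F_g(Tβ) > d_F, which it is for
  any positive TGFβ; we implement it as printed and guard integrations with
  an overflow abort at 10¹² naming the offending component. Fibroblast
  apoptosis d_F = 0.12/day is kept distinct from the MMP–collagen cleavage
  coefficient d_FC (default 10⁻³ ml/pg/day, an estimate): the parameter
  table labels the 0.12 value as apoptosis even though the collagen/MMP
  balance equations reuse the cleavage symbol.
* Neutrophils are recruited by IL-8 with carrying capacity N_max. The
  published table gives the IL-8 "recruitment" constant in concentration
  units (8 pg/ml); we read it as the Hill constant of the recruitment term
  and expose the recruitment magnitude separately (`k14rate`, default
  10 cells/day). Neutrophils release elastase, which degrades elastin.

Constants with no published value (μ_N, d_IL8, c₂, N_max, d_E, d_FC,
`k14rate`) carry documented estimates, flagged in
`attr(immune_params(), "estimated")`, generally mirroring the analogous
published constant (e.g. μ_N = μ = 0.2/day, d_IL8 = d_IL10 = 2.5/day).

### Integration

`wm_integrate()` defaults to `deSolve::lsoda`: the fibroblast growth term
(k₁₀·F_g ≈ 6.6/day at rest) and the fast TNFα turnover (d_Tα = 55/day) make
the system moderately stiff. A fixed-step explicit Euler scheme is also
provided; it is the discretization the agent-based model is checked against.
Any component pushed below zero by discretization is clamped to zero and the
event counted in the trajectory's `clamped` attribute.

## The agent-based tissue model

`ab_run()` puts the same rates on an `rows × cols` grid of alveolar-unit
cells, each holding tissue life (structural integrity in [0, 1]), normalized
elastin and collagen content, local cytokine concentrations, deposited
particles and resident cell agents. Space adds what the well-mixed model
cannot express: localized deposition, diffusion, per-cell damage and matrix
composition.

A few deliberate conventions:

* **Smoking signal.** A square wave with period 10 steps and duty 0.5;
  during "on" steps within the total smoking time `T_s`, `e_s` particles
  deposit on uniformly random cells. After cessation the model runs
  `post_steps` (default 20) further steps.
* **Unit volume.** Each grid cell is a unit well-mixed volume, so a
  secretion rate in pg/cell/day contributes pg/ml/day per resident agent;
  the rate equations define no reference volume, so this is the simplest
  dimensionally consistent choice.
* **Agents as per-cell counts.** Agents of one kind in one cell are
  exchangeable (no rule reads an individual's age), so populations are
  stored as per-cell count matrices and updated with exact multinomial
  draws; `ab_agents()` materializes the individual view. Deterministic mode
  replaces every draw by its expectation.
* **Movement.** Every mobile agent steps to a uniformly random 4-neighbour;
  where local TNFα exceeds its Hill constant the step instead goes to the
  highest-TNFα neighbour (chemotaxis up the gradient, first index wins
  ties). Update phases run in a fixed documented order and all randomness
  flows from one seeded generator, so equal seeds give bit-identical runs.
* **Diffusion.** Optional explicit 4-neighbour diffusion (default
  D = 0.1 cell²/step, stable up to 0.25), mass-conserving with zero-flux
  borders; D = 0 recovers strictly local dynamics.
* **Decay discretization.** With dt = 0.1 day the TNFα decay satisfies
  d_Tα·dt = 5.5, far outside the stability region of linear Euler decay.
  Concentration decay therefore uses the exact factor exp(−d·dt) by
  default. A `decay = "euler"` mode instead evaluates every phase increment
  on the step-start state, making the composite step exactly one explicit
  Euler update — on a 1×1 deterministic grid the agent model then
  reproduces the well-mixed Euler trajectory to numerical round-off, which
  is how cross-scale consistency is tested.
* **DAMPS damage.** Tissue life falls at
  k_damps·dt·½(hill(IL1) + hill(TNFα)); the mean of the two
  pro-inflammatory activations is the simplest symmetric "inflammation
  level". A cell at zero life is destroyed, irreversibly. Damaged cells
  secrete TGFβ in proportion to their damage (rate λ = 5·10⁻⁶ pg/cell/day),
  recruiting fibroblasts for wound healing.
* **Matrix bookkeeping.** Collagen follows the deposition/cleavage balance
  with the normalized fraction c_cl = min(C/C₀, 1) (C₀ = 100 µg per cell);
  elastin declines as dc_el/dt = −k_eldeg·El·c_el (k_eldeg = 0.05 ml/pg/day)
  with no resynthesis — elastin loss in adult lungs is effectively
  permanent.

### Calibration of the exposure response

The spatial constants that the grid model adds — the per-particle TNFα
source `s_p`, the damage rate `k_damps`, the phagocytosis probability
`p_clear` and the influx scale — have no published values. They are
calibrated, once, to the qualitative exposure behaviour the model must
reproduce: zero exposure leaves tissue untouched indefinitely, while *every*
nonzero design point of the exposure grid (exposures 5–20 particles,
smoking times 10–90 steps) destroys at least half of the tissue, including
the mildest corner (5 particles, 10 steps, i.e. 25 particles total and only
3 simulated days).

The frozen defaults are `s_p = 2·10⁵` (a particle-laden cell and its
immediate diffusion ring sit in the saturated region of the TNFα Hill
response after decay), `k_damps = 5/day` (a saturated cell dies in about
5 steps), `p_clear = 0.1` (clearance of insoluble smoke particles by
alveolar macrophages is slow relative to the damage timescale), and an
influx evaluation cap at TNFα = 10 pg/ml — the recruitment cubic has a
local maximum near 3.6 pg/ml and grows as Tα³ beyond its fitted range, so
evaluating it at the extreme concentrations particles induce would flood
the grid with macrophages on pure extrapolation. With these values the
residual tissue life at the mildest design point is limited by the spatial
coverage of the deposited particle crosses (a particle damages its cell and
its diffusion ring), which is what makes the response strict for every
nonzero exposure. A consequence worth stating plainly: the destruction
timescale is compressed — heavy exposures can pass the 80 % damage gate
within one or two simulated days. The model's "days" are effective model
time, not a claim about clinical progression rates.

## The mechanical model

`solve_elasticity()` implements small-strain plane-stress linear elasticity
(thin-tissue assumption, global Poisson ratio 0.3) on a structured mesh of
bilinear quadrilaterals, one element per grid cell. Element stiffness uses
2×2 Gauss quadrature; assembly is sparse; strains are evaluated at element
centroids. The breathing load is displacement-controlled: boundary nodes
follow a uniform strain field of magnitude `eps_app` (default 0.05, the
order of tidal breathing), biaxial by default. Damaged regions could be
remeshed adaptively with an external mesher; we instead keep the fixed
grid-equivalent mesh and assign destroyed cells a modulus of 1 Pa, which
the dead-cell rule makes consistent — destruction changes material, not
topology. Contour extraction
(`extract_damage_contours`: 3×3-cross morphological closing, 4-connected
labelling) is retained for lesion reporting only.

Alive elements take the composition modulus
E = 0.7·c_el·0.1 kPa + 0.3·c_cl·20 kPa (6070 Pa at full content). Rupture
compares each element's maximum principal strain with the normalized linear
blend of the phase failure strains, (c_el·1.0 + c_cl·0.1)/(c_el + c_cl);
matrix-free cells conservatively get the collagen limit. The literature
pins down only the two endpoint failure strains, not how a mixed
composition combines them — the normalized linear blend is our concrete
choice, and it makes the
healthy limit 0.55, an order of magnitude above the applied strain, so
healthy tissue never ruptures spuriously.

One property worth recording: under displacement-controlled loading,
softening an element can only increase the strain *that element* carries,
but it can *decrease* the global maximum (the softened element soaks up
strain and relieves the previous peak). The test suite therefore asserts
the local monotonicity property, together with patch tests, symmetry, and
agreement with an independently coded dense assembly on small meshes.

## Coupling

`run_coupled()` alternates agent bursts (default 10 steps = 1 simulated
day) with mechanical solves. Each cycle: gate on damage (skip the solve and
stop once 80 % of the area is destroyed), export composition to materials,
solve, mark over-strained cells destroyed, resume. The exchange is
in-memory; histories record damage, mean life, peak strain and rupture
counts per cycle.

## The CT-patch layer

One CT voxel at the modeled scanner geometry (0.78 × 0.78 mm pixels,
1.25 mm slices) contains 170 alveoli/mm³ × 0.7605 mm³ ≈ 130 alveoli,
rounded to tens; its computational grid is the most-square factorization
13×10. `simulate_patch_progression()` segments parenchyma at −750 HU
(air-rich side), samples seed pixels, expands them by their in-mask
4-neighbours, runs one coupled job per affected pixel, and linearly remaps
each job's final mean modulus to attenuation, anchored at the healthy
modulus (6070 Pa → original HU) and air (0 stiffness → −1000 HU). The remap
is monotone and clipped so progression can only darken a pixel; MLD is
always quantified over the baseline mask.

### The synthetic patch generator

`synth_patch()` stands in for a clinical patch database; it is explicitly
synthetic and its parameters are generator choices. Healthy patches are
Gaussian parenchyma texture (−820 ± 40 HU) with a fixed number of bright
vessel streaks (above −500 HU, hence excluded by segmentation); moderate
and severe patches add 5 and 15 disk-shaped low-attenuation clusters pushed
toward −980 HU with radii 2–4 and 3–8 px, emulating the growing
low-attenuation areas of progressing emphysema. What the generator does
*not* emulate: reconstruction-kernel texture, airway walls, gravity-
dependent density gradients, inter-patient variability of baseline density,
and annotation noise. Tests passing on synthetic patches therefore show
that the pipeline's direction and statistics behave correctly, not that the
model reproduces absolute clinical HU differences — reproducing a specific
database's 40–60 HU group gaps is explicitly out of scope.

## The experiments

* **Exposure grid** (`run_exposure_experiment`): exposures {0, 5, 10, 15,
  20} × smoking times {10, 30, 50, 70, 90} — the published design states
  the two ranges and a total of 25 runs; five evenly spaced levels per axis
  is the unique matching choice. Three seeds per design point on 13×10
  grids; residual mean tissue life in percent is the outcome. The
  zero-exposure column is an exact invariant (100 %), not a statistical
  one.
* **Parameter screen** (`run_parameter_experiment`): the published 16-row
  fractional factorial over k₈, d_IL10, k₁₂, k₁₃, d_F and d_M, at fixed
  medium exposure (10 particles, 50 steps). Replicates use common random
  numbers — the same seed stream for every row — so between-row spread
  isolates parameter effects, the standard variance-reduction practice in
  sensitivity screening. The factorial's k₈ levels (0.7/0.14) are used
  exactly as published even though the rate table lists k₈ = 0.07; the
  screen explores ranges, not baselines, and the column labelled with the
  cleavage symbol maps to fibroblast apoptosis d_F, consistent with the
  rate table's label. The summary statistic is the SD across the 16 rows of
  mean tissue life at each step, averaged over steps; the published
  absolute value of this statistic depends on unstated grid and time-step
  scales, so the package asserts the bounded-variability property (below
  10 % of initial tissue life) rather than a number. Under the calibrated
  exposure-dominated regime the six screened constants steer cytokine and
  matrix chemistry but barely touch the TNFα-driven damage pathway, so the
  between-row variability of tissue life is very small — the same
  "results all very similar" outcome the screen is meant to detect.
* **MLD progression** (`run_mld_experiment`): synthetic healthy patches,
  baseline vs. post-simulation MLD, Welch two-sample test. Desk scale: 20
  patches × 15 seeds (≈ 70 affected pixels, hence ≈ 70 coupled jobs per
  patch); a clinical-scale run would use 200 seeds per patch. These sizes
  are the package defaults for the experiment drivers and complete in
  minutes on one CPU.

## Degenerate inputs and tie-breaks

Zero-duration integrations return the initial state; empty masks and empty
groups error; all-dead grids skip the mechanical solve via the damage gate;
matrix-free cells get the conservative collagen strain limit with a
warning; moduli above the healthy reference clip to the original HU with a
warning; chemotaxis ties resolve to the first neighbour index; multinomial
splits cap total per-step probabilities at 1.

## Known limitations

* 2D only; no airway/vessel structures inside a job's grid; no 3D
  connectivity.
* Linear isotropic elasticity; no hyperelastic or poroelastic behaviour,
  no dynamics.
* The boundary conditions, Poisson ratio and strain magnitude of the
  original mechanical runs are unreported; ours are documented defaults.
* The calibrated damage constants compress time; absolute timescales and
  absolute HU shifts are not interpretable clinically.
* No parameter inference against experimental cytokine data; the rate
  constants are literature point estimates.
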