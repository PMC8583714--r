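---
title: "Model and methods: simulating rate-varying distraction osteogenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: simulating rate-varying distraction osteogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dosim` simulates bone regeneration during distraction osteogenesis (DO) by
coupling an axisymmetric viscoelastic finite-element model of the
osteotomised bone to a fuzzy-logic mechano-regulatory controller of tissue
differentiation. This vignette is the package's own account of the model:
what is assumed, which parameters matter, which design choices were
genuinely open and how they were resolved, and what the shipped tests do
and do not demonstrate.

## 1. The physical model

### Geometry and discretisation

The bone is a cortical tube (endosteal diameter 12 mm, periosteal 16 mm)
with a transverse osteotomy gap (1 mm at surgery) and marrow-filled
fragments of 30 mm modelled length per side. The domain is meshed with
structured bilinear 4-node axisymmetric quadrilaterals (2×2 Gauss
integration, full 2π circumference so reactions are true newtons). The
callus occupies the gap over the cortical annulus (r ∈ [6, 8] mm); the
medullary part of the gap is not modelled by default (`external_callus`
extends the callus over the cavity but is untested against the reference
configuration). Default element sizes are 0.25 mm in the callus and
0.5 mm in bone, so the initial gap always carries at least four element
rows; the comparison studies in the test-suite use a 0.5/1.0 mm "study
mesh" to keep three full runs within a couple of minutes.

Before every distraction increment the callus is remeshed to the new gap
and all per-element fields (tissue concentrations, perfusion, necrotic
fraction, residual stresses, viscous branch stresses) are mapped over with
a Gaussian sampling-and-weighting scheme. The weights are normalised
(constant fields transfer exactly; values stay within the convex hull of
their sources), regions never exchange state, and an exact coordinate hit
short-circuits to that sample so unchanged mesh parts pass through
identically.

### Where the new tissue appears

Each increment adds regenerate volume. Three accountings are implemented
(`new_volume`): the default, `"center"`, keeps the lower half of the old
callus anchored, translates the upper half with the moving fragment, and
initialises the inserted band at mid-gap to unperfused connective tissue.
This is where regenerating tissue actually appears — the fibrous interzone
sits mid-gap with mineralisation fronts advancing from both fragment ends —
and it reproduces the edge-first perfusion and bone pattern. `"stretch"`
(homogeneous dilation with proportional dilution towards virgin tissue) and
`"slab"` (all new volume at the moving end) are retained for sensitivity
studies; the slab variant concentrates all regeneration on one front,
which is not what radiographs of transported segments show.

### Constitutive behaviour

Callus stress relaxation is modelled with a Prony series on the deviatoric
response (bulk elastic; `bulk_relax` applies it to both), integrated with
the recursive exponential branch-stress update, which is exact for
relaxation under constant strain. The default branch set
(g = 0.396/0.542, τ = 10.775/977.88 s) is the two-term representation of
the in vivo daily relaxation law; `fit_prony()` re-derives it from any
sampled curve. The daily relaxation law itself (`relaxation_force()`)
is a three-branch Maxwell model plus equilibrium term whose amplitudes grow
exponentially with the distraction day, reflecting the stiffening
regenerate; its long-time plateau is 6.6 % of the peak, consistent with
the 6.23 % residual-force rule (`residual_force()`).

`fit_prony()` pins the equilibrium fraction to the fully relaxed tail of
the curve by default — the conventional treatment when the measurement
reaches its plateau, and the only reading under which the fitted long-time
fraction agrees with the residual-force rule; `equilibrium = "free"` gives
the unconstrained fit.

During **distraction events** the whole callus is assigned the
day-dependent empirical law: stiffness from the day's peak force per unit
increment acting over the gap column, Prony branches from the library
(`distraction_material = "empirical"`). This choice reproduces the
near-uniform r/l strain state of the distracted interzone. The
alternative (`"mixture"`) assigns each element its tissue-mixture
properties, which concentrates every increment into the softest layer —
numerically well-defined but it makes each freshly inserted band absorb,
and be destroyed by, the whole increment, an artefact of resolving the
interzone with a strain-threshold controller at element resolution.

During **consolidation** the construct carries a daily 500 N axial load
through a rigid top plate with the fixator spring in parallel, and every
element uses its mixture properties: Young's modulus by the cube-root rule
`E = (Σ cᵢ Eᵢ^{1/3})³`, Poisson ratio linear, Prony weights scaled
linearly to zero as the mineralised fraction reaches 100 %. Default
elastic constants (MPa / –): connective 3 / 0.30, cartilage 10 / 0.45,
woven bone 4000 / 0.36, cortical 20000 / 0.30, marrow 2 / 0.17 — standard
fracture-healing values; with them the fully ossified 15 mm regenerate
moves ≈ 0.02 mm under 500 N once the fixator is calibrated (below), the
published healed-state plateau.

### Fixator

The fixator is a spring fixed at the bottom surface and rigidly linked to
the top fragment surface, active only during consolidation (during
distraction the applied displacement dominates the mechanics). Its law is
linear by default (a monotone piecewise-linear table is accepted);
`calibrate_fixator()` finds the stiffness for which the all-connective,
fully distracted 15 mm construct moves by 0.5 mm under 500 N — the
dynamic-fixation condition that anchors the model — and that single
calibration is shared by all protocols in a comparison.

## 2. The regulation model

Seven per-element state variables drive differentiation: |ε| (dilatational
strain magnitude, %), γ (octahedral shear, %), perfusion, cartilage and
bone concentration, and Gaussian-neighbourhood perfusion and bone
(kernel width σ = one callus element size, 3σ cutoff, self excluded;
cortex and marrow participate as sources, which is how regeneration seeds
from the fragment edges). Strains are read at the end of the load ramp
(the peak stimulus of the event). Inference is Mamdani: min-conjunction,
max-aggregation, centroid defuzzification over symmetric triangular output
sets {negative, zero, low, high}, scaled by per-process maximum daily
rates.

The 13-rule default table encodes: angiogenesis in the favourable window
(0.01 < ε < 3.4, γ < 15) from vascularised neighbours, slow angiogenesis
at rest and under moderate shear; vascular damage at jointly high
invariants and at γ > 30; intramembranous ossification in perfused,
bone-adjacent tissue within the window, maturation at rest; chondrogenesis
under moderate shear (15 ≤ γ < 20) or excessive volumetric strain;
endochondral calcification of cartilage at the ossification front
(neighbour bone and perfusion present) and of perfused cartilage under low
shear; and destruction when ε > 3.4 and γ > 20 together (`destruction =
"either"` makes each sufficient). Memberships hold full value across each
stated window with 10 % tapers outside it — the windows are where the
processes run at full strength, not where they begin to fade.

Three deliberate asymmetries, each open in the underlying quantitative
constraints and resolved here on mechanobiological grounds:

* **Destruction is tension-only by default.** The damage thresholds derive
  from tensile distraction injury. Applied symmetrically to |ε|, the last
  soft interzone layers under the daily compressive load (≈ 35 % strain)
  would be re-destroyed every day and the gap could never bridge — under
  any protocol — contradicting the healed-state observations the model is
  anchored to. Cyclic compression of soft interzone tissue drives
  chondrogenesis (the endochondral route), not rupture; vascular
  inhibition remains symmetric, and `compressive_destruction = TRUE`
  restores full symmetry.
* **Destruction leaves a necrotic fraction, not a clean reset.** A
  destroyed element reverts to unperfused connective tissue with damage
  fraction 1. The damaged fraction cannot regenerate (fully gated above
  0.5, proportionally below), is diluted as new matrix is deposited, and
  is cleared at 3 %/day, accelerated up to five-fold by neighbourhood
  perfusion (debris next to the vascularised cortex resorbs within days;
  avascular mid-gap scar persists for weeks). Without this memory,
  destroying still-undifferentiated tissue is consequence-free, and the
  cost of aggressive early distraction — the central clinical phenomenon —
  vanishes from the model. The strain histories of low-rate and high-rate
  schedules cross every damage threshold at gap sizes proportional to the
  rate, i.e. at nearly identical *times*; what distinguishes them is the
  *volume* of tissue ruptured, and only a volumetric debt with slow
  clearance lets that difference reach the consolidation phase.
* **Endochondral calcification ignores the local strain level.** The
  strain-localised interzone sits above the intramembranous window
  precisely because it is soft; cartilage that forms there calcifies at
  the advancing front (neighbour bone + neighbour perfusion), stiffens,
  and thereby lowers its own strain into the angiogenic window. Gating
  calcification on locally favourable strain deadlocks the model short of
  bridging.

Bookkeeping: new cartilage is recruited from connective tissue; new bone
from cartilage first when the calcification consequent fired, then from
connective tissue; destruction resets the element; concentrations are
renormalised to sum to 100 (conserved to 10⁻⁶ throughout every run, as the
property tests check).

## 3. Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| distraction rates (L/H) | 1 / 2 | mm/day | protocol grammar, two actions 12 h apart |
| latency | 4 | days | no regeneration before distraction starts |
| total transport | 15 | mm | fixed across the protocol family |
| bridging threshold | 0.05 | mm IFM | operational definition of bony union |
| consolidation load | 500 | N | daily physiological axial load |
| fixator calibration target | 0.5 | mm IFM | dynamic-fixation anchor condition |
| max daily rates (perfusion/cartilage/bone) | 3 | %/day | calibrated once so the control run fully ossifies on the ~12-week experimental timescale |
| damage clearance | 0.03 (×1–5 with perfusion) | fraction/day | weeks-scale scar resolution, days-scale near vessels |
| damage gate | 0.5 | fraction | debris must be largely cleared before regeneration |
| kernel σ (biology / transfer) | 1 element | mm | growth propagation range / mapping width |
| element size (callus/bone) | 0.25 / 0.5 | mm | ≥ 4 rows across the initial gap |
| ramp / hold discretisation | 10 / 20 steps | – | resolves the 1 s ramp and both relaxation time constants over the 12 h hold |

Regulation cadence follows the loading events: two steps per distraction
day (after each increment, each worth half a day of the daily rates), one
per consolidation day. Runs stop at day 120 or seven days after bridging
once the IFM has plateaued (|ΔIFM| < 10⁻³ mm).

## 4. Numerical choices

Small-strain kinematics per event, with the geometry update absorbed by
remeshing. Direct sparse Cholesky solves; Newton iteration couples the
(possibly nonlinear) spring with tolerance ‖R‖ ≤ 10⁻⁶ × load. The
constant-strain patch test passes to machine precision on the structured
(graded-rectangle) meshes the package generates; 2×2 quadrature of the
hoop terms is exact there. The viscoelastic update matches the closed-form
ramp-and-hold relaxation response to 10⁻⁴ relative. Residual stresses are
carried between distraction events (as a permanent stress plus decaying
branch stresses); the daily consolidation solve starts from a zero
viscoelastic state, since its load is transient and carrying its permanent
strain would accumulate spurious compression. Degenerate geometries, zero
stiffness elements, non-convergent fits and non-positive Jacobians are
rejected with diagnostics; FE failures mid-run surface the day and action
index after checkpointing when a checkpoint directory is set.

## 5. What the study conditions do and do not emulate

The shipped defaults *are* the reference study conditions: the 12/16 mm
sheep metatarsus geometry, 1 mm osteotomy gap, 4-day latency, twice-daily
distraction to 15 mm, 500 N daily consolidation load, 0.5 mm initial IFM
calibration, and the day-indexed relaxation law. On the 0.5 mm study mesh
the control protocol bridges on day 56 with an IFM plateau of ≈ 0.022 mm,
and the acceptance suite verifies the headline ordering — L11H2 bridges no
later than control, H4L7 later — together with the edge-before-mid-gap
perfusion pattern at the end of distraction.

Known limitations, stated plainly:

* Under the reconstructed rule base the low-to-high schedules *tie* with
  the control rather than strictly beating it: their two-day head start is
  spent while the early damage is still clearing. The delay of high-to-low
  schedules (the damage-volume effect) is robust; the strict low-to-high
  improvement evidently depends on details of the original rule base that
  the quantitative windows alone do not pin down.
* Bridging day is mesh-sensitive at the resolutions practical here (the
  half-size mesh bridges about a week later than the study mesh); protocol
  *orderings*, not absolute days, are the quantity to trust.
* The model is 2-D axisymmetric: no periosteal bulge beyond the cortical
  radius, no fixator pin mechanics, no contact, no poroelastic fluid flow,
  no growth-factor or cell-population biology. Tension/compression
  asymmetry is reduced to the sign of ε.
* Tissue destruction, clearance and the membership geometry are
  reconstructions constrained by the published windows and endpoint
  behaviour, not a replication of any unpublished rule table; the whole
  rule base is a config artifact (`rule_base()`) so alternative published
  sets can be dropped in.

Passing tests therefore demonstrate internal consistency, the numerical
oracles, and reproduction of the anchor observations under these study
conditions — not validation against new animal data.
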