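---
title: "An energy-based subcellular element model of the wing disc cross-section"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An energy-based subcellular element model of the wing disc cross-section}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`episce` simulates a 2D cross-section of a pseudostratified columnar
epithelium patterned after the larval *Drosophila* wing imaginal disc: a
row of columnar cells (apical side up), a squamous (peripodial) layer
above, boundary cells capping the two ends, and two extracellular-matrix
(ECM) chains — one under the columnar basal surface, one over the
squamous layer.  Every component is discretized into nodes (membrane,
nucleus, ECM), and node positions evolve by overdamped Langevin dynamics
with the stochastic force set to zero,

$$C \,\dot{\mathbf x} = -\nabla E,$$

with a damping coefficient per node class (all 1 by default; time is
measured in units of damping × length² / energy).  The potential `E`
sums, per Table-1-style term:

* membrane elasticity, springs `½ k_memb (L − L0)²` along each cell's
  node cycle, plus quadratic bending `½ k_memb,bend (θ − θ0)²` at each
  membrane triplet (rest geometry from the constructed shape);
* apical and basal actomyosin contractility, springs linking laterally
  opposed membrane-node pairs above / below the nucleus
  (`k_api,cont`, `k_bas,cont`), including the basal-most and apical-most
  (corner-level) pairs so that contraction shortens the apical/basal
  surfaces themselves;
* cytoplasmic area conservation `E_vol = k_vol (Ω − Ω₀)²` per cell
  (areas are the 2D realization of cell volume; the printed form has no
  ½ prefactor and none is used);
* volume exclusion by truncated Morse potentials
  `U e^{−d/ξ} − W e^{−d/γ}` between membrane–membrane (across cells),
  nucleus–membrane, nucleus–nucleus and node–ECM pairs; the
  nucleus-size term is the attractive nucleus–nucleus potential within
  a cell, which holds the small nucleus node ring together;
* E-cadherin cell–cell adhesion (lateral), columnar–squamous adhesion
  (apical) and Integrin cell–ECM adhesion (basal) as nearest-partner
  springs; ECM chains carry stretching springs and cosine bending
  `k_ecm,bend (1 − cos(θ − θ0))` with straight rest angle.

The forces are analytic negative gradients of the same expression
(verified against central finite differences in the test suite), and the
integrator is explicit Euler.

## Numerical choices

* **Truncation/shift.** Morse terms are truncated at a per-class cutoff
  (≥ 3× the larger decay length) and shifted by their cutoff value so
  the energy is continuous when pairs cross the interaction range;
  forces inside the cutoff are unchanged.
* **Pair bookkeeping.** Exclusion pairs are found with a skin margin
  (0.3) and rebuilt on a cadence, so the pair set is exact while
  displacements stay below the skin.  Basal (Integrin) adhesion bonds
  persist until stretched beyond `max_range`; lateral and apical
  adhesion re-pairs by nearest partner.  Distance ties — which occur
  exactly on the symmetric built lattice — are broken by
  mirror-symmetric rules (partner of the nearest cell center, then the
  partner nearest the tissue midline), so pairing never injects
  left–right asymmetry.
* **Stability.** The default `dt = 0.002` keeps per-step displacements
  well under the smallest rest length; `step()` raises a stability error
  beyond a safety fraction of it.  The simulation driver enables
  per-node displacement clamping instead, so brief strong contacts
  (mitotic rounding, fresh daughters) do not force a globally smaller
  step.
* **Quasi-static equilibration.** Shape scenarios ask for equilibria,
  not transients; the driver reaches them with FIRE (inertia-accelerated
  minimization of the same energy — identical minima, non-physical
  path).  The physical Euler trajectory approaches the same state but
  needs roughly an order of magnitude more steps: from a flat start the
  lateral/medial curvature ratio decays toward the FIRE equilibrium
  value as the arc propagates inward from the free ends.  Growth
  scenarios, where division timing lives on the physical time axis, use
  the Euler integrator throughout.
* **No anchors.** All forces are internal, so net force and torque
  vanish identically and the tissue neither drifts nor spins; anchoring
  the boundary-cell ends (an alternative we rejected) geometrically
  suppresses the global bending mode.

## Parameters

Lengths are in columnar-cell widths, the energy unit is arbitrary.  The
published source for this model reports that spring-level constants were
calibrated against experiments, but their numeric values are not
available here; the defaults below were calibrated once so that the
model reproduces the qualitative behaviours used for validation, and are
not tuned per scenario.

| parameter | default | meaning |
|---|---|---|
| `k_memb` / `k_memb,bend` | 30 / 2 | membrane stretching, bending |
| `k_squamous` (+ bend 5)  | 8 | softer squamous (peripodial) membranes |
| `k_api,cont`, `L0` | 0.6, 0.3 | apical contractile springs |
| `k_bas,cont`, `L0` | 5, 0.15 | basal contractile springs (dominant) |
| `k_vol` | 30 | area-constraint strength |
| `k_adhL`, `k_adhA`, `k_adhB` | 8, 1, 8 | lateral / apical / basal adhesion |
| `k_ecm`, `k_ecm,bend` | 1, 0.5 | soft, bendable basal ECM |
| Morse `mm` | U 0.6, ξ 0.06 | membrane–membrane exclusion |
| Morse `nm` | U 3, ξ 0.16 | nucleus–membrane exclusion (sets nuclear size) |
| cell geometry | 1 × 4 | width × height; 4/8/4 segments per edge; 3 nucleus nodes |

With basal contractility dominant, a flat tissue's energy minimum is a
uniform arch of keystone-shaped cells: the basal surface shortens
against the compliant ECM while the apical surface widens against the
soft squamous lid.  Medially raising the apical-to-basal contractility
ratio, or medially stiffening the ECM (`k_ecm,c`, scaling both the
chain's stretching and bending — a stiffer matrix is stiffer in both
moduli), flattens the medial domain, reproducing the
older-disc morphology.

Growth parameters (`growth_params()`): the cycle rate δ = 0.08 (cycle
length 12.5 time units), area growth ε = 0.2 capped at 1.45 × Ω₀
(< 2×, because the cross-sectional area does not double when the 3D
volume does), rounding threshold `GP_mit` = 0.86, constriction front
rate h = 3, constriction stiffness boost 4×, volume-exclusion boost 2×.
`h` is set so every basal constriction spring activates well before
division; division then occurs at GP = 1.

## What the scenarios emulate — and what they do not

The scenario presets rebuild the study conditions at desk scale: 20
columnar cells, coarse node counts, a few thousand equilibration steps.
They reproduce, qualitatively, bent-control morphology, medial
flattening under patterned contractility and ECM stiffness, basal
nuclear bias under medially raised apical contractility, interkinetic
nuclear migration during mitotic rounding, and the
proliferation–curvature coupling with compartment-specific cycle
lengths (posterior cycle length 400% or 50% of anterior; buffering
with posterior +50% proliferation plus k_adhB +50%, k_ecm,c +100% or
k_api,cont +300%).

For the growth scenarios, initial cycle phases are drawn
mirror-symmetrically (so a homogeneous division rate gives a
posterior/anterior ratio near 1 by construction) and divisions stay in
the cross-section plane (`p_inplane = 1`); the out-of-plane branch —
target-area restoration by `Ω₀^new = Ω₀^postdiv − εT` — is fully
implemented and unit-tested, but a cross-section scenario measuring
in-plane crowding is cleaner with every division contributing.
Daughters are born with their created polygon area as the momentary
area target, which then ramps to the class target through the normal
growth law: an instantaneous jump to the class target would inject a
large pressure impulse into the integrator without changing the
steady state.  The buffering comparisons (proliferation plus a
cytoskeletal change) are evaluated as paired runs under a shared seed:
the division schedule is then near-identical between the baseline and
the perturbed run, so the pair isolates the mechanical response from
the division-pattern noise.

Known limitations, observed honestly in the validation suite:

* Cell–ECM adhesion strength (`k_adhB`) has almost no influence on
  local basal curvature in this realization: the arc forms by cell
  wedging and the soft ECM follows passively, so the lateral-adhesion
  flattening case does not reach its expected ratio.  In the
  growth scenarios the same dial *does* buffer proliferation-driven
  bending.
* The basal membrane rest-length dial (`L0_memb,basal`) does not
  shorten cells in the bent state: the basal edge is compressed by
  basal contraction, so added rest length is absorbed by membrane
  buckling rather than basal widening.
* Under proliferation, the buffering effect of posterior ECM stiffening
  is weak and borderline: an inextensible foundation can also force the
  added cell material to buckle, so the net sign depends on the
  realized division pattern.
* Squamous cells can transiently self-intersect in crowded growth runs
  (they are thin and soft); columnar geometry remains simple.

These divergences are reported as failing checks rather than hidden by
loosened tolerances.

## Metrics

Local basal curvature is the signed Menger curvature (reciprocal
circumradius through the vertex and its ±window neighbors, default
window 3) along the columnar basal polyline, positive toward the apical
side; profiles can be normalized by total arc length (scale-invariant)
and summarized as mean |κ| ratios over equal arc-length thirds
(lateral/medial) or halves (posterior/anterior).  Cell height is the
distance between basal- and apical-edge centroids; the relative nuclear
position is `d_B/(d_A + d_B)` (0 basal, 1 apical), with mitotic cells
excluded from domain summaries.  The same routines accept digitized
`x,y` point sets from experimental cross-sections via
`read_pointset()`.

## Problem sizes

The shipped presets use 20 columnar cells with 4/8/4 membrane segments
per edge (about 850 nodes), 6000 FIRE iterations for shape equilibria
and 7200–10000 Euler steps (dt 0.0025) for growth runs; these sizes were
chosen as the smallest at which the domain summaries are stable against
discretization.
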