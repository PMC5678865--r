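---
title: "Modeling CXCL12 gradients in a vascularized tumor microenvironment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling CXCL12 gradients in a vascularized tumor microenvironment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cxcl12grad)
```

## The model

`cxcl12grad` simulates how gradients of the chemokine CXCL12 form, point,
and fluctuate in a small piece of tumor tissue. Chemotactic CXCR4+ cancer
cells respond to remarkably shallow CXCL12 gradients — on the order of
0.002 nM/µm, a difference of roughly 10–20 molecules across a 10-µm cell
body — so the question of whether, and in which direction, such gradients
can exist near tumor vasculature is central to understanding
intravasation and metastasis.

The simulated tissue is a 200-µm cube divided into 10-µm cubic
compartments (one cell diameter; 8000 voxels; 8×10⁻³ mm³). Two discrete
cell types occupy voxels, at most one cell per voxel:

* **CXCL12-secreting cells** (fibroblast-like) add ligand to their own
  compartment at rate S (molecules/cell/s).
* **CXCR7+ scavenging cells** bind, internalize and degrade CXCL12
  through the ACKR3/CXCR7 decoy-receptor pathway. They appear in two
  roles: scattered through the tissue, or lining the blood vessel wall
  (endothelial CXCR7).

The continuum side tracks two concentration fields per voxel, free and
ECM-bound CXCL12 (nM). Each 0.1-s transport step composes:

1. **Secretion** into occupied voxels, converted to nM through the 1-pL
   voxel volume (602 molecules ≈ 1 nM·pL).
2. **Transvascular exchange** (when a vessel is present):
   dn/dt = p·A·(C_blood − C_endo) across each 100-µm² face a lining
   compartment shares with the vessel. The blood is an infinite,
   spatially uniform reservoir; the driving concentration on the tissue
   side is the free pool, since only diffusible ligand crosses the wall.
3. **Diffusion** of the free field by an alternating direction explicit
   (ADE) scheme: the average of an upward and a downward Saul'yev sweep,
   written in flux form so that total mass is conserved to round-off and
   no-flux boundaries (grid edges and the vessel wall) are exact. The
   scheme is unconditionally stable; at the default D = 150 µm²/s,
   dt = 0.1 s, dx = 10 µm (λ = 0.15) its impulse response matches the
   no-flux eigenfunction series to better than 1% L2 at 10 s.
4. **Extracellular degradation** of the free pool, exact exponential
   first-order decay. ECM-bound ligand is protected from extracellular
   proteolysis, so it does not decay; it is, however, visible to CXCR7
   uptake (see below).
5. **ECM exchange**: reversible, non-saturable binding
   dB/dt = k_on·F − (k_on/K_p)·B, integrated exactly over the step
   (exponential relaxation to the equilibrium partition B/F = K_p).
   Isoform identity enters mostly here: CXCL12-γ binds ECM far more
   tightly than -β, which binds more tightly than -α, while secretion
   rates and blood levels follow the opposite ranking.
6. **Receptor-mediated uptake** by each CXCR7+ cell from its own voxel.

Degradation and ECM exchange use exact exponential updates rather than
forward Euler, so fields stay non-negative at any timestep. The paper
trail for the splitting order (secrete → exchange → diffuse → degrade →
ECM → uptake) is a package convention: the mechanisms are first-order
insensitive to ordering at dt = 0.1 s, and the order is fixed so results
are bit-reproducible.

### CXCR7 trafficking

Each scavenging cell runs a five-pool trafficking subsystem (counts per
cell): surface receptor R_s, surface complex C_s, internal receptor R_i,
internal complex C_i, and cumulative degraded ligand:

* dR_s/dt = −k_on·L·R_s + k_off·C_s − k_int0·R_s + k_rec·R_i + q_syn
* dC_s/dt = k_on·L·R_s − (k_off + k_int)·C_s
* dR_i/dt = k_int0·R_s − k_rec·R_i + k_degL·C_i
* dC_i/dt = k_int·C_s − k_degL·C_i

The ligand seen by a cell, L, is the **total** (free + bound) local
concentration: CXCR7 binds free and ECM-bound CXCL12 with the same
parameters, and removal is split pro rata between the two pools. (The
alternative reading — that ECM binding also shields ligand from cellular
uptake — is biologically defensible but is not what the model
implements; the uptake-sees-everything convention is the stated model
assumption.) When an internal complex is degraded its receptor returns
to the internal pool (the `+k_degL·C_i` term), which makes the receptor
pool exactly conserved with q_syn = 0 and sustains scavenging
indefinitely — the defining behavior of a recycling decoy receptor. The
resting state is the ligand-free steady state with R_s = R_total.

The subsystem is linear for fixed L, and L is frozen over one transport
step. It is advanced by classical RK4 with substeps bounded by
min(0.05 s, 0.2/max-rate); at the default rates this is positive in
practice, matches an independent stiff integrator (`deSolve::lsoda`) to
~10⁻¹⁰ relative over an hour, and a cell can never overdraw its voxel
because the per-step removal is clipped at the available ligand (clips
are counted and surfaced). CXCR4-mediated uptake is deliberately absent:
CXCL12 binds CXCR7 roughly two orders of magnitude more tightly, and
most tumor CXCL12 degradation is assumed to proceed through CXCR7.

Receptor counts and field concentrations meet only at the voxel-volume
unit bridge (602 molecules per nM per pL); rates inside the ODEs never
carry volume factors.

### Circadian forcing and the vessel

CXCL12 levels in vivo vary up to two-fold over 24 h. Both the cellular
secretion rate and the blood concentration are forced on the cosine

X(t) = ((X_max − X_min)/2)·cos(2πf·(t − (t_start − t_max))) + (X_max + X_min)/2

with f = 1/24 h⁻¹ and X_max/X_min = 2 by default, in phase with each
other. The phase term is implemented exactly as printed above
(`convention = "printed"`); because the more natural reading would place
the maximum at t_max − t_start, both conventions are available and the
default is the printed one. Human phasing is the default (blood maximum
in the morning, t_max = 9); the nocturnal-rodent convention is a 12-h
shift of `t_max`. Blood-level defaults are mean 0.25 / 0.10 / 0.02 nM
for α / β / γ.

The vessel is a 2×2-voxel (400 µm²) rectangular prism spanning the grid,
centered (floored toward the origin on even grids). Its lining shell —
where endothelial CXCR7+ cells sit — is the one-voxel ring around the
cross-section *including* diagonal corners: 12 voxels per layer, 240
total, which is what makes 200 endothelial cells an 83% coverage.
Corner voxels share no face with the vessel and therefore do not
exchange with the blood; the 8 face-sharing voxels per layer exchange
across 100 µm² each. When coverage is below 100%, occupied lining voxels
are drawn uniformly at random (the arrangement along the wall is not
otherwise constrained).

## The two experiment drivers

**`run_setup1()`** probes cell-derived gradients: a cluster of secreting
cells and a cluster of CXCR7+ cells (100 cells each by default) confined
to 60-µm cubes placed 100 µm apart, with no vessel and no circadian
forcing. The reported gradient is the difference of mean total
concentration between the two facing 6×6-voxel cluster faces divided by
the 100-µm cluster separation — the sample sets are a package convention
since the measurement line is not otherwise pinned down. The run ends at
steady state, operationally: the gradient excursion within a trailing
5-min window falls below a threshold. The conventional threshold,
0.1 nM/µm, is orders of magnitude above the gradients the model actually
produces and so triggers almost immediately; it is kept as the printed
default but exposed in `schedule$setup1$steady_threshold`, and the
desk-scale protocol (below) uses 10⁻⁶ nM/µm so that "steady" is
meaningful at the ~10⁻⁴ nM/µm gradients of those runs.

**`run_setup2()`** simulates the vascularized section. Stage 1
initializes the tissue to a quasi-steady snapshot with secretion and
blood held at their clock-start values (circadian forcing is the slowest
process, so it is frozen during initialization); convergence is declared
when the blood-tissue gradient moves less than 1% (relative) over 5 min.
Stage 2 applies the circadian forcing to both sources for 24 h. Outputs
are the time-resolved gradient records and radial concentration
profiles, whose first point is 10 µm from the wall (the first tissue
compartment).

Two gradient metrics follow the sign convention *positive = higher in
tissue than in blood* (the gradient points into the tissue):

* `blood_tissue`: (mean total concentration of the tissue shell at
  `metrics$blood_radius_um` − C_blood(t)) / radius.
* `endothelial_tissue`: (shell at `far_shell_um` − shell at
  `near_shell_um`) / (far − near), i.e. deep tissue versus the wall
  compartments.

**`sweep_composition()`** maps either metric's signed maximum-magnitude
24-h gradient over a grid of secreting × scavenging cell counts
(default axes 25–200 by 25), averaging 5 independent placements per
composition. Replicate seeds fan out from the master seed by a counter
scheme, so any cell of the sweep can be reproduced in isolation.

## Parameters

Structural values are fixed study conditions: 10-µm voxels, 200-µm cube,
400-µm² vessel, 0.1-s transport step, one isoform per run, 200 cells of
each type at baseline (clusters: 100 + 100), 2-fold circadian variation.

The kinetic magnitudes are literature-informed package defaults, clearly
overridable in the configuration; their *orderings* are the established
isoform biology, their magnitudes are not measurements:

| parameter | default | units | role |
|---|---|---|---|
| D | 150 | µm²/s | free CXCL12 diffusivity |
| k_deg | 1×10⁻⁴ | 1/s | extracellular degradation (free only) |
| S (α, β, γ) | 1, 0.5, 0.25 | molec/cell/s | secretion, α highest |
| K_p (α, β, γ) | 1, 5, 25 | — | ECM partition, γ highest |
| k_on_ecm | 0.1 | 1/s | ECM binding rate (lumped site density) |
| blood mean (α, β, γ) | 0.25, 0.10, 0.02 | nM | circadian blood levels |
| p | 0.1 | µm/s | vascular permeability |
| k_on, k_off | 0.1, 0.01 | 1/(nM·s), 1/s | CXCR7 binding (K_D = 0.1 nM) |
| k_int, k_int0 | 0.1, 0.001 | 1/s | complex / constitutive internalization |
| k_rec, k_degL | 0.01, 0.05 | 1/s | recycling, internal degradation |
| R_total | 2×10⁵ | counts | resting surface receptors |

ECM binding is linear (non-saturable): only a dissociation constant
governs the published first-order description, so the site density is
lumped into the partition coefficient K_p = [sites]/K_D, the single
per-isoform ECM knob.

## Numerical choices

* **ADE diffusion.** Flux-form Saul'yev sweeps, averaged up/down; omitted
  fluxes on boundary and vessel faces give exact no-flux conservation
  (drift ≲ 10⁻¹² relative over 10⁴ steps). Accuracy degrades above
  λ = D·dt/dx² ≈ 1 and a warning is emitted, but stability never fails.
* **Exact exponential updates** for degradation and ECM exchange keep
  both fields non-negative for any dt.
* **RK4 with bounded substeps** for trafficking, with a zero floor and
  the ΔL ≤ L clip at the voxel interface. A strictly
  positivity-preserving first-order (Patankar-type) update was rejected:
  at these rates RK4 is already positive and is what lets the package
  meet a 0.1% bar against a stiff reference with macro-sized steps.
* **Degenerate inputs.** Zero cells, zero rates, K_p = 0 (no ECM
  binding) and fold = 1 (no circadian variation) are all exact no-ops of
  the respective operators; empty sample sets and non-positive distances
  are errors, not NaNs.
* **Ties and rounding.** The vessel block floors toward the origin on
  even grids; cluster cubes round their corner to the nearest voxel;
  steady-state detection reports the first sample at or past the
  crossing.

## The desk-scale protocol

The full-scale study conditions (20³ voxels, 0.1-s steps, multi-hour
initializations, 24-h forcing, 8×8 sweeps × 5 replicates) are what
`sim_config()` describes. The test-suite and the reproduction script run
a documented desk-scale protocol, `scaled_config()`:

* *Vascularized runs*: a 100-µm cube (10³ voxels) at dt = 0.5 s, cell
  counts scaled with the tissue volume (25 secreting, 25 tissue CXCR7)
  and the endothelial count preserving 83% lining coverage (100 of 120),
  shells at 10/40 µm, 2-h circadian stage for direction checks and the
  full 24 h only where sign constancy over a day is the claim.
* *Cluster runs*: the full 200-µm geometry (the 60-µm clusters 100 µm
  apart fit no smaller cube) at dt = 0.5 s, steady threshold 10⁻⁶ nM/µm,
  8-h cap.

At this scale the model reproduces the qualitative structure of the
full-scale results: gradients steepen and form more slowly as K_p or S
rises; scavenger numbers depress total grid CXCL12 while barely moving
the inter-cluster gradient (CXCR7 uptake is transport-limited — a
near-perfect sink — so extra scavengers are redundant); endothelial
CXCR7 flips the endothelial-tissue gradient from blood-directed to
tissue-directed; and in-phase circadian forcing of blood and secretion
modulates gradient magnitude without ever reversing direction, because
both sources rise and fall together.

## What the generator does and does not emulate

Cell placements are uniform random draws over admissible voxels
(clusters: within the confinement cube), reproducible from seeds. This
emulates the disorganization of tumor tissue but none of its real
correlates: no cell motility, division or death; no multiple or
branching vessels; no interstitial flow; no saturable ECM; no
isoform-specific proteolysis; no CXCR4 dynamics or chemotaxis — gradient
readouts stop at the molecule-difference conversion
(`molecules_across_cell()`). Passing tests therefore certify the
transport-scavenging-forcing machinery and its documented qualitative
behaviors, not quantitative agreement with any in-vivo measurement.

## Known limitations

* The per-isoform kinetic magnitudes are defaults, not fitted values;
  quantities like the absolute gradient magnitude scale with them. Under
  these defaults CXCR7+ cells are so efficient that tissue CXCL12 stays
  well below blood levels at every composition we sweep, so the
  "gradient into the tissue at high-secreting/low-scavenging
  compositions" regime for CXCL12-α requires stronger secretion or
  weaker uptake than the defaults provide; the direction-flip and
  sign-constancy results do not depend on this.
* The printed circadian phase construction places the forcing maximum at
  t_start − t_max rather than at t_max; both conventions are
  implemented, and the printed one is the default.
* Uptake sees ECM-bound ligand at full strength; protection of bound
  ligand from *cellular* (as opposed to extracellular) degradation is
  not modeled.
* One isoform per run; isoform mixtures would need independent field
  pairs.

```{r example, eval = FALSE}
# a desk-scale vascularized run
res <- run_setup2(scaled_config("setup2"), seed = 1)
glance(res)
autoplot(res)
```
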