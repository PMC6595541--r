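---
title: "Methods: selective magnetic stimulation of a two-fascicle nerve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selective magnetic stimulation of a two-fascicle nerve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`coilsteer` simulates magnetic stimulation of the rat sciatic nerve by an
array of four mm-scale solenoid coils, and asks how selectively per-coil
current weights can recruit intraneural regions. The chain is:

1. **Volume conductor.** The nerve (1 mm diameter, 11 mm long) is extruded
   along its long axis `x` inside an 11 × 10 × 10 mm block of surrounding
   tissue. The cross-section holds two elliptical fascicles (tibial, the
   larger, above; peroneal below, stacked along `z`), each wrapped in a thin
   perineurium, inside epineurium, bounded by a nerve membrane. Conductivity
   is per-tissue and anisotropic only in the fascicles
   (`sigma_x = 0.33`, `sigma_y = sigma_z = 0.08` S/m), because axons run
   along `x`.
2. **Sources.** Each coil winding is discretized into circular filament
   loops; the magnetic vector potential is the Biot–Savart midpoint sum
   `A(r) = (mu0 I / 4 pi) sum dl / |r - r'|`, and the incident electric
   field is the quasi-static phasor `E_inc = -j 2 pi f A`.
3. **Induced field.** The impedance method: each voxel edge is a lumped
   impedance `Z = Lv / ((sigma + j 2 pi f er e0) Av)`; the incident field
   impresses an EMF on every edge, and Kirchhoff's laws determine the
   conservative correction `-grad V`. We solve the equivalent
   node-potential form `div(G (E_inc - grad V)) = 0`, which satisfies the
   same network equations. At 2 kHz the reactive term is ~5 orders of
   magnitude below the conductive one, so the network is resistive by
   default.
4. **Activation.** Fibre excitation is predicted by the activation
   function `dEx/dx` (V/m²) on the cross-sectional plane where it is
   largest; a region's recruitment `alpha` is the fraction of its voxels
   meeting a threshold (default 4 mV/mm² = 4000 V/m², an external
   cable-model constant), and the selectivity of a target is
   `Sel = alpha_target - mean(alpha_others)`.
5. **Tuning.** Per-coil unit-current solutions are superposed under a
   signed weight vector (negative weight = 180° phase). The search
   heuristic zeroes the two coils farthest from the target centroid, fixes
   unity weight on the closest, sweeps the remaining weight over
   ±1.5 in 0.1 steps, then refines both active weights by ±0.1 moves,
   maximising `Sel` with ties broken by the drive energy `k sum(w²)`.

# Numerical design

**Grid.** Axial spacing 1 mm (the order of the internodal distance of large
myelinated axons — `Ex` varies slowly along `x`), uniform square
cross-sectional spacing. The default working resolution is 40 µm
(250 × 250 × 11 voxels ≈ 690k voxels, ~756k network nodes), which keeps a
full four-coil study in minutes on one CPU; 10 µm is a configuration option.
All reported numbers in the package's own tests use the 40 µm grid.

**Solver.** The node-potential system is symmetric positive semi-definite
with the constant nullspace of a pure-Neumann (insulating boundary) problem.
It is solved by conjugate gradients, deflated against constants, with a
block preconditioner that factors one cross-sectional node plane exactly
(CHOLMOD); because the geometry is extruded, all interior planes share a
single factor and both end planes another. The axial edge conductances are
~600× weaker than the in-plane ones at 40 µm (1 mm vs 40 µm edges), so the
preconditioned iteration converges in a few dozen steps at a relative
residual of 1e-8 (default). The matrix depends only on the grid and tissue
table, so the four per-coil solves and any direct multi-coil solve reuse one
assembly and one pair of Cholesky factors. A dense assembly of the same
network, written independently with explicit loops, serves as the oracle in
the test suite; the sparse path matches it to 1e-10 on small heterogeneous
grids.

**Edge conductivity at interfaces.** An edge takes the directional
conductivity of the voxel on its negative side (`sigma_mode = "owner"`,
default) or the arithmetic mean of its adjacent voxels (`"average"`, the
parallel combination of quarter cross-sections). The choice moves interface
fields by a fraction of a voxel, nothing more.

**Rasterization.** Voxels are labelled by the innermost structure containing
their centre. Thin shells (perineurium, membrane, default 30 µm) can be
thinner than a coarse voxel, so shells are closed morphologically: no
fascicle voxel may touch epineurium directly and the membrane ring is at
least one voxel thick. This keeps the anatomical topology — the perineurium
is the dominant barrier around each fascicle — at every supported
resolution.

**Singularity guard.** Grid points interleave the coil volume, so the
Biot–Savart kernel distance is floored at the wire radius when evaluating on
the grid (the field inside a round conductor does not exceed its surface
value); the raw API instead refuses points inside the guard distance.

**Activation plane and sign.** The model is extruded and the coils sit at
the axial mid-point, so `Ex` is exactly even about the mid-plane and a
centred difference vanishes there identically. The activation map is
therefore the centred difference evaluated at the interior axial station
where the signed in-fascicle gradient is maximal — by symmetry the station
adjacent to the mid-plane, which is where the peak gradient is observed.
All phasors share the quadrature phase of the inductive drive (cosine coil
current), so the signed amplitude `-Im(phasor)` is used; it is linear in the
weights, which makes the exact scaling law `alpha(theta; c w) =
alpha(theta / c; w)` hold to the last bit (it is tested `identical`).

# The drive scale

The stimulating coil is driven by a damped RLC discharge with a 2 kHz
damped frequency and 600 A peak current. A single-frequency solver needs the
peak current slew; for a pure cosine that is `2 pi f I0` (7.5e6 A/s), but a
damped discharge can be substantially steeper. This matters: with the plain
cosine value, the activation function everywhere in the fascicles stays a
factor ~4 below the 4 mV/mm² threshold for every weight vector in the
examined ±1.5 range, recruitment is identically zero and the tuning
heuristic has nothing to discriminate. The published operating point of this
configuration, however, fixes the scale: under the tibial-target weights the
peroneal fascicle's activation shoulder sits at ≈3 mV/mm². `current_drive()`
therefore carries an explicit `slew_factor` (peak dI/dt relative to
`2 pi f I0`), whose default 3.69 is calibrated once against that single
observation; every field amplitude is simply linear in it. Selectivity
outcomes at the reference threshold are genuine predictions on top of this
one apparatus constant.

# The synthetic geometry

No machine-readable cross-section exists, so the histology is replaced by a
parametric approximation: a 1 mm circular nerve, tibial ellipse centred at
(0, 0.17) mm with semi-axes (0.23, 0.25) mm, peroneal at (0, −0.29) with
(0.13, 0.14) mm, 30 µm membrane and perineurium. The muscle regions are
convex polygons in fascicle-local coordinates: MG and PL split the tibial
fascicle side by side along `y`, TA is the central block of the peroneal
fascicle. Two qualitative published anchors orient the layout: the tuned
weight patterns (coils 1–2 serve the tibial fascicle, 3–4 the peroneal),
which force the fascicles to stack along `z` facing coils 1/3, and the
selectivity ordering of the muscle regions (PL best, MG worst), which
assigns MG to the tibial half left without a nearby discriminating coil
once the heuristic zeroes the two farthest coils.

What the phantom reproduces: tissue-scale heterogeneity, the
perineurium barrier, fascicle anisotropy, realistic coil-to-region
distances. What it does not: the irregular fascicle outlines and exact
region shapes of real histology, axon-level structure, or any
histology-derived asymmetry. Passing the property suite therefore validates
the method (field solve, superposition, metrics, tuning), while absolute
selectivity values for real nerves depend on geometry details the phantom
only approximates. With ~26–28 voxels per muscle region at 40 µm the
recruitment fractions are quantized at ~4%, so recruitment-vs-threshold
transitions are sharper than they would be at 10 µm.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `dyz_mm` | 0.04 | mm | cross-section resolution; 0.01 reproduces the fine-scale setting |
| `dx_mm` | 1 | mm | axial spacing ~ internodal length |
| `I0_A`, `f_Hz` | 600, 2000 | A, Hz | stimulator peak current and damped frequency |
| `slew_factor` | 3.69 | – | discharge slew / cosine slew; calibrated (see above) |
| `threshold` | 4000 | V/m² | activation-function threshold of a 20 µm fibre (external constant) |
| `w_max`, `w_step` | 1.5, 0.1 | – | examined weight range and grid |
| `clearance_mm` | 0.5 | mm | winding-to-nerve distance |
| `segments_per_turn` | 64 | – | winding discretization; on-axis fields converged to <0.5% |
| `tol` | 1e-8 | – | CG relative residual |

# Degenerate inputs and tie-breaks

Zero-conductivity tissue makes open branches (never a division fault);
a fully insulating grid is rejected. Isolated nodes are pinned to zero
potential. Weight-sweep ties on selectivity go to the lower drive energy,
then to the earlier candidate in sweep order (from +1.5 downward, matching
the published direction); refinement accepts equal-selectivity moves only at
strictly lower energy, which makes the hill climb terminate. The activation
plane tie (two stations symmetric about the mid-plane) resolves to the
distal one.

# Known limitations

- The published figure-level field maps are not reproduced voxel-for-voxel:
  the geometry is parametric and the drive scale carries one calibrated
  constant.
- Threshold-robustness of tuned weights is weaker than published: the
  reconstruction's target/competitor field contrast cannot span a ±25%
  threshold band, and energy tie-breaking prefers the weakest
  just-recruiting candidate, which leaves no margin above threshold.
- The multi-resolution boundary treatment of the original solver is
  replaced by uniform spacing per axis; only the mid-plane metrics are
  reported, which do not depend on it.
- Coil inductance, the drive circuit, wire resistance and heating are out
  of scope; the current waveform is prescribed.
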