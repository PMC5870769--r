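---
title: "Methods: parametric construction and fitting of regular folds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parametric construction and fitting of regular folds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parafold)
```

## Model and assumptions

`parafold` treats a regular fold as a deterministic function from a small
parameter vector to backbone coordinates. Models are all-glycine,
backbone-only (N, CA, C, O per residue; C1'/N-anchor representation for
nucleotides), with idealized bond lengths and angles. No side chains, no
energetics, no sterics: the only score ever computed is geometric
(superposed backbone RMSD). This is appropriate for folds whose topology
is genuinely low-dimensional — coiled coils, collagen, solenoid repeat
proteins, canonical B-DNA — and deliberately inappropriate for anything
else.

All builders are pure functions: the same parameters always yield the
same coordinates, byte for byte. Randomness enters only through the
optimizer and the noise generator, both explicitly seeded.

## Helix classes and derived constants

A helix class is defined by its canonical backbone torsions, not by
hard-coded cylindrical constants:

| class   | phi (deg) | psi (deg) | omega (deg) | handedness |
|---------|-----------|-----------|-------------|------------|
| `alpha` | -57.8     | -47.0     | 180         | right      |
| `ppii`  | -75.0     | 145.0     | 180         | left       |
| `pi`    | -57.0     | -70.0     | 180         | right      |

At load time each class builds a long reference chain with these torsions
(via the NeRF chain-extension algorithm) and *measures* its cylindrical
constants — rise per residue, twist per residue, and per-atom-type
cylindrical offsets (radius, phase, axial shift) for N, CA, C and O. For
the α class this yields rise 1.4807 Å, CA radius 2.2801 Å, 3.604
residues per turn.

These differ slightly from textbook values (1.5 Å / 2.3 Å / 3.6) because
the (rise, twist) ↔ (φ, ψ) map is near-singular around the α-helical
region: small torsion changes trade off rise against twist, and no torsion
pair within ±3° of the canonical one reproduces, say, exactly 3.617
residues per turn. Deriving the constants from the torsions keeps the two
construction routes — the cylindrical (Crick-path) route and the
torsion-angle route — mutually consistent: an α helix built either way
agrees to well under 0.1 Å backbone RMSD.

```{r}
c(helix_class("alpha")[c("rise_per_residue", "helix_radius",
                         "residues_per_turn")])
```

## The generalized Crick construction

A supercoiled helix is a minor helix (one of the classes above) wound
around a superhelical axis of radius $r_0$ and pitch $P$. With
$\alpha = \arctan(2\pi r_0 / P)$ the superhelix pitch angle and $d$ the
minor rise per residue measured along the superhelical path:

- superhelix phase advance per residue:
  $\omega_0 = s\, d \sin\alpha / r_0$ (sign $s$ from the superhelix
  handedness),
- minor phase advance per residue:
  $\omega_1 = \omega_\text{minor} - \omega_0 \cos\alpha$ (the minor twist
  is corrected for the frame rotation carried by the superhelical path).

At arc-length parameter $t$ the path point, the unit vector toward the
axis $\mathbf e_1$, the path tangent $\mathbf T$ and
$\mathbf e_2 = \mathbf T \times \mathbf e_1$ form a moving frame; each
backbone atom type is placed at its class-specific cylindrical offset
$(r_X, \delta\phi_X, \delta z_X)$ in that frame.

Two conventions matter:

- **φ\_CA convention.** `phi_ca` (the "interface angle" of assemblies) is
  the minor-helix phase of the first CA, measured in the moving frame from
  $\mathbf e_1$, i.e. from the direction pointing *toward* the
  superhelical axis, increasing toward $\mathbf e_2$. `phi_ca = 0` starts
  the CA trace facing the axis.
- **Consistent arc-length parametrization.** An atom with axial offset
  $\delta z_X$ lives at effective parameter $t' = t + \delta z_X / d$;
  both the moving frame *and* the minor phase are evaluated at $t'$ (with
  the phase offset re-zeroed by $-\omega_\text{minor}\,\delta z_X/d$ so
  the straight-helix limit is reproduced exactly). Evaluating frame and
  phase at inconsistent parameters breaks peptide continuity at tight
  supercoils (errors up to 0.19 Å at collagen-like curvature); the
  consistent form keeps C–N bond lengths within 0.005 Å of ideal across
  realistic parameter ranges.

As $P \to \infty$ the construction reduces exactly to a translated
straight helix.

## Assemblies and parameters

All lengths are in ångströms, all angles in degrees.

- **Coiled coil** (`crick_params`): `n_chains`, `superhelix_radius`
  (typical trimer: 6.5), `pitch` (150–200), `interface_angle` (= φ\_CA),
  `n_residues`, per-chain `z_shift` and `chain_rotation`, superhelix
  handedness (default left for α coiled coils). Chains sit at equal
  azimuthal spacing, giving exact $C_n$ symmetry when per-chain offsets
  are zero.
- **Tropocollagen** (`build_tropocollagen`): three PPII chains on a
  right-handed superhelix (typical radius 3.0, pitch 85) with staggered
  `z_shift`/`chain_rotation`.
- **Helix pair / solenoid** (`helix_pair_params`, `solenoid_params`): two
  straight α helices placed by signed `axis_distance`, `z_shift`,
  `phi_ca`, `splay` (tilt in the inter-axis plane) and
  `off_plane_rotation`; a solenoid stacks `n_repeats` copies of the unit
  by the screw operation (radius, rise per repeat, twist per repeat).
  Consecutive repeats are related by exactly the same rigid transform.
- **DNA duplex** (`dna_duplex_params`): sequence, rise per base pair
  (3.38) and twist per base pair (36°, i.e. 10.5–11 bp/turn), antiparallel
  complementary strand generated automatically.

Chains are labelled A, B, C, ... (up to 62 chains; beyond that the PDB
single-character chain field overflows and builders refuse).

## Fitting

`fit_structure` wraps a self-contained DE/rand/1/bin differential
evolution: F = 0.75, CR = 0.8, uniform initialization within bounds,
clipping to bounds, one forced crossover dimension, greedy selection.
The budget is exact: `population * (generations + 1)` model builds
(initial population plus one trial per member per generation). The score
is superposed backbone RMSD between the candidate build and the target,
so fits are invariant to the target's pose. `rmsd100` normalizes the
final RMSD to a 100-residue equivalent for cross-size comparison
(defined for N ≥ 20).

Solenoids are fitted in two stages (`two_stage_solenoid_fit`): the
helix-pair unit parameters against the first repeat, then the three
superhelical placement parameters against the whole structure with the
unit frozen. This reduces an 11-dimensional search to 8 + 3 and is the
difference between reliable and unreliable convergence at desk-scale
budgets.

Integer-kind parameters (`parameter_spec(kind = "integer")`) are rounded
before evaluation. Seeded runs are bitwise reproducible; for a fixed seed,
extending the generation budget continues the same RNG stream, so more
budget never hurts the same-seed result.

## Synthetic test conditions — what the tests show and don't

The test suite and `scripts/acceptance.R` use *self-consistent* synthetic
targets: structures built by the package's own generators, optionally with
seeded i.i.d. Gaussian coordinate noise (`add_noise`). Under these
conditions the tests demonstrate:

- exact identities (budget arithmetic, $C_n$ symmetry, screw-operation
  constancy, superposition recovery below 1e-9 Å),
- noiseless parameter recovery (trimer to ~1e-3 Å RMSD at 20×50;
  collagen below 0.5 Å at 30×50; solenoid below 1.0 Å at 50×50 + 40×100),
- correct noise floors (fitting a σ-noised target converges to
  ≈ σ√3 unsuperposed RMSD, the theoretical floor for i.i.d. noise).

They do **not** demonstrate that real structures are fitted well: real
coiled coils have sequence-dependent local geometry, fraying ends and
non-canonical torsions that the idealized model cannot express. The
recovered parameters of a real structure should be read as a geometric
summary, not a reconstruction.

## Numerical choices

- **Superposition** uses the Kabsch SVD with a determinant correction for
  reflections. The returned RMSD is computed from explicit residuals
  rather than the singular-value identity $\sqrt{(E_0 - 2\sum\sigma_i)/n}$,
  which loses ~1e-8 absolute accuracy to cancellation on near-identical
  point sets. The optimizer's internal scorer keeps the fast identity —
  at fitness scales the difference is irrelevant.
- **Primitives** use a width-3 running mean of the CA trace. For a helix
  of radius $r$ and angular step $\Delta$ this leaves a residual radius of
  exactly $r(1 + 2\cos\Delta)/3$ — about 0.50 Å for an α helix. The
  primitive is a smoothed path, not an axis; use `fit_axis` when the axis
  itself is wanted.
- **Torsion fidelity under supercoiling.** The moving frame bends the
  chain, so interior (φ, ψ) of a supercoiled chain drift from the
  canonical class values by roughly half the superhelix pitch angle
  (≈ 6–7° at collagen curvature, < 2° at coiled-coil curvature). Straight
  builds reproduce canonical torsions within measurement tolerance.
- **Chirality.** An α helix is chiral, so a left-handed supercoil is
  *not* the mirror image of the right-handed one: reflection also flips
  the minor helix's handedness. The superhelical paths mirror exactly;
  the atoms do not.

## Problem sizes and cost

Builders are vectorized; constructing a 3×30-residue assembly takes
milliseconds. Fits at the budgets above build 1–4 thousand models and
complete in seconds to tens of seconds. The full test suite runs in about
a minute; `scripts/acceptance.R` in under half a minute.

## Limitations

Glycine-only backbones (plus HYP→PRO-style name normalization on input);
no side chains, no hydrogens, no B-factors beyond defaults; single-model
PDB reading (first model, primary altloc); idealized bond geometry
throughout; the DNA model is a rigid canonical B-form ladder, not a
base-pair-step model. The optimizer is a plain DE without restarts or
adaptive control; for hard landscapes, run several seeds and keep the
best.
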