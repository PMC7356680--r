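---
title: "Modelling multilayer tablet disintegration and dissolution with voxtab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multilayer tablet disintegration and dissolution with voxtab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(voxtab)
```

## Scope and rationale

`voxtab` studies a specific formulation phenomenon: an insoluble
separation layer (polycaprolactone, PCL) placed between an
acetylsalicylic-acid (ASA) layer and a mefenamic-acid (MA) layer of a
triple-layer tablet slows the release of the highly soluble ASA, while a
bilayer of the same two active layers shows no such slowdown and the
poorly soluble MA is unaffected in either geometry. The package combines
three levels of description:

1. closed-form compact physics (densities, porosities, stresses, exposed
   areas) for layered tablets on oval punches;
2. a stochastic voxel cellular automaton (CA) for spatially resolved
   disintegration and dissolution;
3. lumped first-order (Noyes–Whitney) fitting and f2 similarity for
   profile-level comparison.

## Compact physics

A layer's pore-free density is the mass-fraction-weighted harmonic mean of
its component true densities, $\rho_{layer} = 1/\sum_i X_i/\rho_i$.
Porosity is $\varepsilon = 1 - m/(V\rho_{layer})$; a negative value is
reported as an inconsistent-geometry error rather than clamped, because it
means the declared mass cannot fit the declared envelope. Effective
compressive stress is force over footprint area,
$P = 1000\,F/S$ (MPa from kN and mm²).

The oval punch footprint is modelled as an **ellipse** by default, with a
**stadium** (rectangle capped by half-discs) available: tooling drawings
labelled "oval" are ambiguous between the two, and the ellipse reproduces
the reported compaction stresses of these tablets within about 2%. Layer
thicknesses are derived from mass, porosity, density and footprint area
($t = m/((1-\varepsilon)\rho A)$) as *flat-faced model estimates*. Measured
tablet thicknesses include unparameterised punch-cup curvature and are
deliberately not used for voxelization; for the same reason the absolute
exposed areas computed here differ from CAD values, while ratios between
layers ("% of control") are directly comparable. Each interlayer contact
occludes one end face of each of the two layers it joins; a conservation
identity (stacked areas + 2 × interfaces × face area = standalone areas)
is asserted in the tests.

## Voxelization

A tablet is discretized on a cubic grid (reference pitch 74 µm; toy grids
use coarser pitches). The compression axis is z with layer 1 at the
bottom; a one-voxel exterior margin of liquid surrounds the tablet. Every
voxel is a single pure substance: a component, a pore, or exterior liquid —
no sub-voxel mixtures. Within a layer, each voxel is independently a pore
with probability $\varepsilon$, otherwise component $k$ with probability
proportional to its solid volume fraction
$(X_k/\rho_k)/\sum_j X_j/\rho_j$. One uniform draw per voxel against fixed
cut-points makes placement reproducible bit-for-bit per seed. Granule-scale
clustering of components is *not* modelled; real granulated material is
structured at the 100-µm scale, and a cluster-aware placement would be a
natural extension.

## The cellular automaton

The engine is a synchronous three-phase automaton on the 6-neighbour (von
Neumann) lattice; all phases read the state at the start of the step
(double buffering, no sequential-scan bias):

1. **Ingress.** A pore voxel with at least one liquid face-neighbour
   becomes liquid with its layer's `ingress_probability`. This is the
   discrete proxy for capillary imbibition. Per-layer defaults 0.884 (ASA
   layer) and 0.181 (MA layer) preserve the measured capillary-constant
   ratio of the two granulates (≈ 8.84 : 1.81); the faster layer is placed
   near 0.9 so that wetting of a connected pore path is nearly
   step-limited. Both layers sit *below* the simple-cubic site-percolation
   threshold (ε ≈ 0.074 and 0.111 vs ≈ 0.3116), so the pore network does
   not span and release is erosion/dissolution-dominated —
   `percolation_check()` makes this inspectable per layer.
2. **Dissolution.** A soluble solid voxel with a liquid face-neighbour
   loses one unit of its integer dissolution resistance; at zero it
   becomes liquid and its mass is credited to its species' release.
   Resistances are effective per-voxel constants standing in for
   molecular-dynamics-derived dissolution rate parameters that are not
   available here: mannitol and croscarmellose 1, hydroxypropyl cellulose
   3, ASA 4, MA 6 steps. The ordering follows aqueous
   solubility/dissolution rate (excipients ≥ ASA > MA); the magnitudes
   were chosen once so that, on the study geometries, the thin MA layer
   clears the interlayer interface within the ASA release window — the
   regime in which the experimentally observed mechanism (bilayer
   unaffected, triple-layer slowed) can express itself. Insoluble species
   (microcrystalline cellulose, magnesium stearate, PCL) have infinite
   resistance and never transmit liquid.
3. **Erosion.** A solid voxel with fewer than `detachment_threshold`
   (default 2) solid face-neighbours and at least one liquid neighbour
   detaches. Detached soluble material is credited to release immediately
   — a deliberate simplification that conflates fine-particle dissolution
   with detachment; detached insoluble material moves to a separate ledger
   and never appears in API release. With `disintegrant_burst = TRUE`
   (default), a wetted disintegrant voxel converts in one step, mimicking
   a swelling superdisintegrant.

An exact per-species voxel ledger,
`initial = remaining + dissolved + detached`, is maintained and asserted
at every step. The simulated disintegration endpoint is the first time
less than 1% of the initial *soluble* solid remains; insoluble material is
excluded because an inert slab may legitimately persist in a
disintegration tester.

**Randomness.** Each step draws one uniform for every voxel from a seed
derived deterministically from `(run seed, step index)`. Consumption is
therefore independent of the state, which gives (a) bit-identical replay
for identical inputs and (b) common-random-number coupling across rule
variants — e.g. doubling one species' resistance at a fixed seed can never
accelerate that species' release at any time point, a monotonicity the
tests assert.

**Time calibration.** Steps map to seconds by the single factor
`seconds_per_step`. `calibrate_seconds_per_step()` pins a reference run's
time-to-80%-release (or, via the disintegration endpoint, a measured
disintegration time such as the 81 s of the single-layer ASA tablet) to a
target; it is a pure rescaling of the time axis and never touches the rule
constants. No calibration against digitized release figures is performed
anywhere in the package.

## Noyes–Whitney fitting

The first-order rate law $dC/dt = (DS/h)(C_s - C)$ has the closed form
$C(t) = C_s(1 - e^{-(DS/h)t})$ with $C$ the released percent of dose. Only
the product $DS/h$ is identifiable from a single curve, so the diffusivity
$D$ (default 6·10⁻⁶ cm²/s, a typical small-molecule aqueous value) and the
unstirred-layer length $h$ (default 0.45 cm) are fixed configuration
constants and the specific surface $S$ (cm²/g) is the sole fitted
coefficient. The default $h$ is an *effective* lumped length: because $C$
is a percent of dose rather than a concentration, $h$ absorbs the
dose/volume normalisation, and the default is set so that specific
surfaces of one-to-several hundred cm²/g give release half-times of
minutes. For complete-release formulations the plateau is fixed at
$C_s = 100$; sub-plateau behaviour is expressed by passing $C_s < 100$
explicitly, keeping $S$ the only free parameter. Comparisons between fits
require identical $(C_s, D, h)$ and report the surface-reduction ratio
$S_{ref}/S_{test}$, which is invariant to consistent time-unit rescaling.

Numerically, the sum of squares is minimised over $\log S$: a
deterministic 400-point scan of the fixed bracket $[10^{-6}, 10^9]$ cm²/g
locates the basin (the objective is flat far from it, where the model is
pinned at 0 or $C_s$), followed by `stats::optimize()` on the bracketing
interval at tolerance 10⁻¹². Profiles that are all zero (no signal) or
constant at plateau from the first sample (unbounded $S$) are rejected
with informative errors rather than fitted.

## f2 similarity

$f_2 = 50\log_{10}\{[1 + \tfrac1n\sum_t(R_t-T_t)^2]^{-1/2}\cdot 100\}$ on
a common time grid; 100 for identical profiles and > 50 as the
conventional similarity cut-off. Alignment defaults to the intersection of
the two sampled time sets; when fewer than three points coincide but the
ranges overlap, both profiles are linearly interpolated onto the union of
times within the overlap. Full curves are compared by default — the
regulatory convention of truncating one point past 85% release is
available (`truncate_85 = TRUE`) but off, since simulated and reference
curves are compared over their whole course. Values slightly outside
[0, 100] are tolerated as assay noise but flagged with a warning.

## The synthetic-data generator

`paper_formulations()` rebuilds the four study dosage forms — a 500-mg MA
tablet (porosity 13.7%), a 1000-mg ASA tablet (7.1%), their 1500-mg
bilayer and the 1800-mg triple-layer with a 300-mg PCL separator (ASA
7.4% / MA 11.1% in the multilayers) — on the 21.5 × 10 mm oval punch, with
50% drug load in each active layer. Masses, fractions, punch size, the
two printed true densities (ASA 1.3928, PCL 1.1600 g/cm³) and the layer
porosities are study values; the remaining excipient densities are
literature placeholders, and every numeric field is flagged `"paper"`,
`"derived"` or `"placeholder"` in the provenance table (a test asserts no
unflagged placeholder). The MA porosity is kept in both of its reported
contexts (13.7% standalone, 11.1% in multilayers) without attempting a
reconciliation. The PCL layer porosity is set to 0 (melt-compressible
wax, effectively nonporous) — a placeholder, flagged as such.

`noisy_profile()` generates first-order release curves with independent
Gaussian noise (default σ = 1% absolute, 5-min sampling over 60 min,
mirroring the 5-min assay cadence) clipped to [0, 105]; it stands in for
experimental dissolution curves that exist only as figures and were not
digitized. What the generator does *not* emulate: correlated assay error,
inter-tablet variability, the sigmoidal early lag of real disintegrating
systems. Passing tests therefore demonstrate internal consistency and
mechanism expression, not predictive accuracy on real dissolution data.

`toy_tablets()` voxelizes the four dosage forms at a coarse pitch (`scale`
voxels across the major axis, default 24, capped at 50), preserving layer
order and derived thickness ratios. Problem sizes used throughout the
tests and the acceptance script were chosen as the smallest grids on which
the studied effects are resolved: scale 36 (pitch ≈ 0.6 mm, about 7 500
tablet voxels) for the bilayer/triple-layer mechanism comparisons, scale
40 for the conservation suite, and scales 10–24 for unit tests. The full
74-µm study grid (≈ 293³ cells) is supported by the same code path.

## Design choices made where the design was open

* **CA rule set.** The reference automaton behind the original study is
  commercial and its rules are unpublished; the three-phase rule set here
  is this package's own design, built to realize the mechanisms the study
  narrates (pore-network ingress, species-specific dissolution constants,
  surface erosion, an impermeable inert layer) with the fewest moving
  parts. It is labelled a re-design, not a reproduction.
* **Neighbourhood and update.** Faces-only (von Neumann) neighbourhood —
  the simplest transport-consistent choice — and fully synchronous
  updates.
* **Dissolved-solute feedback** (viscosity passivation of pore transport)
  is not modelled; noted as an extension.
* **Percolation check.** The layer spans when a face-connected pore path
  joins one of its end faces (compression axis) to its mid-plane. The
  lateral band is not used as a source, so a single surface pore at
  mid-height does not count as a spanning path.
* **Surface areas.** Absolute CAD areas of the original study are not
  reproducible without the punch-cup geometry; the package reproduces
  the % of control ratios from given areas exactly and labels its own
  flat-face areas as model estimates.
* **Interfaces.** Profiles travel as `time_s, species, released_pct` CSV
  with `#`-prefixed provenance headers; grids as a TSV of flattened state
  and layer arrays plus a JSON sidecar (pitch, species table, seed);
  tablet configs as JSON (YAML readable when the yaml package is
  present). All formats are plain text and round-trip losslessly.

## Known limitations

* Per-voxel resistances and ingress probabilities are effective, not
  first-principles, constants; only their ratios are anchored to measured
  quantities (capillary constants; solubility ordering).
* Detachment-equals-release overstates early release of poorly soluble
  detached material (MA); the MA curves here are best read as
  disintegration-paced.
* Flat-faced geometry underestimates tablet thickness relative to curved
  punches; absolute areas and thicknesses are model estimates.
* Coarse toy lattices exaggerate lateral rim erosion relative to face
  fronts, which *shrinks* the bilayer/triple-layer gap; the mechanism's
  direction is preserved (and is what the tests assert), its magnitude at
  toy scale is conservative.
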