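---
title: "Dye stacking and GAG contact analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dye stacking and GAG contact analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gagstack)
```

## The scientific problem

Methylene blue (MB) is a planar, monocationic phenothiazine dye that binds
glycosaminoglycans (GAGs) — linear anionic polysaccharides such as heparin,
heparan sulfate and chondroitin sulfate — and has long been used as a
colorimetric probe for sulfated GAG content. Molecular simulation studies of
MB with GAG decasaccharides characterize this association through a small
set of trajectory-level observables:

* **π–π stacks.** MB self-associates face-to-face at an inter-plane spacing
  of about 3.7 Å, in parallel and antiparallel long-axis orientations,
  forming oligomers of two to ten molecules.
* **Anionic-site contacts.** The dye's two terminal dimethylamino nitrogens
  carry the most positive charge and anchor electrostatic contacts with the
  GAG's sulfate and carboxylate groups; a contact is counted when such a
  nitrogen is within 8 Å of the site's anchor atom (sulfate sulfur or
  carboxyl carbon).
* **The sulfation-dependence statistic.**
  $D = n_\mathrm{MB} \cdot t / n_{\mathrm{SO}_3}$,
  where $n_\mathrm{MB}$ is the number of dyes bound simultaneously, $t$ the
  fraction of simulation time spent at that count, and $n_{\mathrm{SO}_3}$
  the chain's sulfate inventory. $D$ is undefined for a fully desulfated
  chain.
* **MM-GBSA component bookkeeping.** Binding free energies decomposed into
  van der Waals, in vacuo electrostatic, non-polar solvation and
  Generalized Born reaction-field terms, normalized per interacting drug.

This package implements these analyses over coarse, multi-frame coordinate
trajectories, together with a synthetic trajectory generator that replaces
all-atom molecular dynamics so that every stage can be verified against
known ground truth. The all-atom MD machinery itself (force fields, solvent,
the Generalized Born model) is deliberately out of scope.

## Coarse geometric models

**GAG chains.** Seven sulfation presets are provided (`HP`, `deHP`, `CS4`,
`CS6`, `HS1`, `HS2`, `HS3`), each defined by the anionic sites of its
repeating disaccharide; at dp10 (five disaccharides) heparin carries 15
sulfates, the chondroitin sulfates 5, the heparan sulfates 10, and every
uronic acid one carboxylate. The three heparan sulfates share the same net
charge (−3 per disaccharide) but differ in sulfation pattern, which is
exactly the contrast the $D$ statistic probes. Geometrically a chain is a
coarse scaffold: one backbone bead per monosaccharide every 5.0 Å along a
straight (optionally uniformly bent) axis, with each residue's sites offset
4.0 Å radially, alternating sides of the axis, and multiple sites of one
residue fanned ±40° in azimuth. Sugar-ring internals, glycosidic torsions
and puckering are not modeled; every downstream analysis depends only on
the labeled anchor positions, so this scaffold is sufficient and keeps all
geometry analytic.

**The dye.** MB is a rigid template: 14 ring atoms forming three fused
benzene-like hexagons (C–C 1.39 Å) exactly in a plane, plus the two
terminal nitrogens 1.35 Å beyond the outermost ring vertices on the long
axis, carrying the +1 formal charge. Only the plane, the long axis, and the
nitrogen positions matter downstream.

## The synthetic generator

**Scripted mode** realizes a per-frame script — for every dye: bound or
not, stack membership and position, orientation relative to the previous
stack member — with exact geometry: stacked neighbours are placed at the
target spacing (default 3.7 Å) along a shared normal; bound singletons sit
with a terminal nitrogen exactly `bound_distance` (default 4.0 Å) from
their assigned anchor; bound stacks lie alongside the chain axis so every
member is within the contact cutoff; unbound dyes are parked at least 20 Å
from all sites and from each other. Identical frame layouts are realized
once and reused, placement is fully deterministic, and infeasible scripts
(overlaps, more bound dyes than sites) are rejected with the frame index.
Scripted trajectories make the analysis stack *testable*: recovered stack
sizes, orientations, spacings, bound flags and time fractions must match
the script exactly.

Scripted data emulate the *configurations* of a simulation, not its
physics: there is no thermal noise, no gradual association/dissociation,
no chain flexibility within a frame, and the parked/bound dichotomy is
sharper than any real trajectory. A passing round-trip therefore validates
the bookkeeping and geometry of the analyses, not their robustness to
thermal disorder (the detection thresholds below address that separately).

**Monte Carlo mode** is a rigid-body Metropolis sampler over the dyes
(chain held fixed) with a deliberately minimal potential: a flat-bottom
stacking well of configurable depth, active when a pair satisfies the
geometric stacking criterion within ±0.8 Å of the target spacing
(orientation-independent); a screened-Coulomb attraction between terminal
nitrogens and site anchors; and hard-core repulsion. Moves are
single-molecule translations (≤ 1 Å) and rotations (≤ 15°), one attempt
per dye per sweep — the simplest ergodic move set for rigid bodies — inside
a reflecting spherical cell whose default radius is 60 Å. Initial poses are
drawn uniformly over the cell, which is the stationary distribution of the
interaction-free chain, so the null model is directly comparable to a
random-placement oracle. Trajectories are bit-reproducible from the seed.
The mode exists for mechanistic plausibility checks (does a stacking well
enrich stacking? does site attraction drive binding?), not for
thermodynamic rigor: there is no explicit solvent, no counterions, and no
claim that the sampled ensemble matches any physical temperature.

## Stack detection

Ring planes are fitted by total least squares (SVD); the normal's sign is
fixed deterministically (positive z component, falling back to x then y),
since a least-squares normal is otherwise defined only up to sign. The
inter-plane distance of a pair is the mean of the two unsigned
centroid-to-plane distances, which is symmetric and ignores purely
in-plane offsets. Two dyes are stacked when

* inter-plane distance ≤ `d_max` (default 4.5 Å),
* angle between ring normals, modulo 180°, ≤ `angle_max` (default 30°),
* in-plane centroid offset ≤ `lateral_max` (default 3.0 Å).

The observed spacing (≈ 3.7 Å) is an experimental outcome, not a detection
rule; the defaults are chosen to accept 3.7 Å stacks with thermal wobble
while rejecting T-shaped and edge-on contacts, and all three thresholds
are exposed. Stacks are connected components (size ≥ 2) of the resulting
graph; members are ordered along the mean stack normal (sign-aligned
average of member normals) with ties broken by molecule id, which resolves
"adjacent" for spacing statistics. Orientation (parallel/antiparallel from
the sign of the long-axis dot product) is classified pairwise between
consecutive members — stacks can be mixed, so no whole-stack label is
assigned; numerically perpendicular axes are flagged indeterminate rather
than forced into a class. Because the mean adjacent spacing over all
oligomers and the dimer-only mean can differ in mixed populations, both
summaries are reported.

## Contacts and the binding summary

The dye–site distance is the minimum over the two terminal nitrogens of
the Euclidean distance to the site's anchor atom — the most permissive
reading of "one of the nitrogen atoms", and the one consistent with
per-molecule distance traces. A contact requires the distance to be
*strictly* below the cutoff (default 8 Å).

Two per-type summaries are reported side by side, because published
contact tables do not always state their convention:

* `fraction_pct` — percent of frames in which *at least one* (dye, site)
  pair of the type is in contact (the primary, existence-style reading);
* `pair_occupancy_pct` — the mean over all (dye, site) pairs of each
  pair's own contact time fraction.

Site types absent from a preset (all sulfates on a desulfated chain) are
reported as `NA` and rendered as dashes in table output, never as zeros.

The binding summary takes `n_MB` as the maximum simultaneous bound count
over frames and `t` as the fraction of frames at that count. Other
conventions are defensible (at least the count; longest episode), so the
full distribution of bound counts is always carried in the object and
`fraction_at_least` is precomputed. A trajectory with no binding at all is
flagged (`no_binding`) rather than reported as a zero-count "binding".

Chain bending is summarized per frame as end-to-end distance over polyline
contour length of the backbone beads: 1 for a straight chain, 2/π in the
semicircular limit.

## The D statistic and energy bookkeeping

`compute_D()` applies $D = n_\mathrm{MB} t / n_{\mathrm{SO}_3}$ exactly,
keeps the unrounded value for chaining, and reports a display value rounded
to two decimals. All table-style reporting in the package rounds half away
from zero (so −5.55 prints as −5.6); base R's round-half-even is avoided
because it makes printed tables platform- and representation-sensitive.
With no sulfates, $D$ is undefined and flagged — never coerced to zero or
infinity.

The energetics module is bookkeeping over component tables plus a
transparent surrogate; no solvation model is reimplemented. Frames enter
energy analysis only if at least `min_bound` dyes (default 3) are bound.
Per-drug normalization divides each component by the number of interacting
drugs, reporting at one decimal (half away from zero) with the raw ratio
retained. `additivity_check()` verifies the decomposition identity
$\Delta G = \Delta G_{vdW} + \Delta G_{esurf} + (\Delta G_{eel} +
\Delta G_{egb})$ within 0.15 kcal/mol — the worst-case residual from
independently rounding three addends to one decimal.

The bundled reference table of published MM-GBSA components (see
`mmgbsa_reference()`) is itself an instructive test case: its desulfated
heparin row fails both checks. The printed per-drug cells for ΔG, eel and
eel+egb equal the totals divided by ten (the full dye count) rather than by
the row's own seven interacting drugs, and the printed components miss the
additivity identity by −0.7 kcal/mol. `normalization_consistency()` flags
exactly these cells — a printed per-drug entry is accepted only when it
lies within half a printed decimal (0.05 kcal/mol) of the arithmetic
ratio — and the package reports the arithmetic values rather than silently
matching the printed ones.

The surrogate scorer (`surrogate_energy()`) produces MM-GBSA shaped
records from coarse coordinates — screened Coulomb over nitrogen–site
pairs, Lennard-Jones over ring-atom pairs, a buried-contact surface term,
and a fixed screening factor for the reaction field — so synthetic
end-to-end runs have an energy column with the right structure (its
additivity holds exactly by construction). It is a didactic scorer,
deterministic in the coordinates, with no claim of physical accuracy.

## Numerical choices and degenerate inputs

* Plane fits reject collinear/coincident points (relative second singular
  value below 10⁻⁹) instead of returning an arbitrary normal.
* Orientation classification treats |dot| ≤ 10⁻⁸ as indeterminate.
* Stack member order breaks projection ties by molecule id, making output
  deterministic for symmetric configurations.
* Scripted placement uses no randomness at all; Monte Carlo randomness
  flows from a single integer seed, and pipeline stages derive child seeds
  from the run seed and the stage name (`stage_seed()`).
* Coordinates are Å throughout; trajectory files round-trip exactly at the
  formats' 3-decimal precision.
* An empty frame-filter result is a flagged empty selection with a
  warning, not an error, so pipelines can report it.

## Scale of the bundled verification

The test suite and the acceptance script run at desk scale by design:
scripted scenarios of 100 frames with 10 dyes (1000 frames only where a
fraction of 30.2% must be exactly representable), Monte Carlo contrasts of
4–6 dyes in 10–25 Å cells over 150–250 sweeps with 20 seeds per
comparison, and brute-force oracles (exhaustive pairwise stacking graphs,
exhaustive contact enumeration) on instances small enough to enumerate.
These sizes were chosen as the smallest that make each property
non-vacuous — e.g. Monte Carlo stacking runs are long and dense enough
that stacks actually form, which is asserted, not assumed.

## Known limitations

* The coarse scaffold fixes the chain rigidly within a trajectory; the
  ligand-induced bending seen for chondroitin chains can be *represented*
  (via `bend_radius`) and quantified, but not spontaneously produced.
* The Monte Carlo potential does not reproduce the templating kinetics
  reported for real MB–GAG systems, where the polymer accelerates stack
  formation. In paired-seed experiments across a range of attraction
  strengths, screening lengths and cell sizes, switching the site
  attraction on left first-dimer times equal or *longer*: point-anchored
  nitrogen–site attraction pins dyes at discrete sites, and a pinned dye
  must pay the detachment cost before it can satisfy the strict stacking
  geometry. Reproducing the templating effect would require a smoother,
  orientation-aware dye–chain potential; no such term was added, and the
  Monte Carlo contrast checks assert the two directions that are robust in
  this model (stacking wells enrich stacking; site attraction raises the
  bound fraction).
* Scripted ground truth is exact but idealized; agreement there bounds
  bookkeeping errors only. Performance on thermally disordered data is
  probed indirectly, through the threshold design and the noisy plane-fit
  checks.
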