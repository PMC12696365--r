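---
title: "Characterising tubular spidroin conformers: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising tubular spidroin conformers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silktube)
```

## The scientific problem

Major ampullate spidroins (MaSp1/MaSp2) are very large, block-copolymer-like
intrinsically disordered proteins. In the silk gland they must stay soluble at
extreme concentration while remaining primed for fibre assembly. Solution NMR
sees fast, coil-like dynamics; SAXS sees compact, anisotropic particles.
Coarse-grained simulation ensembles reconcile the two pictures through
metastable *tubular* conformers: the ~3,000-residue chain packs, roughly in
sequence order, into a tube a few nanometres wide and tens of nanometres long,
with hydrophobic poly(Ala) blocks buried and polar X residues (Gln, Tyr, Ser,
Arg) at the surface.

`silktube` implements the desk-scale analysis chain around that picture: the
geometric metrics that define and classify tubular conformers, bead-level
solvent accessibility and burial statistics, a continuum cylinder-shell
packing model, Debye scattering with genetic-algorithm (GA) sub-ensemble
fitting against experimental SAXS curves, rigid stapling of terminal domains
and template-based dimer construction, and the sequence block/mutation
machinery used to probe how amphiphilic patterning controls tubule formation.
Because the original trajectories are large external artefacts, the package
ships synthetic structure generators with analytic ground truth; every
estimator is validated against those.

## The structural containers

One coarse-grained bead represents one residue; all coordinates are stored in
nanometres (PDB files, read and written in Angstrom, are the only unit
boundary), and all bead/sequence indices are 0-based with half-open
intervals. The central S4 classes are `BeadChain` (ordered bead coordinates
with residue codes and chain labels), `ScatteringCurve` (a q/I/sigma profile,
theoretical when sigma is empty), `TubuleAxis` and `EnsembleFit`.

## Tubule geometry

The tubule is characterised hierarchically:

* **Axis and ACL.** The curvilinear axis is the polyline of unweighted
  centres of mass of 150-residue windows taken every 10 residues along the
  sequence (`computeAxis()`); this works because sequence order approximates
  packing order along the tube. The *averaged contour length* (ACL) is the
  arc length of that polyline. Windows much shorter than 150 residues
  under-smooth the backbone; windows beyond ~400 residues erase the tubule.
  When the chain length minus the window is not a step multiple we append one
  final window anchored at the chain end, so the axis always reaches the last
  residues. Masses are taken equal — coarse-grained beads are near-equal in
  mass and no mass table is meaningful at one bead per residue.
* **MaxE** is the exact maximum pairwise bead distance, computed blockwise
  for large chains (identical result to the naive double loop).
* **R_t**, the tube radius, is the 90th percentile (type-7, linearly
  interpolated, hence bit-reproducible) of each bead's distance to the
  nearest point of the axis *polyline* — point-to-segment, not
  vertex-only.
* **R_g and R_h.** R_g is the usual equal-mass radius of gyration. For R_h
  we use the Kirkwood double-sum estimate `N^2 / sum(1/r_ij)`: it needs no
  external hydrodynamics program and is monotone in overall compaction,
  which is what shape classification needs.

### Shape classification and its calibration

On the classical hydrodynamic scale the shape factor R_g/R_h is ~0.77 for a
globular particle, ~1.0 for a coil and ~1.7 for a rod, and
`classifyShape()`'s default boundaries (0.85 and 1.35) separate those
references. The Kirkwood estimator, however, sits on a different scale: for
a bead-filled uniform ball it gives R_h = 5R/6, hence a spherical reference
of ~0.93 rather than 0.77. Rather than silently mixing scales,
`calibrateShapeClasses()` regenerates ball/coil/rod references with the
package's own estimator and places boundaries at the midpoints; both the raw
shape factors and the calibrated classes are reported. This was a genuinely
open design point — which R_h estimator the upstream analyses used is not
stated — and exposing both scales is the conservative resolution.

## Synthetic ground truth

The generators define the conditions under which the estimators are
validated:

* `makeTube()` builds a discrete worm-like axis of exactly the requested
  length (bounded random turning per step, 0.15 rad over 0.5 nm segments by
  default) and hangs beads on it in sequence order with offsets uniform in
  the disk of radius `tubeRadius`. Uniform-in-disk placement is chosen over
  a shell because it makes the 90th-percentile radial law analytic:
  `sqrt(0.9) * tubeRadius`. The default geometry (50 nm axis, 2 nm radius)
  mirrors the tubule parameters the analysis targets. A `labeled` variant
  puts hydrophobic codes inside half the tube radius and polar codes
  outside — the radial law of that labelling is a package choice made so
  burial statistics have a guaranteed ordering to recover, not a literature
  value.
* `makeBall()`, `makeRod()`, `makeCoil()` have closed-form R_g
  (`sqrt(3/5) R`, `sqrt(L^2/12 + d^2/8)`, `b sqrt(n/6)`), used as oracles
  throughout the tests.
* `makeMixtureCurve()` mixes theoretical curves with known weights and
  multiplicative Gaussian noise, giving the GA a target with a known answer.
  When the noise level is zero the sigma column falls back to 1% of I so the
  curve remains usable in chi-squared fits.

Every generator takes one explicit seed, records its ground truth before any
estimator runs, and is bit-reproducible. What the generators deliberately do
*not* emulate: physical chain packing, sequence-dependent bead chemistry,
excluded volume, hydration. Passing recovery tests therefore demonstrates
estimator correctness on known geometry, not fidelity of any simulation.

## Surface partitioning

`beadSASA()` is a Shrake–Rupley accessibility calculation on bead spheres: a
fixed golden-spiral lattice (960 points by default) on each expanded sphere
(bead radius + 0.14 nm probe), points occluded by neighbouring expanded
spheres. The default bead radius, 0.30 nm, is the effective radius of the
mean residue volume 0.113 nm^3. Because the lattice is fixed in space, areas
are rotation invariant only to quadrature resolution (below 2% at the
default density). The burial reference for each residue type is the central
bead of a collinear 3-bead construct at 0.38 nm spacing — the bead-level
analogue of the Gly-X-Gly tripeptide reference — and the conventional 20/50
exposure-ratio cutoffs split beads into buried/intermediate/exposed.

The continuum cylinder-shell model (`cylinderShellSplit()`) treats the
tubule as a cylinder with a surface shell one effective residue radius
(0.3 nm) thick, end caps included: buried fraction
`((R - t)^2 (L - 2t)) / (R^2 L)`. For the tubule geometry (R = 2 nm,
L = 50 nm) this gives 0.714 — the ~70/30 bulk/surface split. The shell
thickness equal to one effective residue radius is a modelling choice of
this package; the continuum ratio stands in for an explicit sphere-packing
construction, and the sphere-packing fraction `n v / (pi R^2 L)` is reported
alongside as a plausibility check.

## Scattering and ensemble fitting

`debyeCurve()` evaluates the exact orientation-averaged Debye sum with unit
form factors (`I(0) = N^2`); no hydration shell or excluded-volume terms are
applied, consistent with fitting purely theoretical curves in the 1–10 nm
mid-range where bead-level contrast differences are second order. Above
5,000 beads a pair-distance histogram (0.01 nm bins) replaces the double
sum; the tests hold it to 0.5% of the exact sum.

`guinierFit()` iterates the standard low-q linear fit of ln I vs q^2 with
the window condition q·R_g <= 1.3 until R_g is stable to 0.1%.
`chiSquare()` uses the analytically optimal multiplicative scale and K−1
degrees of freedom.

`gaEnsembleFit()` selects multisets of 1–50 pool curves (a conformer may
occupy several slots — that multiplicity is its weight), scoring each
chromosome by the chi-squared of its multiplicity-weighted mean curve.
Operators are tournament selection, uniform multiset crossover, point
mutation with occasional size moves, and elitism, which guarantees a
non-increasing best score. The 1–50 ensemble-size bound is the documented
convention of this fitting style; population 50, 1,000 generations, mutation
0.1, crossover 0.5 and elitism 2 are this package's defaults, recorded in
every fit along with the seed, and the GA is validated against exhaustive
multiset enumeration on small pools. Conformer descriptors follow the
`Mx_xxxx` / `MxMy_xxxx_yyyy` dialect (`parseConformerId()`).

## Stapling and dimers

`kabschSuperpose()` is the standard SVD solution with the reflection branch
corrected to det(R) = +1. By default collinear anchor sets are rejected
(the rotation about the line is arbitrary), but `stapleTermini()` opts into
them deliberately: idealised bead anchors are often exactly collinear and
the least-squares fit is still attained. Stapling aligns the terminal
structure's anchor beads (5 by default) onto the core's end, merges the
overlap once keeping the core copy — the core's internal coordinates are
never moved — and enforces an anchor-rmsd acceptance threshold (0.5 nm
default) with warnings for seam spacings outside 0.2–0.8 nm. Dimers are
built by superposing each monomer's N-terminal anchor onto one chain of a
two-chain template; clashes warn rather than fail because combinatorial
dimers drawn from independently folded conformers legitimately collide, and
ordered pairing is used so n monomers give n^2 dimers (29 gives 841).

## Sequence blocks and mutants

`segmentBlocks()` tiles a sequence into maximal poly(Ala) runs (minimum 4 —
long enough to exclude poly(Gly-Ala) alternation, short enough to catch the
native 5–10 residue runs), Gly-rich spans (Gly fraction >= 0.4) and
remainder. `mutateSequence()` implements the mutant series: all-Gly,
all-Ala, blockified Gly/Ala, knockouts (replacement defaults to Gly, the
same convention as blockification; the flag is exposed because the upstream
choice is not stated), seeded scrambles, and poly(Ala) consolidation, which
re-inserts the pooled Ala as equal-as-possible stretches at evenly spaced
points of the depleted sequence — the published constructs are not
reproducible verbatim, so an even-spacing rule was fixed once. Every
operation preserves length; scrambles and consolidation preserve the
residue multiset exactly.

The published MaSp1 repetitive core itself is not redistributable, so
`makeMaspCoreSurrogate()` builds a synthetic 2,880-residue stand-in carrying
its two summary statistics by construction — exactly 39 copies of
`GQGGAGAAAAAAAAG` (~20% of the core) and a combined Gly+Ala fraction of
exactly 75.0% — with Ala-free GGX filler between motif copies so no
accidental motif occurrences can arise. Statistics on the real sequence
require the user to fetch it (`readSequences()`), after which
`countMotif()` and `residueComposition()` apply unchanged.

## Orchestration

`runSizeAssay()` sweeps structure sizes (default 100/200/400 residues),
derives one recorded seed per run from the master seed, and reports the
first length at which the modal shape class stops being spherical — the
desk-scale analogue of the observation that tubules need a minimum chain
length to emerge. `runFullReport()` chains geometry, burial and the
optional SAXS fit into one JSON report embedding the package version, the
full configuration echo, its MD5 hash and all seeds; deterministic sections
reproduce bit-for-bit. Configurations are plain R lists or JSON files, and
the exported functions are the package's interface — the R prompt and
small Rscript wrappers replace a separate shell tool.

## Numerical choices and problem sizes

Percentiles are type-7; the Guinier convergence tolerance is 0.1%; the GA
uses 32-bit-safe derived seeds; chi-squared uses K−1 degrees of freedom;
coincident beads are a hard error in the Kirkwood sum and the SASA kernel.
The test and validation runs use 1,000–3,000-bead tubes, 10^3–10^5-bead
reference shapes and pools of 2–3 curves with exhaustive oracles — sizes at
which every closed form used as an oracle is sharp and the whole suite runs
in well under a minute.

## Known limitations

* SASA is bead-level; it does not attempt per-atom parity with residue-level
  tools, and the burial split depends on the bead-radius and threshold
  choices.
* The Kirkwood R_h is a free-draining approximation; absolute shape factors
  are estimator-specific, which is exactly why calibrated classification is
  provided.
* The Debye calculator ignores contrast and hydration; it is meant for
  comparing conformers and fitting mixtures, not absolute intensities.
* Published per-structure values from the original study (ensemble
  chi-squared of the full pool, fitted-ensemble R_g, the 66/15/19 burial
  split of real MaSp conformers, ACL/MaxE/R_t of real tubules) require the
  deposited trajectories and the experimental scattering curve, which are
  not part of this package; the property suite validates the estimators on
  synthetic ground truth instead.

## A worked example

```{r example, eval = FALSE}
tube <- makeTube(3000, axisLength = 50, tubeRadius = 2, seed = 1)
m <- shapeMetrics(tube$chain)
m

cal <- calibrateShapeClasses()
classifyShape(m$shape_factor, cal)

cylinderShellSplit(radius = 2, length = 50, thickness = 0.3,
                   nResidues = 3102)
```
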