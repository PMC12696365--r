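# silktube

Geometric, surface and scattering analysis of tubular spidroin conformers.

Major ampullate spider silk proteins (spidroins MaSp1/MaSp2) are huge,
repetitive, intrinsically disordered proteins whose solution ensembles
contain metastable *tubular* conformers: the chain packs, roughly in
sequence order, into a tube a few nanometres wide and tens of nanometres
long, with hydrophobic poly(Ala) blocks buried in the core and polar
residues (Gln, Tyr, Ser, Arg) at the surface. `silktube` is an R package
for the analysis chain around that picture, aimed at people working with
coarse-grained (one-bead-per-residue) conformers of silk-like IDPs.

What it computes:

* **Tubule geometry** — a curvilinear axis from windowed centres of mass
  (150-residue windows every 10 residues), and the hierarchical size
  metrics built on it: averaged contour length (ACL), maximum Euclidean
  extent (MaxE), tube radius R_t (90th percentile of bead-to-axis
  distances), R_g, Kirkwood R_h = N² / Σ 1/r_ij, and the shape ratios
  R_g/R_h, R_g/MaxE, R_g/R_t with sphere/coil/rod classification
  (literature boundaries or a self-consistent calibration).
* **Surface partitioning** — Shrake–Rupley solvent accessibility on bead
  spheres, buried/intermediate/exposed classes against a random-coil
  reference, per-residue-type burial tables, and the continuum
  cylinder-shell packing model, buried fraction = ((R−t)²(L−2t))/(R²L).
* **SAXS ensembles** — Debye curves I(q) = Σ sin(q r_ij)/(q r_ij), Guinier
  and Kratky analysis, χ² with analytically optimal scaling, and a
  GAJOE-style genetic algorithm that selects multiplicity-weighted
  sub-ensembles of 1–50 theoretical curves to fit an experimental profile.
* **Assembly** — Kabsch superposition, stapling of terminal-domain
  structures onto core chains, and template-guided combinatorial dimer
  construction (n monomers → n² ordered dimers).
* **Sequence blocks** — poly(Ala)/Gly-rich segmentation, composition and
  motif statistics, and the standard mutant series (all-Gly, all-Ala,
  blockified, knockouts, scrambles, poly(Ala) consolidation).
* **Synthetic ground truth** — tube/ball/rod/coil generators with
  closed-form geometry and mixture SAXS curves with known weights, so the
  whole chain is testable without MD trajectories.

## A worked example

```r
library(silktube)

# a synthetic tubule with known geometry: 50 nm axis, 2 nm disk radius
tube <- makeTube(3000, axisLength = 50, tubeRadius = 2, seed = 1)
shapeMetrics(tube$chain)
#> TubuleMetrics:
#>   ACL 48.783 nm  MaxE 48.402 nm  R_t 1.876 nm
#>   R_g 14.077 nm  R_h 7.745 nm  R_g/R_h 1.817  R_g/MaxE 0.291
#>   shape class: rod
```

The ACL estimate (48.8 nm) recovers the generating 50 nm axis to within
the half-window trimming at each chain end, and R_t (1.876 nm) recovers
the analytic 90th percentile of the uniform-disk radial law,
√0.9 · 2 = 1.897 nm. The shape factor 1.82 is on the Kirkwood scale,
where reference values differ from the classical hydrodynamic ones
(a bead-filled sphere gives 0.93, not 0.77) — classifying against
references regenerated with the same estimator labels this strongly
curved tube a coil:

```r
cal <- calibrateShapeClasses()
classifyShape(shapeMetrics(tube$chain)$shape_factor, cal)
#> [1] "coil"
```

The cylinder-shell packing model for the tubule geometry (50 nm long,
4 nm diameter, shell one effective residue radius thick):

```r
cylinderShellSplit(radius = 2, length = 50, thickness = 0.3, nResidues = 3102)
#> $buried_fraction
#> [1] 0.71383
#> $surface_fraction
#> [1] 0.28617
#> $packing_fraction
#> [1] 0.5578795
```

i.e. the ~70/30 bulk/surface split, at a plausible sphere-packing
fraction of 0.56.

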