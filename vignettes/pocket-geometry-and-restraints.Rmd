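---
title: "Measuring and restraining the GPCR orthosteric pocket"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and restraining the GPCR orthosteric pocket}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrpocket)
```

## The problem

Class A G protein-coupled receptors bind their ligands in a cavity between
the seven transmembrane helices, open to the extracellular side — the
orthosteric pocket. Comparative (homology) models of GPCRs built inside an
implicit-membrane energy function systematically shrink this pocket: the
membrane slab contains no water, so closing the cavity lowers the model
energy. A collapsed pocket wrecks downstream ligand docking, especially for
larger ligands. The remedy implemented here is knowledge-based: measure how
big the pocket really is across experimentally determined structures,
express that knowledge as randomized tetrahedral distance restraints that a
modeling engine can score, and filter the resulting model ensembles back to
realistic pocket volumes.

This package provides every computational step around the modeling engine
itself: pocket definition and volume measurement, distance statistics over
structure sets, ligand-contact detection, restraint generation in the
Rosetta constraint-file dialect, restraint scoring, and ensemble filtering.
Running the comparative modeling, relax or docking protocols themselves is
out of scope; their inputs and outputs (PDB coordinate files, score tables)
are the interface.

## Pocket definition and generic numbering

Residue positions are identified by Ballesteros-Weinstein/GPCRdb generic
numbers (`helix.bw` with an `x`-separated structural position, e.g.
`2.57x56`), which name structurally equivalent positions across receptors.
The package parses both the machine form and the typeset form with a
multiplication glyph (`"2.57 × 56"`); the canonical machine token is always
lowercase-`x` with no spaces. One token in the bundled tetrahedron
definition, `5.46x461`, carries a three-digit structural position; it is
preserved verbatim rather than reinterpreted, since nothing in the source
material resolves it to anything else.

The pocket volume is deliberately measured from C-alpha atoms only:
side-chains differ between receptors and are flexible, while the backbone
positions are comparable across the family and available in both
centroid-mode and full-atom models. Ten surrogate positions on TM2, TM3,
TM5, TM6 and TM7 — the highest and lowest pocket-lining position of each of
the five pocket-forming helices — span the volume polytope. TM1 and TM4 sit
outside the pocket wall and contribute no surrogate. The full 34-position
pocket-lining census is receptor-community knowledge that users can supply
as a pocket-definition file; the package bundles the subset it needs
(surrogates plus the eight tetrahedron vertices) as `default_pocket_definition()`.

Mapping generic numbers to author numbering of a specific entry is a
per-receptor table (`load_residue_map()`), obtainable from the GPCRdb
generic-numbering annotation. The package performs no sequence alignment of
its own: automatic generic-number assignment is a solved problem upstream
and re-deriving it here would only add disagreement.

## Volume measurement

The pocket volume is the convex-hull volume of the ten surrogate C-alpha
points, which equals the sum of simplex volumes of their Delaunay
tessellation. Two independent implementations ship:

* `convex_hull_volume()` enumerates supporting planes (every 3-point plane
  with all remaining points on one side), triangulates each facet polygon
  through its 2D hull, and accumulates facet-area times centroid distance
  over three. This is exact, handles degenerate facets (four or more
  coplanar hull vertices), and is the route used by `pocket_volume()`.
* `delaunay_volume()` enumerates 4-point subsets and keeps those whose
  circumsphere contains no other point. It is quartic in the number of
  points and intended for small sets and as a cross-check; the test suite
  asserts agreement of the two routes to a relative 1e-9 on random point
  sets.

Degenerate inputs (fewer than four points, coplanar or collinear
configurations, rank tested with a 1e-8 Angstrom singular-value tolerance)
raise errors rather than returning zero, so silent garbage volumes cannot
enter the ensemble filter. Brute-force enumeration is entirely adequate at
the problem size this package targets (10-34 points); no incremental hull
construction is warranted.

`tetra_volume_from_edges()` gives the Cayley-Menger determinant volume of a
tetrahedron from its six edge lengths in the order (d12, d13, d14, d23,
d24, d34); a non-positive discriminant (edge set violating the triangle or
tetrahedral inequalities) is a non-realizable error. `superpose_rmsd()` is
a standard Kabsch superposition restricted to proper rotations
(determinant +1), used to compare the upper TM bundle region of models
against a reference over the same ten surrogate positions.

## Distance knowledge base and contact detection

`aggregate_distance_stats()` measures every pairwise C-alpha distance of a
position list in every structure of a set and records per-pair count,
median, mean and standard deviation. Conventions, chosen once:

* median of an even count is the mean of the two middle values;
* the standard deviation is the population form (n denominator) — the
  structure set is treated as a census, not a sample; the sample form is
  available via `sd_form = "sample"`;
* a structure missing some mapped positions still contributes to the pairs
  it can resolve, and the per-pair `n` records how many structures entered
  each statistic.

`detect_pocket_residues()` implements the ligand-contact rule that
historically selected the pocket-lining residues: a residue is a pocket
residue when any of its heavy atoms lies within a 3.5 Angstrom radius of
any ligand heavy atom. The ball is closed (a distance of exactly 3.5
counts), and hydrogens are excluded on both sides — crystal structures
rarely resolve them, and including them where present would make the
criterion structure-dependent. On C-alpha-only models the test degrades to
C-alpha distances with a warning. `rank_residue_frequency()` tallies
contact frequency across structures, descending, with ties broken in
canonical generic-id order.

## Restraint generation

The restraint geometry is two tetrahedrons spanning the pocket, twelve
AtomPair distance restraints in total. Alternative geometries (single
distances, triangles, cubes, the exhaustive all-pairs set) are documented
design history: single distances are too weak, cubes and exhaustive sets
over-restrain and erase receptor-specific pocket shape. Two tetrahedrons
are the working middle ground, and this package implements only that
geometry.

Each edge carries the potential

    f(d) = A * ( ((d - C) / B)^2 + D )

with weight `A`, harmonic steepness `B`, reference distance `C` and
constant offset `D`. Parameters are drawn per tetrahedron (the six edges of
one tetrahedron share a parameter set; the two tetrahedrons draw
independently) from calibrated ranges:

| parameter | range | sampling |
|---|---|---|
| `A` | 2-4 | uniform on integers |
| `B` | 0.4-0.8 | uniform on a 0.1 grid (continuous available) |
| `s` (scale) | 1.03-1.07 | uniform, continuous |
| `D` | -10..-1 | uniform on integers |

`C = s * d_ref`: the reference distance is deliberately inflated 3-7% over
the source distance because the surrounding energy function pulls inward —
a slightly over-wide target counteracts the shrinkage. Whether the original
calibration sampled `B` and `s` on grids or continuously is not
documented anywhere we could consult; the package samples `B` on the
0.1 grid its worked examples exhibit and `s` continuously, with a flag for
continuous `B`. `d_ref` comes either from the bundled census medians of
the twelve edges (`reference_edge_medians()`, knowledge-base mode — the
default) or from the C-alpha distances measured in a supplied template
structure (template mode).

The constraint-file writer emits the Rosetta AtomPair dialect token-exactly:

    AtomPair CA <i> CA <j> SCALARWEIGHTEDFUNC <A> SUMFUNC 2 HARMONIC <C> <B> CONSTANTFUNC <D>

with `C` at 4 decimals, `B` at 1 decimal, `A` and `D` as integers, single
spaces, tetra-1 edges first, edges ordered (v1v2, v1v3, v1v4, v2v3, v2v4,
v3v4) in the declared vertex order. The HARMONIC arguments are center
first, then steepness — standard Rosetta function syntax, which the worked
numeric examples of the dialect also follow. The parser additionally
tolerates typeset-collapsed spacing (`CA66`, `SUMFUNC2HARMONIC`,
`CONSTANTFUNC-8`) seen in print reproductions of such files, but never
emits it; write-parse-write is a byte fixed point.

## Ensemble filtering and classification

Experimental structures of one receptor, even in one activation state,
spread over roughly +/-100 to 200 cubic Angstrom of pocket volume. The
ensemble filter encodes that: the per-receptor median volume is computed
over all generated models, and models within +/-200 cubic Angstrom of it
pass (closed interval). `select_best()` then ranks passing models by total
score, ascending, ties broken lexicographically by label for determinism,
and returns the top five by default. Ranking is by energy only after the
volume filter; a secondary volume sort after energy is a defensible
alternative reading of the source protocol, but energy-only ranking is what
the final scoring step describes, so that is the implemented behavior.

`classify_volume_difference()` grades a model-minus-reference volume
difference: within the band is natural variation; between one and three
bands the pocket deviates (tagged shrunken or enlarged by sign); beyond
three bands the pocket construction is considered failed. Boundaries are
inclusive toward the milder category. `count_docking_successes()` counts
interface scores at or below -6 Rosetta energy units, the conventional
success criterion for productive docking poses in this setting; it is a
score-table post-processor only.

## The synthetic bundle generator

`make_bundle()` builds an idealized 7TM C-alpha bundle: seven textbook
alpha-helices (rise 1.5 Angstrom per residue, twist 100 degrees per
residue, C-alpha radius 2.3 Angstrom) with axes on a circle, leaving a
central cavity. All bundled pocket positions are planted at fixed indices
on the extracellular half of their helix, and the generator emits the
matching residue map, so every resolution, measurement, restraint and I/O
path can be exercised without downloading anything. The default axis-circle
radius of 8.2 Angstrom was chosen once so that the surrogate hull volume
(about 2620 cubic Angstrom) sits at the typical inactive class A pocket
volume of about 2600; `jitter_sd` adds seeded Gaussian noise to emulate
structural variation between entries.

What the generator does *not* emulate: side-chains, loops, helix kinks and
bulges, membrane context, and real energetics. Tests passing on bundles
therefore demonstrate the correctness of the geometry, statistics, and
file-dialect machinery — not that any particular receptor's pocket is
predicted well. Quantitative claims about real receptors require real
coordinates supplied by the user.

`make_ensemble()` draws model records with volumes from a normal law
(default 2600 +/- 200 cubic Angstrom, 100 models — the scale of one
comparative-modeling run) plus independent scores, and emits a parseable
score table. With sd = 200 and band 200, the expected filter pass rate is
the normal-law probability of |Z| <= 1, about 68% — mirroring the observed
fraction of receptors within 2600 +/- 200 cubic Angstrom.

## Numerical and I/O policy decisions

* PDB parsing: first MODEL only; alternate locations resolved keep-first by
  default (deterministic) with a highest-occupancy mode; polymer residues
  without a C-alpha are dropped with a warning (error in strict mode);
  HETATM groups are collected except a default exclusion list of waters,
  common ions and cryoprotectants — membrane lipids and detergents are not
  excluded because they can occupy the pocket. Chain policy defaults to the
  first chain with at least 100 polymer residues, skipping fusion-partner
  chains.
* Pose numbering is always 1..N in file order after selection, matching the
  1-based sequential numbering constraint files use.
* All randomized operations (parameter sampling, bundle jitter, ensembles)
  run off R's global RNG and are reproducible under `set.seed()` or the
  `seed` arguments; the command-line interface records the seed in its
  outputs.
* Problem sizes used in the shipped checks — 10-34 point volumes, 25
  structure statistics, 100-10000 model ensembles, 1000 parameter draws —
  match the scales the method operates at in production, where one
  comparative-modeling run produces 100 models per receptor.

## Known limitations

* The bundled 34-position extended list is partial (the union of positions
  the bundled definitions require); the authoritative full census lives in
  receptor-community resources and is accepted as a user file.
* The census medians behind knowledge-base mode ship as constants; they
  cannot be recomputed without the full experimental structure census they
  were measured on, and the package makes no attempt to re-derive them.
* Only class A (rhodopsin-like) numbering is supported; class B/C/F
  schemes differ.
* `delaunay_volume()` does not resolve cospherical degeneracies; use the
  hull route (the default) for constructed symmetric inputs.
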