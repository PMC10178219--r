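# gpcrpocket

Tools for measuring and controlling the size of the orthosteric
ligand-binding pocket of class A G protein-coupled receptors (GPCRs).

Comparative models of GPCRs built in implicit-membrane energy functions
systematically shrink the pocket between the seven transmembrane helices,
which biases ligand docking against realistic (especially larger) ligands.
`gpcrpocket` implements the knowledge-based machinery that measures and
counteracts this shrinkage around a modeling engine:

* **Pocket definition** via Ballesteros–Weinstein / GPCRdb generic residue
  numbers (`2.57x56`, …), resolved to specific structures through
  per-receptor mapping tables. Ten surrogate positions on TM2/3/5/6/7 span
  the pocket volume polytope.
* **Pocket volume** as the convex-hull / Delaunay-tessellation volume of
  the surrogate Cα atoms: for points x₁…x₁₀, V = Σ over Delaunay simplices
  of |det(v₂−v₁, v₃−v₁, v₄−v₁)|/6, which equals the hull volume. Typical
  inactive class A pockets measure ≈ 2600 ± 200 Å³.
* **Distance knowledge base**: per-pair Cα–Cα distance n/median/mean/SD
  over structure sets, and ligand-contact pocket-residue detection (heavy
  atoms within a closed 3.5 Å ball).
* **Tetrahedral restraints**: two 4-vertex tetrahedrons (12 AtomPair
  restraints) with the potential `f(d) = A·(((d−C)/B)² + D)`, parameters
  drawn per tetrahedron from calibrated ranges (A ∈ {2,3,4}, B ∈ [0.4,0.8],
  C = s·d_ref with s ∈ [1.03,1.07], D ∈ {−10,…,−1}), written bit-exactly in
  the Rosetta constraint-file dialect.
* **Ensemble filtering**: models within ±200 Å³ of the per-receptor median
  volume pass; the best five by total score are selected; volume
  differences classify as within natural variation (≤ 200 Å³), deviating
  (≤ 600 Å³, shrunken/enlarged) or failed (> 600 Å³); docking successes
  are counted at the −6 REU interface-score cutoff.
* **Synthetic fixtures**: an idealized 7TM Cα bundle generator with a
  tunable central cavity, planted residue maps, planted ligands and
  controlled model ensembles, so the entire pipeline is testable without
  downloads.

Intended users are structural bioinformaticians preparing GPCR model
ensembles for docking and virtual screening. Running the modeling, relax or
docking protocols themselves is out of scope; PDB files and score tables
are the interface.

## Worked example

```r
library(gpcrpocket)

# synthetic 7TM bundle with map and pocket definition (no downloads)
bundle <- make_bundle(seed = 1)
res <- resolve_residues(bundle$map, bundle$model, bundle$pocket$surrogates)
pocket_volume(res)
#> [1] 2619.862            # Å³ — a typical inactive class A pocket

# seeded two-tetrahedron restraint set (knowledge-base reference distances)
rset <- build_restraint_set(bundle$map, bundle$model, seed = 42)
rset
#> <restraint_set> seed = 42
#>   tetra1: 2.60x59 3.40x40 5.38x39 7.32x31 | A=2 B=0.8 s=1.0414 D=-2
#>   tetra2: 2.65x64 4.57x57 5.46x461 6.48x48 | A=3 B=0.6 s=1.0595 D=-1
cat(substr(write_constraint_file(rset), 1, 90))
#> AtomPair CA 48 CA 82 SCALARWEIGHTEDFUNC 2 SUMFUNC 2 HARMONIC 23.4325 0.8 CONSTANTFUNC -2

# filter a 100-model ensemble by pocket volume, select the 5 best by score
ens <- make_ensemble(n = 100, seed = 42)
outcome <- filter_by_volume(ens$records, band = 200)
outcome
#> <filter_outcome> median 2618.0 A^3, band +/-200: 69/100 pass
select_best(outcome, setNames(ens$records$total_score, ens$records$label))
#> [1] "model_0073" "model_0015" "model_0090" "model_0052" "model_0021"

# grade model-vs-reference volume differences
classify_volume_difference(c(-16, -350, -637))
#>   delta                 category direction
#> 1   -16 within_natural_variation      none
#> 2  -350                deviating  shrunken
#> 3  -637                   failed  shrunken
```

The restraint lines name Cα atom pairs by 1-based pose number; `C` is the
reference distance (4 decimals), `B` the harmonic steepness, the
SCALARWEIGHTEDFUNC integer the weight `A`, and the CONSTANTFUNC integer the
offset `D`. A pass fraction near 68/100 under a 2600 ± 200 Å³ ensemble is
the expected |Z| ≤ 1 mass of the volume distribution.

A command-line interface wraps the same functions
(`inst/scripts/gpcrpocket`): subcommands `volume`, `distances`, `stats`,
`detect-pocket`, `make-restraints`, `score-restraints`, `filter`,
`classify` and `fixtures`, e.g.

```sh
Rscript inst/scripts/gpcrpocket fixtures --out-dir demo --seed 3
Rscript inst/scripts/gpcrpocket volume --pdb demo/bundle.pdb --map demo/map.tsv
Rscript inst/scripts/gpcrpocket make-restraints --pdb demo/bundle.pdb \
    --map demo/map.tsv --seed 7 --out demo/restraints.cst
```

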