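# gagshape

Conformational shape descriptors for glycosaminoglycan (GAG) conformer
ensembles — heparin, hyaluronan, chondroitin sulfate and friends.

MD studies of GAGs compare solvent models, force fields or constructs
through a standard battery of structural descriptors. `gagshape`
implements that battery as tested R functions over a simple ensemble
container (multi-model PDB / multi-frame XYZ in, tables and grids out):

- **Global shape** — end-to-end distance (EED), mass-weighted radius of
  gyration R<sub>g</sub>, RMSD after optimal proper superposition (Kabsch,
  det(R) = +1), per-atom fluctuations (RMSF about the iterated mean
  structure), and molecular volume as the **minimum-volume enclosing
  ellipsoid** (MVEE), computed by deterministic Khachiyan multiplicative
  weights with away steps to a 1e-7 KKT gap:
  V = (4π/3)·det(A)<sup>−1/2</sup> for the ellipsoid
  {x : (x−c)ᵀA(x−c) ≤ 1}.
- **Ring puckering** — the pyranose torsions τ₁ = C1–C2–C3–C4 and
  τ₂ = C1–O5–C5–C4 classified into ⁴C₁ / ¹C₄ / ²S_O / OTHER, validated
  against Cremer–Pople ring geometry, with per-ring occupancy tables.
- **Glycosidic linkages** — φ = O5′–C1′–O4–C4, ψ = C1′–O4–C4–C3 per
  frame, pooled per ordered linkage type, and free-energy surfaces by
  Boltzmann inversion ΔG = −RT ln(p/p_max).
- **Hydrogen bonds** — geometric criterion (D–A ≤ 3.0 Å, D–H–A ≥ 135°,
  configurable) and the symmetric residue×residue occupancy map.
- **Synthetic ensembles with known ground truth** — arc-shaped chains
  (extended / "U" / "O"), rings planted at Cremer–Pople states, von Mises
  dihedral mixtures, planted hydrogen-bond occupancies, and a labelled
  synthetic heparin dp12 helix — so every analysis stage is verifiable
  without running MD.

## Worked example

Build the synthetic heparin dodecasaccharide helix (two models, mirroring
the two deposited NMR conformers), construct the standard dp10 analysis
window from the ¹C₄-iduronate model, and compute its descriptors:

```r
library(gagshape)

hp <- synthetic_heparin_dp12()
hp
#> conformer_ensemble: 2 frame(s), 300 atoms, 12 residue(s)
#>   residues: IDS SGN IDS SGN IDS SGN IDS SGN IDS SGN IDS SGN

dp10 <- build_dp10(hp)          # picks the 1C4 model, keeps residues 1..10
summarize_series(end_to_end_distance(dp10))
#> dist: 40.88 +/- 0 (n = 1)
summarize_series(radius_of_gyration(dp10))
#> radgyr: 12.76 +/- 0 (n = 1)
summarize_series(volume_series(dp10))
#> volume: 5502 +/- 0 (n = 1)

pucker_occupancy(dp10)[1:4, ]
#>   residue_index residue_name terminal frac_4C1 frac_1C4 frac_2SO frac_other
#> 1             1          IDS     TRUE        0        1        0          0
#> 2             2          SGN    FALSE        1        0        0          0
#> 3             3          IDS    FALSE        0        1        0          0
#> 4             4          SGN    FALSE        1        0        0          0
```

EED ≈ 40.9 Å, R<sub>g</sub> ≈ 12.8 Å and MVEE volume ≈ 5502 Å³ for the
extended helical decasaccharide; iduronate rings classify ¹C₄ and
glucosamine rings ⁴C₁, as they should for this construct.

Ground-truth recovery on a generated ensemble — a "U"-shaped chain whose
noise-free EED is the semicircle chord 2L/π = 28.65 Å:

```r
ens <- generate_arc_chain(turn_angle = 180, noise_sigma = 0.1,
                          n_frames = 50, seed = 1)
summarize_series(end_to_end_distance(ens))
#> dist: 28.67 +/- 0.161 (n = 50)
```

The full pipeline (descriptor summaries, pucker tables, free-energy
grids, contact maps, provenance and a checksum manifest) runs over any
set of labelled ensembles via `run_analysis()` / `write_report()`, or
from a shell through the thin wrapper
`inst/scripts/gagshape-cli.R` (`analyze` and `simulate` subcommands).

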