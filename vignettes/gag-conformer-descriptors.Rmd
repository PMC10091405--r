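---
title: "Conformational descriptors for glycosaminoglycan conformer ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational descriptors for glycosaminoglycan conformer ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gagshape)
```

## The problem

Glycosaminoglycans (GAGs) — heparin, hyaluronan, chondroitin sulfate — are
linear, highly anionic polysaccharides whose biology is driven by their
conformational behavior: overall chain shape (extended, "U"-shaped, or
nearly closed "O"-shaped), pyranose ring puckering, glycosidic linkage
geometry, and intramolecular hydrogen bonding.  Molecular-dynamics studies
of GAGs produce conformer ensembles — multi-model PDB files or
trajectories — and compare them through a standard battery of descriptors.
`gagshape` implements that battery as reusable, tested R functions:

* **Global shape**: end-to-end distance (EED), mass-weighted radius of
  gyration ($R_g$), Kabsch-superposed RMSD against a fixed reference,
  per-atom fluctuations (RMSF), and the molecular volume measured as the
  minimum-volume enclosing ellipsoid (MVEE) of the atom cloud.
* **Ring puckering**: the two ring torsions per pyranose, classified into
  the chair ($^4C_1$, $^1C_4$) and skew-boat ($^2S_O$) states, with
  per-ring occupancy tables.
* **Glycosidic linkages**: per-linkage $\varphi/\psi$ series, populations
  pooled per ordered linkage type, and Boltzmann-inverted free-energy
  surfaces.
* **Hydrogen bonds**: geometric-criterion detection and the
  residue-by-residue occupancy contact map.

Every stage is verifiable without running MD: the package ships synthetic
conformer-ensemble generators with *known ground truth* — arc-shaped
chains of tunable curvature, rings planted at prescribed Cremer–Pople
pucker states, von Mises mixtures of dihedral angles, and two-residue
fixtures with planted hydrogen-bond occupancies.

## The data model

A `conformer_ensemble` is a topology (atom names, elements, masses,
residue assignment) plus an `n_frames × n_atoms × 3` coordinate block in
Ångström.  `read_structure()` builds one from a multi-model PDB (one frame
per `MODEL`) or multi-frame XYZ file; `write_ensemble()` round-trips to
the PDB coordinate precision of $10^{-3}$ Å.  Atom and residue indices are
1-based, the R convention; author residue numbers are preserved in the
topology for reporting.

Rings are recognized by atom-name pattern (presence of O5, C1..C5), not by
residue-name whitelist — PDB and force-field residue codes differ across
dialects while ring atom names are stable.  An alias table
(`heparin_aliases()`) maps component codes such as `SGN`/`IDS` to the
display names GlcNS6S/IdoA2S used in linkage-type labels.

## Descriptor conventions

Choices that affect comparability are explicit and overridable:

* **EED endpoints** default to C1 of the first (nonreducing-end) residue
  and C4 of the last residue — the glycosidic anchor atoms that carry the
  1→4 chain.  Any other endpoint pair can be passed explicitly.
* **$R_g$** is mass-weighted over *all* atoms including hydrogens, the
  common trajectory-toolkit default.
* **RMSD and RMSF** use all non-hydrogen atoms by default, because
  hydrogen placement in experimental models is model-dependent.  The RMSD
  rotation is constrained to determinant +1, so mirror images retain a
  strictly positive RMSD.
* **RMSF** is computed about the iterated mean structure: frames are
  superposed onto the running mean, the mean recomputed, until it moves
  by less than $10^{-6}$ Å (at most 10 iterations).  The summary is
  mean ± SD *over atoms*, and reports label it as such, since an
  over-time-windows convention also exists in the literature.
* **All summary SDs are population SDs** (divide by $n$): these are frame
  statistics, not sample estimates of a larger population.  Replicate runs
  aggregate as mean-of-run-means ± population SD of the run means
  (`aggregate_runs()`).

## Minimum-volume enclosing ellipsoid

The volume descriptor is the volume of the Löwner ellipsoid
$\{x : (x-c)^\top A (x-c) \le 1\}$ of the selected atoms, by default all
atoms — the natural reading of the space occupied by the molecule.
`minimum_volume_ellipsoid()` solves the lifted $(d+1)$-dimensional
formulation with Khachiyan-style multiplicative weights plus Wolfe–Atwood
away/drop steps, which converge linearly near the optimum.  Iteration
stops when both sides of the KKT gap fall below the tolerance (default
$10^{-7}$), which guarantees every point satisfies
$(x-c)^\top A(x-c) \le 1 + 10\,\varepsilon$ and at least one support point
lies on the boundary — the minimality witness asserted by the tests.  The
algorithm is deterministic.  Coplanar or collinear input raises a
degenerate-geometry error rather than being silently regularized: a flat
"ellipsoid" of volume zero would corrupt descriptor summaries unnoticed.
The test suite cross-checks the converged volumes against an independent
interior-point log-barrier optimizer of $-\log\det A$ on small instances,
and against closed forms (octahedron → unit ball, cube → circumscribed
ball).

## Ring puckering

The two torsions $\tau_1$ = C1–C2–C3–C4 and $\tau_2$ = C1–O5–C5–C4 carry
the classification.  Conventions, stated once: ring atoms are ordered O5,
C1..C5; Cremer–Pople $\theta = 0$ is the $^4C_1$ chair of D-pyranoses;
$\theta = 180°$ is $^1C_4$; the $^2S_O$ skew-boat sits on the $\theta=90°$
equator at the pseudorotation phase $\varphi = 150°$, where C2 lies above
and O5 below the mean plane.

The classification windows were fixed by *validating against ideal
Cremer–Pople geometry*, using the package's own ring generator as oracle.
Ideal values of $(\tau_1, \tau_2)$ are $(-54°, +54°)$ for $^4C_1$,
$(+54°, -54°)$ for $^1C_4$, $(-48°, -48°)$ for $^2S_O$ and $(+48°, +48°)$
for its mirror $^OS_2$.  A plausible-looking alternative — requiring
$|\tau_1| \le 20°$ for the skew — turns out to be geometrically
unreachable: on ideal equator rings the radial symmetry of the ring forces
$\tau_1 = \tau_2$ identically, so no equator state has one torsion near
zero and the other chair-like.  The released rule is therefore a sign
pattern on the magnitude window $(20°, 80°)$: $(-,+) \to {}^4C_1$,
$(+,-) \to {}^1C_4$, $(-,-) \to {}^2S_O$, anything else (including the
planar ring and $^OS_2$) → `OTHER`.  Every class sits ~30° from the
nearest window edge, so classification survives 0.05 Å coordinate noise
with ≥ 99% agreement (asserted over $10^4$ generated frames).

Terminal rings are *flagged, never filtered*: force fields are known to
disrupt ring conformation at chain termini, and that artifact should stay
visible in occupancy tables.

## Glycosidic free-energy landscapes

$\varphi$ = O5$_{n+1}$–C1$_{n+1}$–O4$_n$–C4$_n$ and
$\psi$ = C1$_{n+1}$–O4$_n$–C4$_n$–C3$_n$, IUPAC sign convention, wrapped
to $(-180°, 180°]$.  Populations are pooled per *ordered* linkage type
(A→B never mixes with B→A, which form separate panels in GAG studies) and
binned on a 5° grid — 72 × 72 bins, fine enough to resolve wells ~50°
apart in $\psi$ while keeping ≥ 10 counts per occupied bin at the
$10^4$–$10^5$ sample sizes used here.  Bins are half-open $[{\rm lo},
{\rm hi})$ and wrap-consistent (+180° joins the −180° bin).

Boltzmann inversion uses $\Delta G_b = -RT \ln(p_b / p_{\max})$ with
$R = 1.9872 \times 10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ and $T = 300$ K by
default (the usual simulation temperature; overridable).  Empty bins have
no defined free energy; they are assigned the value of a half count and
flagged, so heatmaps render finite, and they are excluded from any
minimum determination.  Multiplying all counts by a constant leaves
$\Delta G$ unchanged, and the global minimum over non-empty bins is
exactly 0 — both asserted as invariants.

## Hydrogen bonds

Donors are O/N atoms with an attached hydrogen (bond inferred from a
heavy–H distance < 1.2 Å in the first frame, or name pairing when no
coordinates are available); acceptors are all O/N.  The default criterion
is donor–acceptor distance ≤ 3.0 Å *and* D–H–A angle ≥ 135° — the common
trajectory-toolkit defaults; when a topology carries no hydrogens the
distance cut alone applies and the output is flagged as heavy-atom-only.
Occupancy is per unordered residue pair (direction collapsed), the
fraction of frames with at least one bond between the two residues; the
matrix is symmetric with the diagonal holding intra-residue bonds.
Tightening the criterion can only shrink occupancies (a tested
monotonicity invariant).

## The synthetic generators — what they emulate and what they do not

All generators draw randomness from a single integer seed through a
private RNG stream, so identical spec + seed yields bit-identical
ensembles and the caller's RNG state is never touched.

* `generate_arc_chain()` places unit anchors on a planar circular arc of
  total turn $\Theta$: 0° is the extended chain, ≈180° the "U", ≈330° the
  "O".  Each unit carries a fixed, documented 9-atom motif (C1..C5, O5,
  O4, O3, HO3) so the end-to-end, linkage and hydrogen-bond stages all
  run; the last unit's motif is mirrored so C4 sits exactly on the
  terminal anchor, making the default EED exactly the first-to-last
  anchor chord $2r\sin(\Theta/2)$, $r = L/\Theta$ — a closed form the
  tests exploit.  The hydroxyl points along the in-plane normal so that
  *near-closed* arcs ($\Theta \gtrsim 340°$) bring a terminal donor and
  acceptor into bonding geometry, giving a deterministic first↔last
  residue contact that extended chains lack.  Noise is isotropic Gaussian
  per atom per frame — the simplest model sufficient for robustness
  tests; heavier-tailed or correlated noise is out of scope.
* `generate_ring()` builds a six-membered ring as a regular hexagon plus
  Cremer–Pople out-of-plane displacements at prescribed $(q, \theta,
  \varphi)$; re-analysis reproduces the planted coordinates within 1° and
  0.01 Å at zero noise.
* `generate_dihedral_samples()` draws $(\varphi, \psi)$ pairs from a von
  Mises mixture (Best–Fisher rejection sampling, implemented in-package
  since no circular-statistics package is available in the dependency
  set).
* `generate_hbond_toggle()` plants a Bernoulli hydrogen-bond occupancy by
  switching a donor/acceptor pair between a bonded (2.8 Å, ~180°) and a
  far-apart geometry frame by frame.

What passing recovery tests on these fixtures shows: the analysis chain
is *correct* — planted shapes, pucker fractions, well centers and
occupancies come back at their known values through the full I/O →
analysis → report path.  What it does not show: anything about force
fields, solvent models, or sampling convergence of real MD; the fixtures
are geometric idealizations with uncorrelated noise, not physical
ensembles.

## The synthetic heparin helix

For descriptor comparison against the experimental heparin
dodecasaccharide NMR entry, the package includes
`synthetic_heparin_dp12()`, an idealized, atomically decorated model
built from published structural knowledge of the heparin helix: 12
alternating IdoA2S/GlcNS6S residues (IdoA2S at the nonreducing end), a
helix with 4.2 Å rise and 90° twist per residue — the two-fold screw
relating successive disaccharides (8.4 Å and 180° per disaccharide) —
GlcNS6S rings in $^4C_1$ throughout, and two frames mirroring the two
deposited models: iduronate rings in $^2S_O$ (frame 1) or $^1C_4$
(frame 2).  Substituents (N- and O-sulfates, carboxylate, hydroxyls,
hydrogens) are placed at standard bond lengths with heavy substituents
equatorial.  This is a labelled synthetic stand-in, not the deposited
entry; its geometry parameters were fixed from the helix literature
before any descriptor was computed and not adjusted afterwards.

`build_dp10()` reproduces the standard analysis construct: select the
model whose iduronate rings classify as $^1C_4$ (the conformation chosen
for MD starting structures), then keep 10 residues from the nonreducing
end.  Both the model and the window are overridable, since the exact
truncation used in any given study is rarely stated.  On this construct
the package computes EED 40.9 Å, $R_g$ 12.8 Å and MVEE volume 5502 Å³
(the acceptance script recomputes these), in line with the
experimental-structure descriptor column reported for heparin dp10
(41.0 Å, 12.8 Å, 5325 Å³); the remaining few-percent volume gap is the
expected cost of idealized substituent placement, and would also move at
the few-percent level under a heavy-atom-only volume convention.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use sizes chosen to make
statistical assertions sharp while completing in minutes on one CPU:
$10^3$–$10^4$ frames for pucker and occupancy recovery, $10^5$ pooled
samples for two-well landscape recovery, 1000 random point clouds for
MVEE enclosure invariants, and 100 random 5-point instances for the
superposition oracle.  MVEE tolerance is $10^{-7}$ on the KKT gap;
superposition treats reference clouds with a vanishing second singular
value as degenerate (collinear); torsions with collinear atom triples
raise rather than return an arbitrary angle.

## Known limitations

* Ring classification covers the three states relevant to GAG analysis
  plus `OTHER`; it is not a full 38-state Cremer–Pople classifier, and
  furanoses are out of scope.
* Hydrogen-bond analysis is intramolecular and geometric; water-mediated
  bridges and lifetime kinetics are not computed.
* The synthetic heparin helix approximates the experimental entry's
  descriptors at the few-percent level but is not a substitute for the
  deposited coordinates when absolute per-atom detail matters; pass the
  real entry through `read_structure()` + `build_dp10()` when it is
  available.
* Volume is the MVEE volume specifically — deliberately *not* a convex
  hull or solvent-accessible volume, which are different descriptors.
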