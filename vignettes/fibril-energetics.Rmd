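---
title: "Solvation energetics of amyloid fibril models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solvation energetics of amyloid fibril models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Amyloid fibrils are stacks of identical protein chains related by a helical
rise and twist. A practical way to rank the stability of fibril polymorphs
is a solvation (buried-surface-area) free energy: each atom of an interior
chain buries some of its solvent-accessible surface area (SASA) when the
chain sits inside the fibril, and each square Angstrom of buried area is
assigned an energy by an atomic solvation parameter (ASP) that depends on
the atom's chemistry. Summing over a chain's atoms gives a stabilization
free energy per chain, ΔG°; dividing by the number of ordered residues
gives an energetic efficiency per residue. Plotting fibril structures on
these two axes separates weakly stable intermediates from the tightly
packed folds extracted from patient tissue.

`fibrilstab` implements this pipeline for tau fibrils formed with RNA
cofactors, including the device used to model a bound polyanion: *charge
compensation*, where the burial penalty of specific lysine, arginine and
histidine nitrogens — those facing RNA density — is removed.

```{r, eval = FALSE}
library(fibrilstab)
stack <- synthetic_standin("9o8e")          # 5 layers, core S341-H449
ch    <- central_chain_ids(stack)
areas <- buried_areas(stack, ch)
plain <- chain_summary(residue_energies(areas), ch)
comp  <- chain_summary(apply_charge_compensation(
           areas, asp_table(), builtin_compensation_specs()[["9o8e"]]), ch)
```

# The model, step by step

## Helical expansion and the central chain

A deposited fibril model is a single layer (one chain per protofilament) or
a short stack. `apply_helical_symmetry()` generates an N-layer stack: layer
k is the input rotated by k·twist about the fibril axis and translated by
k·rise along it. Energies are always evaluated on a chain of the **central
layer**, so that both axial neighbours (and the partner protofilament, if
any) occlude it; at least three layers are required, five is the default
evaluation depth, matching standard practice for deposited fibril models.
The expansion *centres* the input layer — whether published five-layer
models centre the deposited layer or append upward is not documented
anywhere we know of; centring is the symmetric choice and only affects
which chain is "central", not its environment.

`estimate_helical_params()` solves the inverse problem: Kabsch-superpose
the Cα atoms of layer k onto layer k+1, then screw-decompose the rigid
transform (angle from the rotation-matrix trace, axis from the rotation,
rise as the translation component along the axis, axis oriented so rise is
positive). Averaging over layer pairs — with the twist averaged on the
circle, to behave near ±180° — is exact on noise-free stacks and accurate
to ~0.02 Å / 0.01° under 0.1 Å coordinate noise. Paired protofilaments
related by a pseudo-2₁ screw appear as |twist| ≈ 180° with roughly halved
rise, and are labelled `pseudo_21_paired` within a 5° window.

Generated fibrils are left-handed by default (negative small twists), as
most amyloid fibrils are presumed to be; sign conventions follow the
deposited parameters.

## SASA: Shrake–Rupley with a deterministic lattice

`sasa()` places a quasi-uniform golden-angle spiral lattice (no RNG) of
`n_sphere_points` points on each atom's expanded sphere (vdW radius +
probe, probe default 1.4 Å) and counts points not inside any neighbour's
expanded sphere. Radii default to C 1.70, N 1.55, O 1.52, S 1.80 Å with a
1.70 Å fallback — implementation defaults, configurable via
`radius_set()`. Hydrogens are always removed first; heteroatoms are
excluded by default (optionally retained as occluders only), because the
energy model sums over protein residues.

Two exactness properties pull in different directions. With a lattice fixed
in the lab frame, adding occluders can only remove accessible points, so
monotonicity is *exact* — but rotating the whole model shifts which points
survive, so rigid-motion invariance is only approximate. We therefore
evaluate, by default, in a canonical frame: coordinates are rotated into
the model's principal axes (signs fixed by third moments, proper rotation
enforced). The frame co-rotates exactly with any rigid motion, making SASA
*exactly* invariant under rigid motion of the model. The price is that the
frame depends on the full atom set, so monotonicity under *added* occluders
is exact only at fixed orientation — `sasa(..., orient = FALSE)` exposes
that mode, and the tests check each property in the regime where the
estimator guarantees it. For near-symmetric models with degenerate
principal axes the canonical frame is arbitrary but still deterministic
for a given input.

The default `n_sphere_points = 960` leaves the total buried area of a
fibril chain converged to well under 0.5% (doubling the count is part of
the test suite); 4000 points reproduce an independent brute-force oracle
(different lattice, naive all-pairs occlusion, pure R:
`brute_force_sasa()`) to ~0.1% total area.

## The reference state for "buried" area

"Area buried" needs a reference. The unfolded-chain reference used by the
established buried-area energy methods is approximated per residue by a
**tripeptide-like in-situ host**: each residue is scored inside the
fragment consisting of itself plus its covalently adjacent residues
(author numbering ±1), extracted with its in-fibril coordinates. Buried
area is then `max(0, reference − assembly)` per atom. This choice makes
ΔG° ≈ 0 for a fully extended isolated chain and reproduces the
stabilization-on-assembly convention; the precise in-house reference used
to produce published tables is not public, which is the main reason
absolute ΔG° values carry a tolerance of order ±15% when compared across
implementations.

## From area to energy

The ASP table has five classes — apolar carbon, polar N/O, carboxylate
O⁻, charged N⁺, sulfur — with the classic Eisenberg–McLachlan parameters
(+16, −6, −24, −50, +21 cal mol⁻¹ Å⁻², shipped as a versioned TSV, fully
overridable). Energies are reported as stabilization free energies:

    ΔG(residue) = − Σ_atoms σ(class) · buried_area

so burying apolar carbon is stabilizing (negative) and burying a charged
nitrogen is a positive penalty; stable fibrils come out negative, matching
the published sign convention. Histidine nitrogens are classified polar by
default (neutral His); `asp_table(his_charged = TRUE)` flips them to
charged. A chain's ΔG° is exactly the sum of its residue contributions,
and ΔG° per residue divides by the number of residues modeled in the
evaluated chain. For paired protofilaments the two central chains are
summarized separately and averaged.

## Charge compensation

A bound polyanion is modeled by *nullifying penalties*, not by moving
atoms: for each residue in a `compensation_spec()` the energy terms of its
designated nitrogens — Lys NZ (1), Arg NE/NH1/NH2 (3), His ND1/NE2 (2) —
are set to zero *when positive*. Negative terms are untouched, so
compensation can only stabilize (a property the tests enforce against
random specs). Nullifying per-atom terms and re-classifying the atoms
coincide whenever the term is positive; per-atom nullification is
implemented because it is the literal reading of "penalties were removed".

Built-in specs carry the published residue lists for the three RNA-tau
fibrils. Two editorial notes, recorded rather than silently fixed: the
published compensation list for the AD-seeded fibril prints "K783", which
does not exist in tau numbering and is read here as K383 (the position
named in the accompanying proximity list); and the proximity list for that
fibril (adding H374/H388, dropping K343/K347/R349) differs from the
compensation list — the compensation list is the one used in the published
calculation, and the proximity variant ships as the separate builtin
`9o8e_proximity`.

## Segment superposition

`segment_rmsd()` pairs residues strictly by position within two
closed author-numbered ranges of equal length (the published comparisons
superpose *different* sequence spans, e.g. N359–K383 onto V318–E342, so
sequence-identity pairing is impossible by construction), takes Cα atoms by
default, and delegates to a standard SVD Kabsch solver with the
determinant correction (never a reflection). Which atom set produced the
published RMSD values is unstated; Cα is the field default and the
acceptance tolerance (±0.2 Å) absorbs the difference.

## The stability landscape

`load_atlas_table()` ingests an Amyloid-Atlas-style table (heuristic or
explicit column mapping; rows with blank energies are skipped and
counted), `classify_stability()` places any ΔG°-per-chain against the ex
vivo band — default [−47, −29] kcal/mol, endpoints inclusive and
overridable since the published range is approximate — and
`export_landscape()` writes a deterministic JSON plot-spec with
before/after compensation links.

# The synthetic generator: what it emulates, and what a green test means

`make_layer()`/`make_fibril()` build fibrils with the structural features
the analysis relies on: residues at ~4.8 Å Cα–Cα spacing along a straight,
C-shaped (240° arc) or S-shaped (two opposed half-turns) in-plane path;
full heavy-atom side chains from idealized internal templates (correct
atom names, counts and bond-plausible distances; alternating sides of the
path), one chain per protofilament, stacked by rise/twist, with optional
seeded Gaussian jitter (default off). `synthetic_standin()` instantiates
the studied structures with their true core sequences (from the 449-residue
tau40-His construct, shipped as FASTA), author numbering and deposited
helical parameters.

What the generator does **not** emulate: real β-sheet hydrogen-bond
geometry, rotamers, steric-zipper packing density, or RNA atoms. Green
tests on synthetic fibrils therefore establish the *mechanics* —
bookkeeping identities, symmetry operations, monotonicity, oracle
agreement, sign conventions, residue counts — not agreement with published
absolute energies or inter-fold RMSDs, which require the deposited
coordinates. The tests that do compare against published absolute values
run the genuine code path and fail with instructions when the deposited
files are absent (drop `<accession>.cif` into
`options(fibrilstab.deposited_dir=)`); they are deliberately not skipped.
That said, the stand-ins land close to the published energies (e.g. the
compensated AD-seeded stand-in within ~13% of the printed per-chain
value), because core size, composition and packing scale dominate the
statistic.

# Numerical choices and degenerate inputs

* Sphere points ≥ 60 enforced; defaults 960 (pipeline) / 10,000 (oracle).
* Kabsch requires ≥ 3 non-degenerate points; reflection-requiring inputs
  still return a proper rotation (the optimum under that constraint).
* Screw decomposition near 0° returns a pure translation; near 180° the
  axis comes from the column space of R + I; twist averaging is circular.
* Altloc resolution is deterministic: `first_conformer` (default,
  alphabetical; chosen because the published energies do not state which
  conformer of the flexible N327–E342 stretch entered the sums) or
  `highest_occupancy` with alphabetical tie-break.
* Layer annotations: explicit, from `_Lk` chain-id suffixes, or inferred
  geometrically for deposited-style stacks (identical chains ordered along
  the principal axis of their centroids).
* Config files are JSON (`jsonlite`); every numeric default lives in
  `run_config()`; reruns are byte-identical.

# Known limitations

* Absolute ΔG° values depend on the unpublished reference state and ASP
  set behind the published tables; cross-implementation agreement is
  expected only within the stated tolerances.
* The energy model is burial-only: no electrostatics beyond the ASP
  classes, no conformational entropy, no protonation/pKa.
* RNA is represented only through compensation residue lists; RNA atoms
  are never modeled.
* The mmCIF reader covers coordinate-file `atom_site` loops only.
* Synthetic geometry is non-physical by design (see above).
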