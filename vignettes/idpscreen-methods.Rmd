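---
title: "Methods: ensemble fragment mapping and docking screens for disordered proteins"
author: "idpscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble fragment mapping and docking screens for disordered proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An intrinsically disordered protein (IDP) has no single folded structure: it
populates an ensemble of rapidly interconverting conformations.  Structure-based
drug discovery against such a target cannot start from "the" structure, but it
can start from the ensemble.  The premise of this package is that individual
members of the ensemble -- particularly the more compact ones, which bury
surface and form transient tertiary contacts -- can present genuine concave
binding pockets, and that a small molecule binding such a pocket may shift the
ensemble's behaviour.

`idpscreen` implements the corresponding three-step computational screen:

1. **Characterize and select.**  Read a multi-model ensemble, compute per-conformer
   radius of gyration (Rg), solvent-accessible surface area (SASA) and
   non-bonded contact count, and select a small, structurally diverse subset
   with a bias towards compact members.
2. **Map.**  Dock a set of small fragment probes exhaustively over each selected
   conformer's surface, cluster the strongest poses into *hot spots*, score hot
   spots by potential ligand efficiency, and assemble proximal high-ranking hot
   spots into *pockets*.
3. **Screen.**  Dock every member of a fragment-like compound library
   (molecular weight < 325 Da) into every pocket with a rigid receptor and a
   flexible ligand, and rank compounds within each pocket.

## Per-conformer descriptors

- **Rg** is the root-mean-square distance of (by default) heavy atoms from
  their centroid, unweighted because ensembles vary in protonation; mass
  weighting is available.
- **SASA** uses Shrake-Rupley sampling with a deterministic golden-spiral
  point set (default 960 points/atom, water probe 1.4 Å).  At 960 points the
  isolated-sphere error is below 2%.
- **Contacts** are heavy-atom pairs within 5.4 Å whose residues are at least
  3 apart in sequence.  Published uses of this descriptor rarely quantify it;
  these two numbers are package choices, configurable everywhere they appear.  The
  spatial-hash implementation is exactly equivalent to the brute-force double
  loop (tested).

**Diversity selection.**  Conformer-conformer distance is distance-matrix RMSD
over Cα atoms: the RMS difference of internal distance matrices.  We chose it
over superposed RMSD because optimal superposition is ill-conditioned for
disordered chains (it mostly measures the failure of superposition, not
conformational difference).  Selection is greedy weighted max-min: each
conformer carries a compactness weight `exp(-bias * (Rg_i - Rg_min) /
(Rg_max - Rg_min))`; the first pick is sampled proportionally to the weights
under a seed, and each later pick maximizes weight times the minimum distance
to the already-selected set.  `bias_strength = 0` is plain max-min diversity;
the default 1 gives a mild compactness bias.  The quantitative form of the
bias is a package design choice -- only its direction (towards compact
members) is inherited from the method being reproduced.

## The interaction model

The docking engine is deliberately a *desk-scale surrogate* for the kind of
commercial pipeline used in production fragment screens (exhaustive
rigid-body docking, semi-empirical ligand charges, molecular-mechanics
minimization with a Poisson-Boltzmann solvent).  One force field is used for
both scanning and minimization:

- **van der Waals:** 12-6 Lennard-Jones,
  `eps_ij [(rmin_ij/r)^12 - 2 (rmin_ij/r)^6]`, with `rmin_ij = rmin_i +
  rmin_j`, `eps_ij = sqrt(eps_i eps_j)`, shifted to zero at the 9 Å cutoff.
  Per-element parameters come from a small built-in table (editable JSON);
  full force-field atom typing is deliberately not reproduced.
- **Electrostatics:** Coulomb with distance-dependent dielectric
  `eps(r) = 4r`, i.e. `332.06 q_i q_j / (4 r^2)` kcal/mol, shifted at the
  cutoff.  Ligand partial charges are Gasteiger charges (computed by RDKit
  through the bundled Python backend) with hydrogen charges folded into their
  parent heavy atoms, a documented surrogate for semi-empirical AM1/BCC
  charges.
- **Desolvation:** a surface-area term.  The implicit-solvent convention is
  `E_solv = sigma * SASA`, so the binding contribution is
  `sigma * (SASA_bound - SASA_free) = -sigma * (buried ligand surface)` with
  `sigma = 0.025` kcal/mol/Å²: burial is stabilizing.  We compute the buried
  area analytically from pairwise sphere-cap overlaps rather than by point
  sampling; this is smooth, fast, and *exactly* rotation invariant, which
  sampled SASA is not.  (A sign-flipped reading -- burial as a pure penalty --
  was tried and rejected: at this coarse resolution it overwhelms the vdW term
  and pushes every minimized pose off the protein, contradicting the method's
  own purpose.)

Units are fixed throughout: kcal/mol, Å, elementary charges; Coulomb constant
332.06 kcal·Å/(mol·e²).

**Pose search.**  Placement centres are grid points (default spacing 2 Å)
whose surface offset -- distance to the nearest atom centre minus that atom's
vdW radius -- lies in [1, 4] Å.  Each centre is combined with uniformly
sampled rigid orientations (Shoemake quaternions, seeded) and each ligand
conformer; every candidate is scored in compiled code, the best non-clashing
candidates are locally minimized (quasi-Newton on rigid translation +
rotation + rotatable-bond torsions; protein fixed; energy can only decrease
because the start is kept when the optimizer fails to improve), and the
`top_k` lowest-energy poses are returned.  Everything is deterministic given
the seed.

## Hot spots, L_e and pockets

Poses from all probes on one conformer are pooled and clustered by greedy
leader clustering on pose centroids (strongest pose first, leader radius
3.5 Å).  A cluster becomes a hot spot only if at least two *distinct* probes
bind it: a hot spot is by definition a locus where different probes
accumulate, and single-probe clusters carry un-averaged, systematically
optimistic scores.

Hot spots are ranked by **potential ligand efficiency**

    L_e = ( sum over distinct probes of  E_vdW(best pose) / heavy atoms ) / N_probes

using only the van der Waals component, per the defining formula; `e_total`
is used to pick poses but never enters L_e.  Where the source method is
ambiguous about summing all bound poses versus the best pose per probe, we
take the best pose per probe (flagged choice).  Ties are broken by distinct
probe count, then lexicographically by centroid, so ranking is deterministic.

**Pockets** are connected components (edges = centroid distance <= 8 Å) of
the top 25% of ranked hot spots, keeping components with at least two
members.  Because "two or more high-ranking hot spots" is the *definition* of
a pocket, the high-ranking cut is floored at two hot spots -- otherwise the
definition would be vacuous whenever a conformer has fewer than eight hot
spots.  Pocket lining residues are those with a heavy atom within 4.5 Å of
any member pose atom; a pocket is flagged *long-range* when two lining
residues are >= 12 residues apart in sequence, marking the
conformation-specific tertiary-contact sites the method is designed to find.
The 3.5 / 8 / 0.25 / 4.5 / 12 values are explicit stand-ins for quantities
the source method leaves unspecified; all are arguments and all are echoed
into the run summary.

## The screen

Libraries are read from SMILES or SDF V2000 via RDKit (bundled Python
backend): simple pH 7.4 rules (carboxylic acids deprotonated, aliphatic
amines protonated) fix the charge state, molecules are classed neutral or
charged, 3D conformers are embedded with a seeded ETKDG, and hydrogens are
stripped after their charges are aggregated.  The fragment-like filter keeps
molecular weight strictly below 325 Da.  Docking into a pocket restricts the
search box to the pocket's bounding box plus a 4 Å margin and is otherwise
the same engine.  Within a pocket, `E_rank` is the 1-based position by
minimized `e_total` and `L_Re = e_total / heavy_atom_count`.  Hit selection
keeps `e_total <= -4` kcal/mol and `L_Re <= -0.25` kcal/mol/heavy-atom (the
source's cutoffs are unstated; these defaults are configurable), caps each
pocket at 20, and deduplicates across pockets keeping each ligand's
best-energy pocket.

## The synthetic world

Real IDP ensembles with published coordinates at this scale do not exist for
the original target, so the package carries its own generator; it is
first-class, tested code, and its outputs flow through the public PDB/SMILES
interfaces.

- **Chains** are self-avoiding Cα random walks (3.8 Å steps, 2.6 Å clash
  floor, bounded backtracking) with one pseudo side-chain heavy atom per
  residue, confined to spheres whose radii are stratified across models so
  every ensemble covers the compact-to-extended continuum (max/min Rg ratio
  >= 1.5 at the default spread).
- **The planted pocket** (model 1 when requested) threads a 34-residue
  stretch over a deep spherical cap (polar angle up to ~137°, shell radius
  `cavity_radius + 2.6`), giving a concave bowl whose interior and approach
  column no other atom may enter.  Wall side chains are oxygen (deep vdW
  wells, net negative charge under the default table) and tilt *into* the
  bowl, while the rest of the chain is aliphatic and held away from the
  bowl's outer wall; the planted cleft is thereby the chain's one genuinely
  druggable site, closed by residues far apart in sequence (long-range
  contact by construction).  These quarantine margins are part of the
  fixture's definition of "planted truth": during development, free tails
  allowed to drape against the wall exterior created probe-sized slot sites
  that out-scored the cavity -- physically real behaviour, but not the truth
  the fixture is supposed to plant.
- **The toy library** samples a curated list of 45 valid fragment SMILES
  (with precomputed pH-7.4 molecular weights, verified in tests against
  atomic-mass summation), honouring a requested charged fraction and MW
  window.  Spec-style "substituent decoration" is not performed -- duplicates
  with distinct identifiers stand in for catalogue depth.
- **The planted binder** is benzylpiperazine: at pH 7.4 both ring nitrogens
  protonate (+2), pairing an aromatic anchor with a doubly charged head --
  shape- and charge-complementary to the oxygen-lined bowl.

What a green planted-pocket test establishes: the mapping machinery finds an
engineered, strongly differentiated concave site and the screen prefers a
designed complementary binder over random fragments.  What it does not
establish: performance on real all-atom ensembles, where competing surface
sites are abundant and the energy scale is far less separated.

## Numerical choices and degenerate inputs

- Energies are reported to 4 decimals in TSVs; JSON is written with sorted,
  stable structure for diffability; every output file is written to a
  temporary name and renamed, so partially written files never appear.
- One master seed drives everything; per-stage and per-(pocket, ligand) seeds
  are derived by a stable string hash below 2^31.
- Zero pockets, zero hits, empty pose lists and oversized ligands are valid,
  schema-stable results, not errors; impossible fixture geometry and
  mismatched ensembles are errors that name the offending model or stage.
- The LJ/Coulomb shift at the 9 Å cutoff means the pair well depth is
  `-eps` only up to an analytically known constant (< 2% of `eps` for
  carbon-carbon pairs); tests assert the exact shifted value.

## Known limitations

- The force field is a teaching-grade surrogate: no atom typing, no
  directional hydrogen bonds, no polarization, monopole-level electrostatics
  with a crude dielectric, and a one-parameter desolvation term.
- Probe and ligand conformers come from a single seeded embedding; ring
  flexibility and stereochemistry are not explored.
- Fixtures are Cα + pseudo-side-chain resolution, not all-atom; hydrogens
  are supported in input but all shipped computations are heavy-atom-only
  with aggregated charges.
- The hot-spot clustering radius, "high-ranking" fraction, proximity cutoff
  and hit thresholds are stand-ins for unpublished values; conclusions that
  depend on them should be checked for robustness by varying the
  configuration.
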