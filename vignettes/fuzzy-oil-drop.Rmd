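---
title: "The fuzzy oil drop model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fuzzy oil drop model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oildrop)
```

## The model

A water-soluble globular protein behaves like a fuzzy micelle: hydrophobic
side chains concentrate near the center of the molecule and polar ones face
the solvent. `oildrop` quantifies how closely a given structure realizes
that ideal.

Each residue is reduced to its *effective atom*, the unweighted mean of its
heavy-atom positions. Three per-residue distributions, each normalized to
sum to one, are compared:

* **T (theoretical)** — the molecule is centered, aligned so its longest
  effective-atom axis is X and the longest YZ-projection axis is Y, and
  enclosed in a 3D Gaussian whose standard deviations follow the 3-sigma
  rule, $\sigma_k = \max_i |k_i| / 3$ for $k \in \{x, y, z\}$. T is this
  Gaussian evaluated at the effective atoms and normalized. It is the
  hydrophobicity density each residue *would* carry if the molecule were a
  perfect micelle, and depends only on geometry.
* **O (observed)** — pairwise hydrophobic interactions collected over
  neighbors within a cutoff $c$:
  $O_i \propto \sum_{j \ne i} (H^r_i + H^r_j)\, w(r_{ij})$, with
  $w(r) = 1 - \tfrac12\left(7s^2 - 9s^4 + 5s^6 - s^8\right)$, $s = r/c$,
  $w \equiv 0$ beyond the cutoff. $H^r$ is the intrinsic hydrophobicity of
  the residue type under the active scale.
* **R (uniform)** — $1/N$ per residue: the complete absence of a core.

The distributions are compared by Kullback–Leibler divergence (base 2,
bits), and the *relative distance*

$$\mathrm{RD} = \frac{D_{KL}(O\|T)}{D_{KL}(O\|T) + D_{KL}(O\|R)}$$

locates O between the two references: RD < 0.5 means the observed
distribution is closer to the centric Gaussian ideal than to featureless
uniformity — the structure carries a micelle-like hydrophobic core.

## Tunable parameters

* **cutoff** (`cutoff`, Angstrom, default 9): the interaction radius of the
  observed-density collector. 9 Å is the value the contact function was
  originally parametrized with; changing it rescales the neighborhood O
  integrates over.
* **hydrophobicity scale** (`scale`): a required input mapping the 20
  standard residues to intrinsic hydrophobicities. The statistic itself is
  scale-agnostic, and published RD values for real proteins are only
  reproducible approximately (we treat ±0.05 as the reproduction band)
  unless the original scale is known. The shipped default is the
  Kyte–Doolittle scale rescaled linearly to [0, 1]
  (`default_scale()`); any two-column text file can be supplied via
  `read_hydrophobicity_scale()`.
* **classification thresholds** (`classify_residues()`): expressed in units
  of the uniform level $1/N$ so they are chain-length invariant. Defaults:
  core when $\min(T, O) \ge 1.5/N$, surface when $\max(T, O) < 1/N$
  (strictly below, so a perfectly flat profile classifies as
  hydrophobically insignificant rather than all-surface), discordant
  (excess/deficit) when $|T - O| \ge 1/N$. The underlying zone boundaries
  used in published figures are not stated anywhere we know of; these
  defaults are this package's own convention.

## Fragments and eliminations

The status of a chain fragment is always evaluated *inside* the structural
unit it belongs to: T and O are restricted to the fragment's residues and
renormalized to one, R becomes $1/n_\mathrm{fragment}$, but the orientation
and the Gaussian envelope of the parent are never re-derived
(`fragment_rd()`, `eliminate_and_rescore()`). Elimination of a range that
matches no residues is a no-op rather than an error, so scripted scans can
pass empty selections harmlessly. Ranges use author (PDB) numbering, e.g.
`"35,53,55-58"`.

## The early-stage intermediate

The partially unfolded (early-stage) form assumes backbone preferences
alone determine conformation: each residue's $(\phi, \psi)$ is replaced by
the nearest point $(\phi_e, \psi_e)$ of an elliptical path through
Ramachandran space, and an ideal-geometry backbone is rebuilt from the
projected dihedrals (`make_early_stage()`).

Numeric constants for that path (its axes, tilt and the positions of the
seven A–G stations) have, to our knowledge, never been published. We
therefore treat the path as a mandatory configuration object with a shipped
default rather than pretend to know ground truth: the default
(`default_ellipse_path()`) is an origin-centered ellipse, tilt 45°,
semi-axes (73.597463, 177.598292), fitted so the path passes exactly
through the canonical right-handed helix (−57, −47), beta (−120, +130) and
left-handed helix (+57, +47) points, which carry the C, E and G labels; D
is placed midway (by path parameter) between C and E, F between E and G,
and A, B divide the remaining arc evenly. Tests enforce the zone invariants
(helix→C, beta→E, left-helix→G, D between helix and beta, F after beta)
for any supplied path, and all early-stage behavior is interpreted relative
to the configured path; absolute RD values of rebuilt intermediates are
*not* comparable across path choices.

Projection details: both dihedral axes are periodic, so distances are
measured on the torus (equivalent to considering all ±360° images of the
query); the minimizer is located on a 3600-point sampling of the path and
refined locally to below 1e-6°, with exact ties resolved to the smallest
path parameter. Codes are assigned by nearest station in arc length.
Terminal residues lack one dihedral of the pair; their surviving angle is
kept unprojected and their code is undefined. Omega is fixed at 180°
(no cis-proline handling), and no optimization or relaxation step follows
the dihedral replacement — the intermediate is a pure backbone-geometry
construct, which also means its side-chain-free effective atoms
(mean of N, CA, C, O) are systematically closer to the backbone axis than
in the native form.

## The synthetic generator

`generate_cloud()` and `generate_backbone()` produce structures whose
ground-truth micelle-likeness is known by construction:

* *micelle*: positions drawn from the 3D Gaussian with $\sigma$ = aspect/3
  (default aspect 24 Å per semi-axis, the envelope of a small globular
  domain), residue types assigned so intrinsic hydrophobicity is
  rank-correlated with local Gaussian density. A minimum inter-residue
  distance of 3.6 Å (a typical effective-atom contact floor) is enforced by
  rejection, with an explicit packing error rather than an endless loop
  when the density is infeasible.
* *anti_micelle*: identical positions, reversed assignment — hydrophobicity
  on the surface.
* *uniform*: positions uniform in the ellipsoid, types random.
* *ideal_helix*: a continuous (−57, −47) backbone; an elongated helix
  cannot wrap hydrophobicity around a center, making it the negative
  control analogous to a single-helix antifreeze peptide.
* *mixed_helix_strand*: half helix, half extended strand, for exercising
  the code assignment.

The generator emulates exactly the statistical feature the analysis
measures — the spatial arrangement of intrinsic hydrophobicity — and
nothing else. Cloud modes have no chain connectivity, no side-chain
geometry and no physically realistic packing, so passing the synthetic
recovery tests demonstrates that the statistic detects (anti-)centric
hydrophobicity arrangements, not that it reproduces any particular real
protein's value. Determinism: every generated structure is a pure function
of its `synthetic_spec` (including the seed).

Benchmark sizes used by the shipped analyses and checks — clouds of 60
residues, 20 seeds per mode, a 37-residue helix control — are large enough
that the micelle/anti-micelle RD separation (about 0.4–0.5 in the mean) is
far from the 0.5 decision line, while keeping a full run in seconds.

## Numerical choices

* Divergences use base-2 logarithms; O entries below 1e-15 are treated as
  exact zeros under the $0 \log 0 = 0$ convention; `D_KL` with $P > 0$
  where $Q = 0$ raises rather than returning infinity.
* $\sigma$ components are never floor-clamped: a flat (planar or linear)
  point set raises a degenerate-geometry error at T evaluation instead of
  silently producing a distorted Gaussian.
* Orientation ties (several pairs at the maximal distance) resolve to the
  first pair in residue order; axis signs put the first residue of the pair
  on the positive side. T is even in every coordinate, so neither choice
  affects results.
* The observed-density sum excludes the self term $j = i$: the collector
  accumulates pairwise interactions, and a self term would add a constant
  $2H^r_i$ of double-counted intrinsic hydrophobicity. Because this
  convention is not universal, `observed_profile(include_self = TRUE)`
  restores it for comparison.
* Effective atoms use heavy atoms only; hydrogens (present in NMR entries,
  absent from most X-ray entries) would otherwise make the two experiment
  classes inconsistent. For multi-model entries the first model is the
  default. Alternate locations keep the highest occupancy, ties first in
  file.
* Backbone rebuilding uses sequential internal-coordinate (NeRF) placement
  with ideal bond lengths/angles; measured torsions of a rebuilt chain
  reproduce the inputs to ~1e-13°, far inside the 1e-4° contract.

## Limitations

* RD values for real proteins depend on the hydrophobicity scale; compare
  values across structures under one scale, not across scales.
* The early-stage path constants are a package convention (see above).
* Domain decomposition is manual: the unit of analysis is whatever you load
  or select, and fragments are user-supplied ranges.
* No nucleic acids, ligands, assemblies, or protein–protein interfaces.
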