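---
title: "Methods: quantifying edge-conductivity pores in lipid bilayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying edge-conductivity pores in lipid bilayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgepore)
```

## The problem

Membrane-inserted β-sheet oligomers of amyloid-β can permeabilize
phospholipid bilayers. The mechanism of interest here is *edge
conductivity*: a continuous column of water and polar lipid atoms forms
along the exposed lateral edge of the β-sheet — a side-by-side pair of
N-terminal β1 strands whose hydrophilic 13–16 stretch (His-His-Gln-Lys,
the HHQK domain) anchors lipid head groups — and ions cross the membrane
along that column. `edgepore` implements the statistics with which such
simulations are analysed, plus a scripted synthetic-system generator that
makes every statistic verifiable against planted ground truth.

## The defect reaction coordinate ξ

The hydrophobic transmembrane slab (default thickness 2.8 nm, centred on
the bilayer centre) is divided into `n = 28` contiguous slices of 0.1 nm.
For one frame,

ξ = (number of slices containing ≥ 1 lipid-oxygen or water-oxygen atom) / n.

ξ is intrinsically discrete (multiples of 1/28); 0 means an intact
membrane, 1 a continuous polar defect. The ensemble distribution p(ξ),
obtained by direct counting over all frames of all replicates, transforms
to a free energy ΔG(ξ) = −RT ln p(ξ) with R = 0.0083145 kJ mol⁻¹ K⁻¹ and
T = 300 K. Bins with p = 0 are *undefined* (returned as `NA`), never 0 or
±∞.

Numerical choices:

* **Slice membership** is half-open with exact boundaries assigned to the
  *lower* slice, i.e. intervals (lo, hi]. This is deterministic and
  order-independent; an atom exactly on the bottom face of the slab falls
  outside. Planted test atoms sit at slice centres, 0.05 nm from any
  boundary, so the rule never affects the closed-loop tests.
* **Bilayer centre** = mass-weighted centre of all lipid atoms (the
  source protocol says "relative to the center of all lipid atoms" without
  stating weighting; mass weighting matches the semantics of the common
  MD density tools, and a geometric centre is available via
  `center_weighting = "geometric"`).
* **ξ histogram bin width** is exactly 1/n — one bin per attainable value —
  because ξ is discrete; any coarser binning would conflate counts.

### Per-edge attribution

The source analyses report ξ separately along each β-strand edge without
stating the spatial restriction used. The rule adopted here (a documented
package choice, not the source's): a polar atom counts toward an edge when
its *lateral* (xy, minimum-image) distance to the nearest edge-strand
heavy atom is ≤ 1.0 nm (`edge_lateral_cutoff`, configurable). Edges are
vertical strand pairs, so in-plane proximity is the natural restriction;
an atom equidistant from two edges counts toward both, hence per-edge
ξ ≤ total ξ frame-wise but per-edge values need not sum to the total.

## Density, contacts, ion coordination

* **Partial densities**: per frame each selected atom contributes to the
  bin of z − z_centre; density = count/(bin width × box area), averaged
  over frames within a replicate, then mean ± SEM across replicates.
  Number density is the default (the source figures do not state units);
  mass density is available. Atoms beyond the profile range are dropped,
  not clamped, and Σ bins × bin volume equals the mean in-range atom count
  exactly — a conservation law the tests assert.
* **Contacts**: a residue is in contact with a partner category in a frame
  iff ≥ 1 heavy-atom pair is within 0.5 nm (minimum image). Presence is
  boolean — the source reports frequencies bounded by 1, which a pair
  *count* would violate — and frequency is the fraction of frames,
  averaged across replicates with equal weight (the source does not state
  whether replicates are frame-count weighted; equal weighting was chosen
  and is what the SEM assumes).
* **Ion shells**: partner heavy atoms within 0.35 nm of the ion. The
  protein subcategories are hard-wired to the groups the ion-coordination
  figures use — backbone carbonyl O of residues 9–21 (β1 strand), H13/H14
  imidazole nitrogens, Q15 side-chain carbonyl O — and `protein_total`
  counts all protein heavy atoms. Coordination profiles bin every
  (ion, frame) observation by depth; all ions are binned by default
  (whether the source restricted its profiles to crossing ions is
  unstated; crossing-only profiling can be had by selecting the ions that
  appear in `crossing_events`).
* **Crossings**: a three-state machine per ion — bulk above (z > h + m),
  slab (|z| ≤ h), bulk below — with h = 1.4 nm (half the defect slab) and
  a hysteresis margin m = 0.4 nm that suppresses boundary chatter. An
  event is bulk → slab → opposite bulk without revisiting the origin bulk.
* **Permeation barrier**: the source discusses barrier differences but
  never defines the barrier operationally; since it presents exactly the
  axial ion densities, the package adopts Boltzmann inversion,
  ΔG(z) = −RT ln(ρ(z)/ρ_bulk), with ρ_bulk the mean density over
  |z| ∈ [2.5, 3.5] nm. Empty bins are `NA`, a zero bulk density is an
  error.

## Stability metrics

RMSD uses the standard least-squares superposition (Kabsch via SVD) with
proper-rotation enforcement (no reflections), over mainchain (N, Cα, C, O)
plus Cβ atoms of the transmembrane β-strands; collinear masks are
rejected. β-structure content is a backbone-dihedral criterion —
φ ∈ [−180°, −45°] and (ψ ∈ [45°, 180°] or ψ ∈ [−180°, −150°]) — rather
than an H-bond method like DSSP, because the idealized synthetic sheets
have exact dihedrals but no realistic hydrogen-bond geometry. Trajectories
are pooled by mean edge RMSD into pools I/II/III at thresholds
(0.3, 0.6) nm: the 0.6 nm boundary is anchored to the reported loss of ion
conduction above that deviation; the 0.3 nm boundary is a package choice
(the source figure does not print its pool edges). Ties go to the upper
pool.

## The model builder

Identifiers follow `<SizeWord>-<k>pe-<composition>`: oligomer size word
(Di…Octa), number of side-by-side β1-strand pair edges, and either a
dot-separated strand composition or a template code (`2OTK`, `3SGO`). The
parser keeps the composition digits as given — their mapping onto strand
classes is not defined by the grammar. β-sandwich assembly generates the
second sheet copy by a rigid transform: 180° rotation about the membrane
normal then lateral translation (face-to-face antiparallel), or
translation only (face-to-back parallel). The exact symmetry parameters of
the original models are not published; both the packing rotation and the
offset are exposed as arguments, and a minimum inter-copy heavy-atom
distance (0.25 nm) guards against clashes. Strand deletion removes atoms,
drops emptied chains, and recomputes edges from the new outermost strands
(per sheet layer, the strand at each lateral extreme).

## The synthetic world

`make_bilayer_system()` builds a stated world, not a tuned one: mirror-
symmetric leaflets of pseudo-lipids with head groups near ±2 nm (polar
oxygens kept outside the 2.8 nm core, so the pristine ξ is exactly 0 and
the lipid mass centre is exactly 0), water slabs of ~2.5 nm, and KCl at
600 mM ionic strength with counts derived from the water-slab volume
(n = 0.6022 · c · V). Defaults (36 lipids/leaflet, 400 waters, 6×6×9 nm
box) are a desk-scale rendition of the simulated systems (which used
170–250 lipids); all analyses depend only on role tags and coordinates,
so lipid chemistry fidelity is unnecessary. Generation is seeded and
byte-reproducible.

What a green test establishes: that every analysis operation recovers its
planted ground truth exactly on scripted coordinates. What it does not:
force-field physics, realistic lipid disorder, thermal fluctuations of
the aggregate, or the multi-microsecond kinetics of pore formation —
trajectories here are scripted, not simulated, and the headline
simulation results (2.5/7.5 kJ/mol force-field barrier differences,
> 4 kJ/mol mutant shifts, multi-µs pore stability) are out of desk-scale
reach by construction.

## Degenerate inputs and tie-breaks

Empty atom selections are legal for selections (empty index vector) but an
*error* for the ξ polar set (a missing polar selection is not the same as
a dry slab); empty density selections give an all-zero profile with a
warning; coordination bins with zero observations are `NA`. Unknown
atoms load as role `other` with a warning — never dropped — so toy systems
read cleanly. The frame_table dialect prints 17 significant digits so
write/read round trips are bit-exact; PDB is Å on disk (nm ÷ 10, 3
decimals, the format's own precision limit).

## Dependencies and substitutions

The package is pure base R plus `jsonlite`. No pre-installed R package
provides PDB trajectory IO, so the fixed-column multi-MODEL PDB subset is
implemented here. The analysis configuration serializes as JSON rather
than YAML (no YAML parser among the available dependencies); the config
contract — one flat document, lossless round trip, every default
printable — is unchanged. The neighbour search used by contacts and
shells is a periodic cell list; the test suite checks it against an
independent all-pairs O(N²) oracle, including ±0.01 nm threshold
bracketing at both cutoffs.
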