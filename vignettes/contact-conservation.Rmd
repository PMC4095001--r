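---
title: "Contact conservation and interface area in MD ensembles: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact conservation and interface area in MD ensembles: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdcontacts)
```

This vignette documents the models, conventions and numerical choices
behind `mdcontacts`, in the spirit of a methods section: what exactly
is computed, which knobs matter, what the synthetic validation does and
does not demonstrate, and where the known limitations are.

## The model

A *trajectory* is an ordered set of conformations (frames) of a
two-partner complex with a stable residue identity across frames: a
residue is identified by chain ID, author residue number and insertion
code, exactly as deposited, and every residue belongs to exactly one of
the two partners (defined by disjoint chain-ID sets). Residues may be
present in only some frames; the registry is the union over frames, and
a contact involving such a residue is simply absent from the frames
lacking it.

Two residues, one per partner, are **in contact** in a frame when at
least one heavy atom of each lies at Euclidean distance *strictly*
below the cutoff (default 5 Å). The strict inequality is a deliberate
convention — a pair at exactly 5.000 Å is not a contact — and the
single-qualifying-atom-pair reading follows the standard contact-map
definition used in docking assessment (any atom pair below the cutoff
establishes the residue contact). Distances are computed in double
precision with no periodic-boundary imaging: input snapshots are
assumed whole and imaged upstream, which is how MD engines' PDB export
is normally run.

For contact (*k*, *l*) present in `nc_kl` of the `N` frames the
conservation rate is `CR_kl = nc_kl / N`. Pairs never in contact are
omitted from the record table: the universe of absent pairs is the full
cross-product and carries no information (they appear implicitly as
zeros of the consensus matrix). Tables print CR to two decimals;
thresholding always uses full precision.

The coefficient at threshold *t* is

```
C_t = nc_t / (sum_i nc_i / N)
```

with `nc_t` the number of distinct pairs with `CR_kl >= t`
(*inclusive*: a contact conserved in exactly 70% of frames counts
toward `nc_70`) and the denominator the mean number of contacts per
frame. Two properties follow and are enforced as tested invariants:
`C_90 <= C_70 <= C_50`, and the double-counting identity
`sum_kl nc_kl = sum_i nc_i`. One property deliberately does *not*
hold: `C_t` is not bounded by 1, because the numerator counts distinct
pairs while the denominator is a per-frame mean; the implementation
never clips it. An ensemble with no contact in any frame has no
defined coefficients and raises an identified error rather than
dividing by zero. Every supplied frame is analysed; there is no
internal subsampling.

## Structure input

The PDB reader is a vectorised fixed-column parser supporting
multi-model files (one frame per `MODEL`/`ENDMDL` block; a file without
`MODEL` records is one implicit frame) and ordered snapshot sets, whose
rosters may differ per file. Filtering rules, applied per frame:

* waters (`HOH`, `WAT`, `SOL`, ...) are always dropped;
* `HETATM` records are dropped unless `include_het = TRUE`, except
  selenomethionine, which is part of the polymer and is kept and mapped
  to MET (its Se atom to the sulfur radius);
* hydrogens and deuteriums are retained but flagged, so they are
  invisible to contact detection and surface computation (MD-derived
  snapshots often carry hydrogens; how the original contact analyses
  treated them is not documented, so keeping-but-ignoring is the
  conservative choice — a "heavy atom" is any non-H, non-D element,
  taken from the element column when present, else inferred from the
  atom-name convention);
* alternate locations are resolved per frame to the highest-occupancy
  conformer, ties going to the first encountered, giving a bit-stable
  registry.

Coordinates and cutoffs are in Å throughout; residue numbering is the
author numbering verbatim. Binary MD formats (XTC/DCD) are out of
scope; convert to multi-model PDB upstream.

## Solvent-accessible surface and interface area

SASA uses Shrake–Rupley sphere sampling rather than Lee–Richards
slicing: it is simpler, trivially deterministic, and agrees with
slicing implementations to within ~1–2% on protein interfaces, which
sets the ±3% tolerance used when comparing interface areas against
published reference values. Each heavy atom's sphere of radius
(r<sub>vdW</sub> + probe) carries a golden-section spiral lattice —
deterministic, so results are bit-for-bit reproducible for fixed
parameters, with no RNG — and the accessible fraction is the fraction
of lattice points outside every neighbouring expanded sphere.

Parameters and defaults:

* `probe_radius = 1.4` Å (water);
* `n_sphere_points = 960`: the isolated-atom sampled area is within 1%
  of the analytic 4π(r + probe)² there (tested), and the error falls
  as the lattice grows;
* radii: a Chothia-style heavy-atom table shipped as an editable TSV
  (`inst/extdata/radii_chothia.tsv`): tetrahedral C 1.87, trigonal and
  aromatic C 1.76, N 1.65, O 1.40, S 1.85 Å, with an element-based
  fallback for nonstandard atoms and an error naming the atom when no
  radius resolves. Hydrogens are excluded from SASA entirely.

The per-frame interface area is `(ASA(A) + ASA(B) − ASA(AB)) / 2`,
the isolated-partner terms computed by deleting the other partner's
atoms at unchanged coordinates (the standard buried-ASA convention; no
re-relaxation). Per-residue burial is the relative ASA loss
`100 (ASA_free − ASA_complex) / ASA_free`, with residues whose free
ASA is below 0.1 Å² flagged as `NA` rather than divided.

Numerical notes. The additivity identity — summed per-residue ASA loss
equals twice the interface area — holds exactly by construction and is
asserted in tests. Because the lattice orientation is fixed in space,
rigidly rotating a complex changes each atom's sampled area slightly;
across the many atoms of an irregular interface these errors average
to below 0.5% of the interface area (tested), but on small, perfectly
periodic synthetic interfaces they add coherently and can reach ~1–2%
at 960 points. Exactly coincident atoms are a degenerate input: the
occlusion test is strict (`distance < R`), so a perfect duplicate does
not occlude its twin; deduplicate upstream if such inputs can occur.

## Contact typing and distance monitoring

Polarity classes come from an editable two-column table; the shipped
dialect is COCOMAPS-style, with hydrophobic = {ALA, VAL, LEU, ILE,
MET, PHE, PRO, TRP, GLY} and the remaining 11 standard residues
(including CYS, TYR and HIS) hydrophilic. Published
hydrophilic-contact counts for reference complexes are sensitive to
the CYS/TYR/GLY assignments, which is why the table is configuration,
not code. Unknown residue names either raise an error (`strict =
TRUE`) or warn and take a configurable default class.

Distance monitoring takes explicit atom-name selections (e.g. Asp
OD1/OD2 against Lys NZ) rather than inferring functional groups, and
reports the per-frame minimum heavy-atom distance; the two selections
must target distinct partners. This deliberately stops short of
hydrogen-bond or salt-bridge *detection* (donor–acceptor geometry):
the package's premise is that a plain distance criterion retains
persistent apolar interactions that motif-based detectors miss.

## Rendering

Consensus maps place partner A on x and partner B on y (flippable),
one square mark per nonzero cell, gray level `1 − CR^gamma` — linear
by default (`gamma = 1`), strictly darker for more conserved, with the
gamma option because weakly conserved contacts are nearly invisible at
small marker sizes. PNG and SVG devices are supported, and the matrix
itself can be exported as labelled text for external plotting. A
single structure is rendered as the N = 1 consensus of itself, which
makes the two renderers pixel-identical by construction (tested by
byte comparison).

## The synthetic generator, and what the tests show

`generate_toy_complex()` lays two chains of single- or three-atom
pseudo-residues (alternating ALA/SER, so polarity code paths are
exercised) on parallel lines 20 Å apart, 8 Å spacing along the chain.
A designated slot pair sits at 4.5 Å — comfortably inside the 5 Å
criterion — and every non-slot residue pair is at least 8 Å away, so
the expected contact set is known exactly. `generate_trajectory()`
toggles each slot independently per frame with its persistence
probability p from one seeded RNG stream (the seed is echoed into a
`REMARK` for provenance, the caller's RNG state is left untouched, and
an explicit per-frame schedule can replace the draw for scripted
cases). Validation shows empirical CR recovers p within three binomial
standard errors at N = 2000, and the worked 10-frame ensemble (three
contacts present in 10, 7 and 3 frames; mean 2 contacts/frame;
C₅₀ = C₇₀ = 1.0, C₉₀ = 0.5) matches independent direct counting.

What this emulates is the *statistics* of contact persistence; it does
not emulate correlated contact dynamics, realistic side-chain packing,
solvation, or crowded interfaces where one residue contacts many.
Passing these tests therefore demonstrates correctness of the
counting, surface and I/O machinery — not that any particular real
interface is rigid or flexible, which remains a property of the input
ensemble.

Validation problem sizes were chosen to keep the full suite quick on a
single CPU while leaving the statistical checks well-powered:
ensembles of up to 2000 frames for persistence recovery, 100
randomized ensembles for the invariants, ≤500-atom frames for
brute-force contact-oracle equality, and 240–3840 lattice points for
the SASA convergence ladder.

## Limitations

* PDB input only (no mmCIF, no binary trajectory formats).
* Protein–protein interfaces of exactly two partners; no
  intra-molecular contact maps, no atom-level maps.
* No relative (Gly-X-Gly-normalised) accessibility, polar/apolar area
  split, or volume computations.
* No hydrogen-bond/salt-bridge geometric detection — by design, see
  above.
* Reference X-ray structures used by the published-value tests are not
  redistributed with the sources; those tests report their absence
  until the files are supplied under `inst/extdata/reference/`.
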