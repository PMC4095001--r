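# mdcontacts

Interfaces of protein–protein complexes are not static: over a
molecular-dynamics (MD) trajectory, some intermolecular residue–residue
contacts persist in every frame while others form and break.
`mdcontacts` quantifies that persistence for a two-partner complex. It
is aimed at structural bioinformaticians and simulators who have an
ensemble of complex conformations (a multi-model PDB trajectory or an
ordered set of PDB snapshots) and want a compact, reproducible summary
of how conserved the binding interface is.

## What it computes

**Contacts.** Residue *k* of partner A and residue *l* of partner B are
in contact in a frame when at least one heavy (non-hydrogen) atom of
each lies at a distance below 5 Å (the CAPRI convention; the cutoff is
configurable and strictly exclusive).

**Conservation rate.** Over *N* frames, with *nc<sub>kl</sub>* the
number of frames containing contact (*k*, *l*):

> CR<sub>kl</sub> = nc<sub>kl</sub> / N

so CR = 1 for a contact present in every frame; pairs never in contact
are omitted.

**Conservation coefficients.** With *nc<sub>i</sub>* the number of
contacts in frame *i* and *nc<sub>t</sub>* the number of distinct
contacts with CR ≥ *t*:

> C<sub>t</sub> = nc<sub>t</sub> / (Σ<sub>i</sub> nc<sub>i</sub> / N),  t ∈ {0.50, 0.70, 0.90}

i.e. the count of well-conserved contacts normalised by the mean number
of contacts per frame. Note C<sub>t</sub> can exceed 1 (the numerator
counts distinct pairs, the denominator is a per-frame mean) and is not
clipped.

**Consensus map.** A partner-A × partner-B residue map where each
contact is drawn in grayscale, darker meaning more conserved; a single
structure renders as the all-black N = 1 special case.

**Interface area.** Half the solvent-accessible surface area (SASA)
buried on complexation, (ASA(A) + ASA(B) − ASA(AB)) / 2, per frame,
with SASA from deterministic Shrake–Rupley sampling over Chothia-style
heavy-atom radii (probe 1.4 Å, 960 lattice points). Per-residue burial
percentages, 100·(ASA<sub>free</sub> − ASA<sub>complex</sub>)/ASA<sub>free</sub>,
identify hot-spot residues.

**Characterization.** Contacts are typed by residue polarity
(hydrophilic–hydrophilic / hydrophobic–hydrophobic / mixed, with an
editable residue table), and minimum-distance series between selected
functional groups can be tracked along the trajectory.

A seeded synthetic-trajectory generator
([`generate_trajectory()`]) builds toy two-chain complexes whose
contacts persist with specified per-contact probabilities, so the whole
pipeline is testable without any external structure.

## Worked example

```r
library(mdcontacts)

## a 50-frame synthetic trajectory: three interface contacts held with
## persistence probabilities 1.0, 0.7 and 0.3
spec <- persistence_spec(cbind(c(2, 4, 6), c(2, 4, 6), c(1.0, 0.7, 0.3)),
                         n_frames = 50, seed = 11,
                         n_res_a = 8, n_res_b = 8)
pdb <- file.path(tempdir(), "toy_traj.pdb")
generate_trajectory(spec, path = pdb)

traj <- read_multimodel_pdb(pdb, chains_a = "A", chains_b = "B")
sets <- trajectory_contacts(traj, cutoff = 5.0)
rec  <- conservation_rates(sets)
rec[, c("chain_a", "resno_a", "chain_b", "resno_b", "nc", "cr")]
#>   chain_a resno_a chain_b resno_b nc   cr
#> 1       A       2       B       2 50 1.00
#> 2       A       4       B       4 41 0.82
#> 3       A       6       B       6 14 0.28

conservation_coefficients(rec, vapply(sets, `[[`, integer(1), "n_contacts"))
#> conservation over 50 frames (mean 2.10 contacts/frame)
#>   C_50 = 0.95 (2 contacts conserved in >= 50% of frames)
#>   C_70 = 0.95 (2 contacts conserved in >= 70% of frames)
#>   C_90 = 0.48 (1 contacts conserved in >= 90% of frames)

area_series(traj, sasa_params(n_sphere_points = 240))
#> interface area over 50 frame(s): 43.5 +/- 12.0 A^2
```

The empirical conservation rates (1.00, 0.82, 0.28) estimate the
generating persistence probabilities (1.0, 0.7, 0.3) to within binomial
sampling error at N = 50; only the fully persistent contact counts
toward C₉₀, so C₉₀ ≈ 1 / 2.1 ≈ 0.48.

`run_all(run_config(...))` executes this whole workflow plus consensus
map rendering, polarity typing and per-residue burial in one call,
writing TSV tables, the map image and a run manifest to an output
directory; `inst/cli/mdcontacts` exposes the same pipeline as a shell
command with subcommands (`run`, `contacts`, `consensus`, `area`,
`burial`, `distance`, `map`, `fixtures`).

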