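Package: mdcontacts
Title: Conservation of Intermolecular Contacts and Interface Area in MD
    Ensembles of Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how well the intermolecular residue-residue
    contacts of a two-partner protein complex are conserved across the
    frames of a molecular-dynamics ensemble. Parses multi-model PDB
    trajectories or ordered snapshot sets, detects heavy-atom contacts
    under a 5 Angstrom cutoff, computes per-pair conservation rates and
    the C50/C70/C90 conservation coefficients, renders grayscale
    consensus contact maps, and tracks the complex interface area as
    half the solvent-accessible surface buried upon complexation
    (Shrake-Rupley sampling with Chothia-style radii). Includes a
    seeded generator of synthetic two-chain complexes with controlled
    per-contact persistence for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    bio3d,
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
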