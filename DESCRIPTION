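Package: contactvol
Title: Grid-Based Interatomic Contact Areas, Volumes and Water-Mediated
    Interactions in Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies interatomic and inter-residue contacts in PDB
    structures with a deterministic grid engine: contact surface area and
    contact volume between van der Waals spheres with multi-atom overlap
    sharing, an atomic-overlap-weighted volume variant, per-atom solvent
    accessible surface area, water-mediated hydrophilic contacts with
    element-specific mosaic distances, covalent and non-covalent contact
    typing, residue-level aggregation with sequence-separation classes and
    backbone dihedrals, and mean/range contact matrices across multi-model
    (NMR or trajectory snapshot) ensembles.  Includes a batch command-line
    driver, CSV outputs, heatmap rendering, and a nearest-water hydration
    profiling statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    png
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite
Config/testthat/edition: 3
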