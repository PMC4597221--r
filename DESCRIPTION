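Package: cutoffLensing
Title: Catalytic-Site Prediction in Enzymes by Cutoff Lensing of Elastic
    Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Structure-based prediction of catalytic residues in enzymes
    from C-alpha elastic network models built over a scan of cutoff radii
    ("cutoff lensing"). At each cutoff three per-residue indicators are
    computed: a spectral stiffness from the highest-frequency normal
    modes, the local connectivity (degree) and the closeness centrality
    of the residue contact graph. Indicator profiles are reduced to peak
    patterns by high-pass filtering (with a 4-point smoothing step for
    closeness), evaluated against catalytic-site annotations, and
    combined at indicator-specific optimal cutoffs into per-residue and
    per-structure scores. Includes PDB C-alpha parsing, annotation
    mapping, deterministic synthetic-structure generators for testing,
    and command-line style driver functions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
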