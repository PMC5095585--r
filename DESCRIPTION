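Package: katomics
Title: Differential Acetylome Calling and Acetyl-Site Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for calling lysine-acetyltransferase-dependent acetylation
    sites from replicate shotgun-proteomics identifications, and for the
    downstream characterization of the called sites.  Includes SEQUEST-style
    PSM score filtering and peptide-to-protein site mapping, presence/absence
    differential calling across control and knockdown replicates, the
    spectral-count acetylation abundance factor, sequence-context logo
    analysis of acetylated lysines against a proteome-sampled lysine
    background, structural-feature extraction from replicate molecular
    dynamics ensembles (RMSD, hydrogen-bond occupancy, backbone to side-chain
    distances, backbone dihedrals) with reproducible-difference detection,
    and circular-ROI quantification of centrosomal fluorescence signal with
    centriole-count phenotype classification.  A synthetic-data module
    generates every input the pipeline consumes, with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    tiff
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite
Config/testthat/edition: 3
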