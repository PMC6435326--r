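Package: glycotrack
Title: Differential O-Glycoproteomics, Cell-Track Metrics and Image
    Quantification for Embryonic Macrophage Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantification pipeline for dimethyl isotope-doublet
    O-glycoproteomics: peptide-spectrum-match log-ratio computation, an
    empirical null model of flow-through peptide ratios with a 3-sigma
    candidate cutoff, fold-change classification of Tn and T antigen
    glycosites, site- and protein-level summaries, and a rank test for
    glycosite multiplicity. Companion trajectory analytics for 3D nuclei
    tracks (instantaneous speed, segment directionality, tissue entry
    time) and image-derived quantifications (Pearson colocalization,
    batch-normalized arbitrary units, multichannel line profiles, border
    cell migration percentage), together with synthetic-data generators
    that provide ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    png
Suggests:
    tiff,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
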