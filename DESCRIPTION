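Package: evcargo
Title: Extracellular Vesicle miRNA Cargo Enrichment, Seed-Site Targeting,
    and Multielectrode-Array Activity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for studies of stimulus-dependent microRNA
    cargo in astrocyte-derived extracellular vesicles and its effect on
    neuronal network activity. Normalizes hybridization-based miRNA count
    matrices (positive-control spike-in scaling followed by quantile
    normalization), calls stimulus-enriched cargo against a
    constitutive-release baseline with a fold-change rule, validates by
    delta-delta-Ct relative quantification, and clusters enriched miRNAs for
    heatmap display. Scans 3'-UTR sequences for canonical miRNA seed-match
    sites (6mer, 7mer-A1, 7mer-m8, 8mer) and models the two-nucleotide
    site-disruption mutants used in luciferase reporter assays. Quantifies
    extracellular recordings from multielectrode arrays: Butterworth
    high-pass filtering, spike detection at a multiple of the noise standard
    deviation, inter-spike-interval burst clustering, electrode quality
    control, raster binning, baseline-normalized spike and burst rates, and
    paired pre/post comparisons. Every input has a synthetic generator with
    known ground truth so the full pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
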