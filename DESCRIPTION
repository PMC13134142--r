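Package: hicdyn
Title: Multi-Stage Hi-C Chromatin Architecture Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for binned Hi-C contact matrices across an
    ordered series of cellular stages (e.g. erythroid differentiation):
    matrix balancing with the equal-marginal contract, distance-expected and
    observed/expected transforms, A/B compartment eigenvector calling with
    automatic sign orientation, stage-to-stage compartment switching tables,
    saddle plots and compartment strength, distance-decay curves, long-range
    contact fractions, per-bin distal-to-local ratio (DLR) and
    interchromosomal contact frequency (ICF), insulation-score TAD boundary
    detection with aggregate pileups and domain-strength dynamics,
    interval-overlap fold-enrichment maps, and a radial-positioning
    classifier for 3D genome-model bead ensembles. A seedable synthetic-data
    generator provides contact matrices, annotation intervals, tracks, and
    bead ensembles with planted ground truth for every downstream statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    jsonlite,
    xml2,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
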