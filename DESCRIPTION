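Package: inxtools
Title: Gene-Family Events, Synteny, Coexpression and Single-Channel
    Analysis for Ctenophore Innexins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs gene gain, loss and duplication events for the
    ctenophore innexin radiation by Dollo parsimony and LCA-mapping
    reconciliation on a four-species tree; detects tandem gene-family
    clusters and conserved microsynteny blocks from genome gene-order
    tables; computes single-cell UMI coexpression statistics (binarized
    expression, per-cell innexin histograms, metacell marker calls,
    minimum-denominator coexpression percentages) and bulk expression
    ratios; and analyzes voltage-clamp sweeps for putative innexon
    hemichannel activity (quality-control filtering, Gaussian-mixture
    unitary-amplitude estimation, half-amplitude idealization, slope
    conductance and reversal-potential fitting, open probability, and
    Nernst reversal predictions). Reproducible simulators provide
    synthetic inputs with the statistical structure each analysis
    assumes, with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Matrix,
    mclust,
    rtracklayer,
    GenomicRanges,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
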