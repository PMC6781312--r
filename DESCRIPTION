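Package: blockpath
Title: Multi-Block Latent-Variable Path Modeling and Design-Space
    Development for Multi-Unit Pharmaceutical Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for Quality-by-Design modeling of multi-unit
    pharmaceutical manufacturing processes. Organizes per-unit process
    data into named blocks, fits two-matrix partial least squares (PLS),
    super-score multi-block PLS (MBPLS) and the Wangen-Kowalski
    multi-block PLS path model (MBPLSPM) by NIPALS-type alternating
    least squares, and ranks critical process units and parameters with
    block and variable importance in the projection (BIP/VIP) indices.
    Includes per-block principal component analysis with Hotelling T2
    outlier limits, variance inflation factor collinearity diagnostics,
    leave-one-out cross-validated Q2 model comparison, response-surface
    fitting of critical quality attributes, overlapped (multi-response)
    design-space construction on a factor grid, a packaged 52-run
    D-optimal wet-granulation/compaction design, a synthetic case-study
    generator with known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
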