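Package: molmeth
Title: Single-Molecule Targeted DNA Methylation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of targeted enzymatic methyl-seq long reads at
    single-molecule resolution for plant genomes. Enumerates cytosine sites
    in CG, CHG and CHH contexts on the captured strand of target regions,
    assigns and aligns conversion-ambiguous reads, calls per-molecule ternary
    methylation states, applies conversion-failure read filters and
    internal-control conversion-rate QC, and computes per-molecule
    methylation-proportion statistics (mPPM, between-condition DmPPM tests),
    regional average-level comparisons, within-molecule context
    co-methylation, consecutive-run and footprint signatures, and
    single-molecule heatmaps with hierarchical read clustering. Includes a
    seeded epiallele simulator that generates converted reads with ground
    truth so every stage of the pipeline can be validated without sequencing
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
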