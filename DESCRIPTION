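Package: combiscreen
Title: Simulation and Analysis of Combinatorial CRISPR Activator Sort-Seq Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for pooled combinatorial CRISPR-activator screens read out
    by FACS bin sorting and barcode sequencing. Provides a synthetic screen
    simulator with known ground truth (combinatorial construct enumeration,
    Poisson lentiviral transduction, toxicity-driven clone depletion,
    four-bin extreme sorting, multinomial read sampling with PCR-jackpot
    UMIs and spiked controls), scar-anchored barcode/UMI read extraction,
    UMI outlier filtering and prefix grouping, fluorescence-weighted
    activation scoring, plasmid-versus-cells dropout toxicity scoring,
    construct-level analyses of domain order, fusion position and copy
    number, and biochemical featurization of activation domains (net charge
    per residue, hydropathy, disorder fraction, and kappa/omega charge and
    hydrophobe patterning).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
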