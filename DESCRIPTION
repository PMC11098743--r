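Package: screenflux
Title: Pooled Transporter CRISPRi/a Screen Scoring and Amino Acid Flux
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Gene-level scoring of pooled CRISPR interference/activation
    transporter screens (non-targeting-control pseudogene null, top-7
    phenotype scores, Mann-Whitney screen scores, in vivo replicate QC)
    and estimation of amino acid import, consumption and export rates
    from stable-isotope tracer time courses (natural-abundance
    correction, internal-standard and total-ion-count normalization,
    standard-curve quantification, initial-slope regression). Includes
    synthetic-data generators with known ground truth for screens,
    tracer kinetics and qPCR competition assays, plus small helpers for
    competition, viability and lipid-peroxidation readouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
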