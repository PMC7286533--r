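Package: gerpmix
Title: Population-Genetic Models of GERP Conservation Scores with Functional Turnover
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates nucleotide and codon substitution along phylogenies under
    purifying selection and a two-state functional-turnover Markov process,
    computes rejected-substitution (GERP) conservation scores by maximum
    likelihood, fits neutral/constrained/turnover mixture models to
    standardized score distributions per tree-size bin via a kernel-density
    overlap statistic, compares nested mixture models with a
    simulation-calibrated Lambda test, and provides power analyses for
    conservation detection together with a synthetic genome-like score
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
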