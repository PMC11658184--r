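Package: tRNAcharge
Title: Aminoacylation and 3' End Integrity Analysis for Periodate-Treated tRNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies tRNA aminoacylation (charging) levels from
    periodate-treated small RNA sequencing libraries. Periodate oxidation
    removes the 3' terminal nucleotide of uncharged tRNAs while the amino
    acid on charged tRNAs protects it, so the fraction of reads retaining an
    intact CCA tail measures the charged fraction. The package loads and
    validates a mature tRNA reference with Sprinzl coordinate annotation,
    simulates treatment-aware sequencing libraries with ground truth for
    validation, fit-aligns reads with an affine-gap scheme tolerant of
    reverse-transcriptase artifacts, classifies per-read 3' tail states
    (CCA/CC/shorter/non-templated additions), derives charging and retention
    indices across genes and isodecoder/isoacceptor families, profiles
    misincorporations and truncations on Sprinzl-anchored axes, calls
    5' tRNA-derived fragments, and assembles reproducible report bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse
Config/testthat/edition: 3
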