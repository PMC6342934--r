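Package: pamscreen
Title: PAM Depletion Screens, Amplicon Edit Calling and Gel Cleavage Quantitation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for characterizing CRISPR nucleases from
    bacterial depletion screens and targeted sequencing. Extracts randomized
    protospacer-adjacent motif (PAM) regions anchored on a fixed protospacer,
    scores per-PAM depletion of a nuclease-expressing library against an
    empty-vector control across replicates, and summarizes depleted PAMs as
    position frequency matrices, information content, IUPAC consensus and
    Krona-compatible PAM wheels. Classifies amplicon reads into wild-type,
    indel and homology-directed repair outcomes with a global affine-gap
    aligner, implements the closed-form gel-band estimator of DNA cleavage
    and nicking under strand independence, and enumerates PAM-compatible
    target sites on both strands of arbitrary sequence. A synthetic-data
    generator emulates the screen and amplicon designs with machine-readable
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
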