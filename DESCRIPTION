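Package: epibind
Title: Epitope Ranking from Peptide-Array Binding Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models monoclonal-antibody binding to near-random peptide
    libraries measured on photolithographic microarrays. Provides a
    synthetic landscape generator with planted linear epitopes, replicate
    averaging and detector-saturation correction, register-shift sequence
    encoding, high-binder up-weighting and composition-model subtraction,
    a fully connected neural-network regressor trained on four antibody
    concentrations at once, cognate-rank evaluation against large random
    sequence sets, single-residue substitution scans, antigen tiling maps,
    and robustness suites (training-set downsampling and similarity
    filtering).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
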