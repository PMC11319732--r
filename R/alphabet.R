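#' The 16-letter amino-acid alphabet of the peptide library
#'
#' Photolithographic peptide libraries of this design are built from 16 of
#' the 20 natural amino acids (C, I, M and T are absent for synthesis
#' reasons). All sequences handled by this package are over this alphabet;
#' natural sequences are first mapped onto it with [map_missing_aa()].
#'
#' @return Character vector of the 16 one-letter codes, in the fixed order
#'   used throughout the package ("ADEFGHKLNPQRSVWY").
#' @export
aa_alphabet <- function() {
  strsplit("ADEFGHKLNPQRSVWY", "")[[1]]
}

#' The 19-token encoding alphabet
#'
#' Sequence inputs to the binding model are framed token strings over the 16
#' amino acids plus three structural tokens: "X" (blank padding), "("
#' (N-terminus marker) and ")" (C-terminus marker). The order is frozen so
#' that one-hot encodings and trained weight matrices are stable across runs.
#'
#' @return Character vector of 19 tokens.
#' @export
token_alphabet <- function() {
  c(aa_alphabet(), "X", "(", ")")
}

# internal: named index lookup for the token alphabet
token_index <- function() {
  toks <- token_alphabet()
  stats::setNames(seq_along(toks), toks)
}

assert_alphabet <- function(sequences, what = "sequence") {
  bad <- grepl(sprintf("[^%s]", paste(aa_alphabet(), collapse = "")),
               sequences)
  if (any(bad)) {
    stop(sprintf(
      paste0("%s contains letters outside the 16-letter alphabet (%s): ",
             "%s%s (map I/T/M/C with map_missing_aa() first)"),
      what, "ADEFGHKLNPQRSVWY",
      paste(utils::head(sequences[bad], 3), collapse = ", "),
      if (sum(bad) > 3) ", ..." else ""
    ), call. = FALSE)
  }
  invisible(sequences)
}

# per-element concentration formatting (vectorized format() would pad all
# elements to a common width, e.g. 0.5 -> "0.500")
format_conc <- function(x) {
  vapply(x, function(v) format(v, trim = TRUE, scientific = FALSE),
         character(1))
}

# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
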