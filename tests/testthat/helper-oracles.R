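# Independent brute-force oracles and small fixture builders shared by the
# test files. The oracles deliberately use naive loops, independent of the
# package's implementation paths.

# best ungapped overlap of motif vs peptide: enumerate every offset
brute_overlap_score <- function(peptide, motif, energies) {
  p <- strsplit(peptide, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  best <- 0
  for (off in seq(-(length(m) - 1), length(p) - 1)) {
    s <- 0
    for (j in seq_along(m)) {
      i <- off + j
      if (i >= 1 && i <= length(p) && m[j] == p[i]) s <- s + energies[j]
    }
    best <- max(best, s)
  }
  best
}

brute_affinity <- function(landscape, peptide) {
  comp <- 0
  for (ch in strsplit(peptide, "")[[1]]) {
    comp <- comp + landscape$composition_coeffs[[ch]]
  }
  brute_overlap_score(peptide, landscape$motif, landscape$match_energy) +
    comp
}

# build a binding_table directly from a value matrix (for the saturation
# and weighting arithmetic tests)
make_bt <- function(sequences, values, concentrations = c(0.125, 0.5, 2, 8),
                    cap = 65536L) {
  values <- as.matrix(values)
  colnames(values) <- sprintf("c%s", epibind:::format_conc(concentrations))
  flags <- matrix("measured", nrow(values), ncol(values),
                  dimnames = dimnames(values))
  structure(list(sequence = sequences, log10_binding = values,
                 flags = flags, concentrations = concentrations,
                 saturation_cap = cap, duplicates_collapsed = 0L),
            class = "binding_table")
}

# a deterministic stand-in for a trained model: predicts from a supplied
# function of the sequences, one column per concentration
stub_model <- function(fn, concentrations = c(0.125, 0.5, 2, 8)) {
  structure(list(fn = fn, concentrations = concentrations),
            class = "stub_model")
}

predict.stub_model <- function(object, sequences, ...) {
  out <- object$fn(sequences)
  if (is.null(dim(out))) {
    out <- matrix(out, nrow = length(sequences),
                  ncol = length(object$concentrations))
  }
  out
}

# registering the S3 method so generic dispatch works inside the package
registerS3method("predict", "stub_model", predict.stub_model,
                 envir = asNamespace("stats"))
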