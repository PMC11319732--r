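test_that("array tables round-trip losslessly", {
  la <- abundant_signal_landscape(seed = 3)
  lib <- generate_library(library_spec(n_peptides = 50, seed = 8))
  ds <- simulate_binding(la, lib, cognate = lib[1])
  path <- tempfile(fileext = ".tsv")
  write_array_table(ds, path)
  ds2 <- read_array_table(path)
  expect_identical(ds2$counts, ds$counts)
  expect_identical(ds2$peptides, ds$peptides)
  expect_equal(ds2$concentrations, ds$concentrations)
})

test_that("array table reader validates format", {
  path <- tempfile(fileext = ".tsv")
  hdr <- c("sequence",
           as.vector(outer(c("c0.125", "c0.5", "c2", "c8"), 1:4,
                           paste, sep = "_r")))
  row <- function(seq, val) paste(c(seq, rep(val, 16)), collapse = "\t")
  writeLines(c(paste(hdr, collapse = "\t"),
               row("ADEFG", 850), row("PLEEVLN", 900), row("GGGGG", 850)),
             path)
  ds <- read_array_table(path)
  expect_equal(nrow(ds$peptides), 3)
  expect_equal(dim(ds$counts), c(3, 4, 4))

  writeLines(c(paste(hdr, collapse = "\t"), row("ADEFG", 70000)), path)
  expect_error(read_array_table(path), "saturation cap")

  writeLines(c(paste(hdr, collapse = "\t"), row("ADEFG", 850.5)), path)
  expect_error(read_array_table(path), "non-integer")

  writeLines(c(paste(hdr[-2], collapse = "\t"),
               paste(c("ADEFG", rep(850, 15)), collapse = "\t")), path)
  expect_error(read_array_table(path), "missing")

  # duplicate feature ids
  la <- abundant_signal_landscape(seed = 3)
  ds <- simulate_binding(la, c("ADEFG", "GGGGG"))
  ds$peptides$feature_id <- c("F1", "F1")
  write_array_table(ds, path)
  expect_error(read_array_table(path), "duplicate feature ids")
})

test_that("replicates are averaged on the log scale without outlier removal", {
  ds <- structure(list(
    peptides = data.frame(sequence = "ADEFG", feature_id = "F1",
                          control = FALSE, cognate = FALSE),
    concentrations = c(2, 8),
    counts = array(c(100L, 1000L, 850L, 850L), dim = c(1, 2, 2)),
    saturation_cap = 65536L, landscape = NULL), class = "array_dataset")
  # replicates are the 3rd dimension: (100, 850) at 2 nM, (1000, 850) at 8 nM
  ds$counts <- array(as.integer(c(100, 1000, 850, 850)), dim = c(1, 2, 2))
  bt <- average_replicates(ds)
  expect_equal(unname(bt$log10_binding[1, 2]),
               (log10(1000) + log10(850)) / 2)

  ds$counts <- array(c(100L, 1000L), dim = c(1, 1, 2))
  ds$concentrations <- 8
  bt <- average_replicates(ds)
  expect_equal(unname(bt$log10_binding[1, 1]), 2.5) # (2 + 3) / 2

  ds$counts <- array(rep(850L, 4), dim = c(1, 1, 4))
  bt <- average_replicates(ds)
  expect_equal(unname(bt$log10_binding[1, 1]), log10(850),
               tolerance = 1e-12)
  expect_equal(round(unname(bt$log10_binding[1, 1]), 4), 2.9294)
})

test_that("noise-free simulated data averages to exactly log10 mu", {
  zero_cc <- setNames(numeric(16), aa_alphabet())
  la <- binding_landscape("PLEEVLN", rep(0.5, 7),
                          composition_coeffs = zero_cc, gain = 2,
                          noise_sigma = 0, seed = 5)
  lib <- generate_library(library_spec(n_peptides = 200, seed = 2))
  ds <- simulate_binding(la, lib)
  bt <- average_replicates(ds)
  mu <- la$baseline_counts +
    la$gain * outer(10^affinity(la, lib), la$concentrations)
  expect_equal(unname(bt$log10_binding), log10(round(pmin(mu, 65536))),
               tolerance = 1e-12)
})

test_that("duplicate sequences collapse by averaging their log values", {
  ds <- structure(list(
    peptides = data.frame(sequence = c("ADEFG", "ADEFG"),
                          feature_id = c("F1", "F2"),
                          control = FALSE, cognate = FALSE),
    concentrations = 8,
    counts = array(c(100L, 1000L), dim = c(2, 1, 1)),
    saturation_cap = 65536L, landscape = NULL), class = "array_dataset")
  bt <- average_replicates(ds)
  expect_equal(length(bt$sequence), 1)
  expect_equal(unname(bt$log10_binding[1, 1]), 2.5)
  expect_equal(bt$duplicates_collapsed, 1L)
})

test_that("saturation correction applies the concentration-ratio rule", {
  cap_log <- log10(65536)
  bt <- make_bt("ADEFG", matrix(c(3.0, 3.5, 4.0, cap_log), 1))
  out <- correct_saturation(bt)
  expect_equal(unname(out$log10_binding[1, 4]), 4.0 + log10(4))
  expect_equal(round(unname(out$log10_binding[1, 4]), 3), 4.602)
  expect_equal(unname(out$flags[1, 4]), "saturation_substituted")
  expect_equal(out$flags[1, 1:3], setNames(rep("measured", 3),
                                           colnames(out$flags)[1:3]))

  # cascade: 2 nM and 8 nM both saturated, 0.5 nM = 3.7
  bt2 <- make_bt("ADEFG", matrix(c(3.0, 3.7, cap_log, cap_log), 1))
  out2 <- correct_saturation(bt2)
  expect_equal(unname(out2$log10_binding[1, 3]), 3.7 + log10(4))
  expect_equal(unname(out2$log10_binding[1, 4]), 3.7 + 2 * log10(4))
  expect_equal(unname(round(out2$log10_binding[1, 3:4], 3)),
               c(4.302, 4.904))

  # nothing saturated -> identity
  bt3 <- make_bt("ADEFG", matrix(c(3.0, 3.2, 3.4, 3.6), 1))
  expect_identical(correct_saturation(bt3), bt3)

  # idempotence on an already-corrected table
  expect_identical(correct_saturation(out2), out2)

  # saturation at the lowest concentration is flagged, not corrected
  bt4 <- make_bt("ADEFG", matrix(c(cap_log, cap_log, 3, 3), 1))
  expect_warning(out4 <- correct_saturation(bt4), "lowest")
  expect_equal(unname(out4$log10_binding[1, 1]), cap_log)
  expect_equal(unname(out4$flags[1, 1]), "saturated_uncorrected")
})

test_that("length filter and cognate exclusion keep retained values intact", {
  seqs <- c("ADEF", "ADEFG", "ADEFGHKLNPQ", "ADEFGHKLNPQR", "RHSVVVP",
            "RHSVVVP")
  bt <- make_bt(seqs, matrix(seq_len(24), 6, 4))
  f <- filter_by_length(bt)
  expect_equal(f$sequence, c("ADEFG", "ADEFGHKLNPQ", "RHSVVVP", "RHSVVVP"))
  expect_equal(f$log10_binding, bt$log10_binding[c(2, 3, 5, 6), ])

  e <- exclude_cognates(f, "RHSVVVP") # duplicates: all copies removed
  expect_equal(e$sequence, c("ADEFG", "ADEFGHKLNPQ"))
  expect_equal(attr(e, "n_removed"), 2L)
  expect_equal(e$log10_binding, bt$log10_binding[2:3, ])

  expect_equal(attr(exclude_cognates(f, "WWWWWWW"), "n_removed"), 0L)
  expect_warning(filter_by_length(make_bt("ADE", matrix(1:4, 1))),
                 "no peptides")
})

test_that("kmer coverage counts distinct substrings over 16^k", {
  expect_equal(kmer_coverage(c("ADEF", "DEFG"), 4), 2 / 65536)
  expect_equal(kmer_coverage(paste(aa_alphabet(), collapse = ""), 1), 1.0)
  lib <- generate_library(library_spec(n_peptides = 2000, seed = 21))
  cov <- vapply(1:5, kmer_coverage, numeric(1), sequences = lib)
  expect_true(all(diff(cov) <= 0)) # monotone nonincreasing in k
  expect_warning(z <- kmer_coverage("ADEFG", 9), "exceeds")
  expect_equal(z, 0)
})

test_that("replicate correlations flag disagreeing channels", {
  la <- abundant_signal_landscape(seed = 31)
  la$noise_sigma <- 0.005 # low-noise fixture: replicates must agree
  lib <- generate_library(library_spec(n_peptides = 4000, seed = 15))
  ds <- simulate_binding(la, lib)
  cm <- replicate_correlation(ds)
  expect_equal(diag(cm), setNames(rep(1, 4), rownames(cm)))
  expect_equal(max(abs(cm - t(cm))), 0)
  expect_true(all(cm[upper.tri(cm)] > 0.95))
  expect_equal(nrow(attr(cm, "flagged")), 0)

  # destroy one replicate by permuting its cells
  set.seed(99)
  ds$counts[, , 4] <- array(sample(ds$counts[, , 4]), dim = dim(ds$counts)[1:2])
  cm2 <- replicate_correlation(ds)
  expect_lt(max(abs(cm2[1:3, 4])), 0.2)
  expect_equal(nrow(attr(cm2, "flagged")), 3)

  ds$counts[, , 4] <- ds$counts[, , 1] # identical replicates correlate at 1
  cm3 <- replicate_correlation(ds)
  expect_equal(cm3[1, 4], 1)
})

test_that("binding tables round-trip through TSV", {
  la <- abundant_signal_landscape(seed = 3)
  lib <- generate_library(library_spec(n_peptides = 30, seed = 8))
  bt <- correct_saturation(average_replicates(simulate_binding(la, lib)))
  path <- tempfile(fileext = ".tsv")
  write_binding_table(bt, path)
  bt2 <- read_binding_table(path)
  expect_equal(bt2$sequence, bt$sequence)
  expect_equal(bt2$log10_binding, bt$log10_binding, tolerance = 1e-6)
  expect_identical(unname(bt2$flags), unname(bt$flags))
  expect_equal(bt2$concentrations, bt$concentrations)
})
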