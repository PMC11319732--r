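test_that("absent amino acids map to their library surrogates", {
  expect_identical(map_missing_aa("KLISEED"), "KLVSEED")
  expect_identical(map_missing_aa("CTM"), "SSL")
  expect_identical(map_missing_aa("ADEFGHKLNPQRSVWY"), "ADEFGHKLNPQRSVWY")
})

test_that("similarity counts match the brute-force register scan", {
  expect_equal(similarity_count("AAARHSV", "RHSVVVP"), 4L)
  expect_equal(similarity_count("AARHSVVVPAA", "RHSVVVP"), 7L)
  expect_equal(similarity_count("GGGGGGG", "RHSVVVP"), 0L)
  set.seed(3)
  peps <- epibind:::random_peptides(sample(5:11, 50, TRUE))
  expect_equal(similarity_count(peps, "RHSVVVP"),
               vapply(peps, function(p) {
                 as.integer(brute_overlap_score(p, "RHSVVVP", rep(1, 7)))
               }, integer(1), USE.NAMES = FALSE))
  expect_true(all(similarity_count(peps, "RHSVVVP") <=
                    pmin(nchar(peps), 7)))
})

test_that("similarity filtering is monotone and removes planted probes", {
  cognate <- "RHSVVVP"
  seqs <- c("AARHSVVVPAA", "RHSVVAAAA", "GGGGGGG", "AAARHSV", "DDDDDDDD")
  bt <- make_bt(seqs, matrix(3, 5, 4))
  expect_equal(filter_by_similarity(bt, cognate, 7)$sequence, seqs)
  kept <- lapply(2:6, function(k) {
    filter_by_similarity(bt, cognate, k)$sequence
  })
  for (i in 2:length(kept)) {
    expect_true(all(kept[[i - 1]] %in% kept[[i]])) # superset monotonicity
  }
  f4 <- filter_by_similarity(bt, cognate, 4)
  expect_false("AARHSVVVPAA" %in% f4$sequence) # full-motif probe removed
  expect_equal(attr(f4, "n_removed"), 2L)
  # max_common = 0: only peptides sharing no aligned residue survive
  f0 <- filter_by_similarity(bt, cognate, 0)
  expect_equal(f0$sequence, c("GGGGGGG", "DDDDDDDD"))
})

test_that("downsampling is seeded, sized and order-preserving", {
  bt <- make_bt(epibind:::random_peptides(rep(8L, 101)),
                matrix(rnorm(404), 101, 4))
  expect_identical(downsample(bt, 1), bt)
  d <- downsample(bt, 0.5, seed = 4)
  expect_length(d$sequence, 50)
  expect_true(all(d$sequence %in% bt$sequence))
  expect_identical(downsample(bt, 0.5, seed = 4)$sequence, d$sequence)
  d2 <- downsample(bt, 0.5, seed = 5)
  expect_length(d2$sequence, 50)
  expect_false(identical(d2$sequence, d$sequence))
})

test_that("substitution scans normalize to the wild type", {
  # stub predictor: linear binding proportional to matches with a target
  target <- "PLEEVLN"
  mod <- stub_model(function(s) {
    v <- epibind:::best_overlap_score_cpp(s, target, rep(0.4, 7))
    cbind(v, v, v, v)
  })
  scan <- substitution_scan(mod, target)
  expect_equal(dim(unclass(scan)), c(7, 16))
  wt <- strsplit(target, "")[[1]]
  expect_equal(unname(unclass(scan)[cbind(1:7, match(wt, aa_alphabet()))]),
               rep(1, 7))
  expect_true(all(unclass(scan) >= 0))
  # every true substitution loses 0.4 log units relative to the cognate
  off <- unclass(scan)[cbind(1:7, match(wt, aa_alphabet()))] /
    unclass(scan)[1, "A"]
  expect_equal(unname(off), rep(10^0.4, 7), tolerance = 1e-10)

  clipped <- substitution_scan(mod, target, clip = 1.1)
  expect_true(all(unclass(clipped) <= 1.1))
  expect_error(substitution_scan(mod, target, concentration = 3),
               "not modelled")
})

test_that("the ground-truth substitution matrix penalizes motif positions", {
  la <- abundant_signal_landscape(seed = 1)
  tm <- true_substitution_matrix(la, la$motif)
  wt <- strsplit(la$motif, "")[[1]]
  expect_equal(unname(tm[cbind(1:7, match(wt, aa_alphabet()))]), rep(1, 7))
  # off-motif substitutions reduce expected binding
  expect_true(all(tm[1, setdiff(aa_alphabet(), c(wt[1], "W", "Y", "R",
                                                 "F"))] < 1))
})

test_that("antigen tiling scores every residue with the covering-tile max", {
  target <- "PLEEVLN"
  mod <- stub_model(function(s) {
    v <- epibind:::best_overlap_score_cpp(s, target, rep(0.5, 7))
    cbind(v / 8, v / 4, v / 2, v)
  })
  expect_error(tile_antigen(mod, "ADEF"), "shorter")

  antigen <- "ADEFGHKLNP"
  tp <- tile_antigen(mod, antigen)
  expect_equal(nrow(tp$tiles), 4) # 10 - 7 + 1
  expect_equal(nrow(tp$residues), 10)
  expect_true(all(is.finite(tp$residues$score)))

  # planted motif: the maximum tile sits at the motif locus
  antigen2 <- paste0("ADEFGHKLNP", target, "GGGGGHKLNP")
  tp2 <- tile_antigen(mod, antigen2)
  expect_equal(tp2$tiles$start[which.max(tp2$tiles$score)], 11)
  # residue scores at the motif exceed the flanks
  expect_gt(min(tp2$residues$score[11:17]),
            max(tp2$residues$score[1:4]))

  # I/T/M/C in the antigen are mapped, not rejected
  tp3 <- tile_antigen(mod, "ADEFITMCKLN")
  expect_equal(paste(tp3$residues$mapped_residue, collapse = ""),
               "ADEFVSLSKLN")

  # constant model gives a flat profile
  flat <- stub_model(function(s) matrix(2.9, length(s), 4))
  tpf <- tile_antigen(flat, antigen2)
  expect_equal(var(tpf$tiles$score), 0)

  # mean aggregation is bounded by max aggregation
  tpm <- tile_antigen(mod, antigen2, aggregate = "mean")
  expect_true(all(tpm$residues$score <= tp2$residues$score + 1e-12))
})

test_that("epitope tables serialize as annotated TSV", {
  target <- "PLEEVLN"
  mod <- stub_model(function(s) {
    v <- epibind:::best_overlap_score_cpp(s, target, rep(0.5, 7))
    cbind(v, v, v, v)
  })
  scan <- substitution_scan(mod, target)
  p1 <- tempfile(fileext = ".tsv")
  write_epitope_table(scan, p1)
  df <- read.delim(p1, comment.char = "#", check.names = FALSE)
  expect_equal(nrow(df), 7)
  expect_equal(names(df)[1], "position")

  tp <- tile_antigen(mod, paste0("ADEFGHKLNP", target))
  p2 <- tempfile(fileext = ".tsv")
  write_epitope_table(tp, p2)
  df2 <- read.delim(p2, comment.char = "#", check.names = FALSE)
  expect_equal(nrow(df2), nchar(paste0("ADEFGHKLNP", target)))
})
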