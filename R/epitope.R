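#' Map the four absent amino acids onto the library alphabet
#'
#' The arrays omit C, I, M and T; natural sequences are mapped onto the
#' 16-letter alphabet by PAM250-nearest substitution: I->V, T->S, M->L,
#' C->S. All other letters pass through unchanged.
#'
#' @param sequences Character vector of protein sequences.
#' @return Character vector over the 16-letter alphabet.
#' @examples
#' map_missing_aa("KLISEED") # "KLVSEED"
#' @export
map_missing_aa <- function(sequences) {
  chartr("ITMC", "VSLS", sequences)
}

#' Single-residue substitution scan of a cognate sequence
#'
#' Predicts binding for every single amino-acid substitution of the cognate
#' over the 16-letter alphabet, converts to the linear scale at the scan
#' concentration (2 nM by default) and normalizes to the unmutated
#' cognate's value. Wild-type cells are exactly 1 by construction. An
#' optional display clip maps values above `clip` to `clip` (presentation
#' only; the raw matrix is what downstream analyses should use).
#'
#' @param object A `binding_model` or `binding_ensemble`.
#' @param cognate Cognate sequence over the 16-letter alphabet.
#' @param concentration Scan concentration in nM (default 2).
#' @param clip Optional upper display clip (e.g. 1.1); `NULL` for raw.
#' @return Object of class `substitution_matrix`: an L x 16 numeric matrix
#'   (rows `"<pos><wt>"`, columns the alphabet) with the scan metadata in
#'   attributes.
#' @export
substitution_scan <- function(object, cognate, concentration = 2,
                              clip = NULL) {
  assert_alphabet(cognate, "cognate")
  aa <- aa_alphabet()
  L <- nchar(cognate)
  wt <- strsplit(cognate, "")[[1]]
  variants <- character(L * 16L)
  for (i in seq_len(L)) {
    for (j in seq_along(aa)) {
      v <- wt
      v[i] <- aa[j]
      variants[(i - 1L) * 16L + j] <- paste(v, collapse = "")
    }
  }
  conc_j <- match(concentration, object_concentrations(object))
  if (is.na(conc_j)) stop("concentration not modelled", call. = FALSE)
  pred <- predict(object, c(cognate, variants))[, conc_j]
  lin <- 10^pred[-1] / 10^pred[1]
  m <- matrix(lin, nrow = L, ncol = 16L, byrow = TRUE,
              dimnames = list(paste0(seq_len(L), wt), aa))
  # exact wild-type identity: the substituted sequence IS the cognate
  m[cbind(seq_len(L), match(wt, aa))] <- 1
  if (!is.null(clip)) m <- pmin(m, clip)
  structure(m, class = c("substitution_matrix", class(m)),
            cognate = cognate, concentration = concentration, clip = clip)
}

object_concentrations <- function(object) {
  if (inherits(object, "binding_ensemble")) {
    object$models[[1]]$concentrations
  } else {
    object$concentrations
  }
}

#' Ground-truth substitution matrix of a synthetic landscape
#'
#' The oracle counterpart of [substitution_scan()]: expected linear counts
#' of every single mutant, normalized to the cognate, computed directly from
#' the generative affinity function (detector ceiling applied).
#'
#' @param landscape A [binding_landscape()].
#' @param cognate Sequence to scan (default the planted motif).
#' @param concentration Concentration in nM (default 2).
#' @return L x 16 numeric matrix, same layout as [substitution_scan()].
#' @export
true_substitution_matrix <- function(landscape, cognate = landscape$motif,
                                     concentration = 2) {
  aa <- aa_alphabet()
  L <- nchar(cognate)
  wt <- strsplit(cognate, "")[[1]]
  variants <- character(L * 16L)
  for (i in seq_len(L)) {
    for (j in seq_along(aa)) {
      v <- wt
      v[i] <- aa[j]
      variants[(i - 1L) * 16L + j] <- paste(v, collapse = "")
    }
  }
  mu <- function(s) {
    pmin(landscape$baseline_counts +
           landscape$gain * concentration * 10^affinity(landscape, s),
         landscape$saturation_cap)
  }
  m <- matrix(mu(variants) / mu(cognate), nrow = L, ncol = 16L,
              byrow = TRUE, dimnames = list(paste0(seq_len(L), wt), aa))
  m[cbind(seq_len(L), match(wt, aa))] <- 1
  m
}

#' Tile an antigen and predict per-tile binding
#'
#' The antigen is decomposed into overlapping tiles (7-mers with 6-residue
#' overlap by default, i.e. offset 1), the absent amino acids are mapped
#' onto the library alphabet, and log10 binding at the scan concentration
#' is predicted per tile. Per-residue scores aggregate over the tiles
#' covering each position (maximum by default; mean available).
#'
#' @param object A `binding_model` or `binding_ensemble`.
#' @param antigen Antigen amino-acid sequence (20-letter alphabet allowed).
#' @param tile_len Tile length (default 7).
#' @param overlap Residues shared by consecutive tiles (default 6).
#' @param concentration Concentration in nM (default 2).
#' @param aggregate Per-residue aggregation, `"max"` (default) or
#'   `"mean"`.
#' @return Object of class `tiling_profile`: list with the per-tile data
#'   frame (`start`, `tile`, `score`) and the per-residue data frame
#'   (`position`, `residue`, `score`).
#' @export
tile_antigen <- function(object, antigen, tile_len = 7L, overlap = 6L,
                         concentration = 2,
                         aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(overlap < tile_len)
  mapped <- map_missing_aa(antigen)
  assert_alphabet(mapped, "mapped antigen")
  L <- nchar(mapped)
  if (L < tile_len) stop("antigen shorter than one tile", call. = FALSE)
  step <- tile_len - overlap
  starts <- seq.int(1L, L - tile_len + 1L, by = step)
  tiles <- substring(mapped, starts, starts + tile_len - 1L)
  conc_j <- match(concentration, object_concentrations(object))
  if (is.na(conc_j)) stop("concentration not modelled", call. = FALSE)
  score <- predict(object, tiles)[, conc_j]
  res_score <- vapply(seq_len(L), function(p) {
    cov <- which(starts <= p & starts + tile_len - 1L >= p)
    if (length(cov) == 0) return(NA_real_)
    if (aggregate == "max") max(score[cov]) else mean(score[cov])
  }, numeric(1))
  structure(list(
    tiles = data.frame(start = starts, tile = tiles, score = score),
    residues = data.frame(position = seq_len(L),
                          residue = strsplit(antigen, "")[[1]],
                          mapped_residue = strsplit(mapped, "")[[1]],
                          score = res_score),
    concentration = concentration, aggregate = aggregate),
    class = "tiling_profile")
}

#' Identity matches of a peptide with a cognate 7-mer, best register
#'
#' The maximum over all ungapped offsets (partial overlaps with at least
#' one aligned position included) of the number of positions at which the
#' peptide and the cognate carry the same residue. Identity only - no
#' similarity matrix.
#'
#' @param peptides Character vector.
#' @param cognate7 Cognate sequence (typically the 7-mer epitope).
#' @return Integer vector of best-register match counts.
#' @examples
#' similarity_count("AAARHSV", "RHSVVVP") # 4
#' @export
similarity_count <- function(peptides, cognate7) {
  as.integer(round(best_overlap_score_cpp(
    peptides, cognate7, rep(1, nchar(cognate7)))))
}

#' Remove training peptides similar to the cognate
#'
#' Robustness probe: retain only peptides whose best-register identity with
#' the cognate is at most `max_common` residues, then retrain and re-rank.
#' How fast the ranking degrades as `max_common` falls measures how much
#' the model leans on near-cognate training examples.
#'
#' @param bt A `binding_table`.
#' @param cognate7 Cognate sequence.
#' @param max_common Maximum allowed identity count (2-6 in the robustness
#'   ladder).
#' @return The filtered `binding_table`; attribute `n_removed` records how
#'   many rows were dropped.
#' @export
filter_by_similarity <- function(bt, cognate7, max_common) {
  stopifnot(inherits(bt, "binding_table"))
  keep <- similarity_count(bt$sequence, cognate7) <= max_common
  out <- subset_binding_table(bt, keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Downsample a binding table
#'
#' Seeded uniform subsample without replacement of `floor(fraction * n)`
#' rows, used to probe how model quality decays with training-set size.
#'
#' @param bt A `binding_table`.
#' @param fraction Fraction of rows to keep, in (0, 1].
#' @param seed Integer seed.
#' @return The subsampled `binding_table` (original row order preserved).
#' @export
downsample <- function(bt, fraction, seed = 1L) {
  stopifnot(inherits(bt, "binding_table"), fraction > 0, fraction <= 1)
  n <- length(bt$sequence)
  if (fraction == 1) return(bt)
  keep <- sort(with_seed(seed, sample.int(n, floor(fraction * n))))
  subset_binding_table(bt, keep)
}

#' Write a substitution matrix or tiling profile as TSV
#'
#' @param x A `substitution_matrix` or `tiling_profile`.
#' @param path File path.
#' @export
write_epitope_table <- function(x, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (inherits(x, "substitution_matrix")) {
    writeLines(sprintf("# epibind substitution scan, cognate=%s, conc=%gnM",
                       attr(x, "cognate"), attr(x, "concentration")), con)
    df <- data.frame(position = rownames(x), unclass(x),
                     check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (inherits(x, "tiling_profile")) {
    writeLines(sprintf("# epibind tiling profile, conc=%gnM, aggregate=%s",
                       x$concentration, x$aggregate), con)
    df <- merge(x$residues,
                stats::setNames(x$tiles, c("position", "tile",
                                           "tile_score")),
                by = "position", all.x = TRUE)
    utils::write.table(df[order(df$position), ], con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    stop("unsupported object", call. = FALSE)
  }
  invisible(path)
}
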