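#' Read and write peptide-array count tables
#'
#' Tables are UTF-8 TSV with one metadata comment line (`# epibind ...`), a
#' header row, column 1 `sequence`, optional `feature_id`/`control`/`cognate`
#' columns, and one integer count column per concentration x replicate named
#' `c{conc}_r{rep}` (e.g. `c0.125_r1`). Write-then-read is lossless.
#'
#' @param path File path.
#' @param saturation_cap Detector ceiling; counts above it are a format
#'   error (default 65536).
#' @param sep Field separator (default tab).
#' @return `read_array_table` returns an `array_dataset`.
#' @export
read_array_table <- function(path, saturation_cap = 65536L, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sequence" %in% names(df)) {
    stop("missing 'sequence' column in ", path, call. = FALSE)
  }
  count_cols <- grep("^c[0-9.]+_r[0-9]+$", names(df), value = TRUE)
  if (length(count_cols) == 0) {
    stop("no c{conc}_r{rep} count columns found in ", path, call. = FALSE)
  }
  concs <- sort(unique(as.numeric(sub("^c([0-9.]+)_r[0-9]+$", "\\1",
                                      count_cols))))
  reps <- sort(unique(as.integer(sub("^c[0-9.]+_r([0-9]+)$", "\\1",
                                     count_cols))))
  expect <- as.vector(outer(concs, reps,
                            function(co, re) sprintf("c%s_r%d",
                                                     format_conc(co), re)))
  missing_cols <- setdiff(expect, count_cols)
  if (length(missing_cols) > 0) {
    stop("incomplete concentration x replicate grid; missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cnt <- as.matrix(df[expect])
  bad <- which(cnt != round(cnt) | cnt < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-integer or negative counts at data rows: ",
         paste(utils::head(unique(bad[, 1]), 5), collapse = ", "),
         call. = FALSE)
  }
  over <- which(cnt > saturation_cap, arr.ind = TRUE)
  if (nrow(over) > 0) {
    stop(sprintf("counts above the saturation cap (%d) at data rows: %s",
                 saturation_cap,
                 paste(utils::head(unique(over[, 1]), 5), collapse = ", ")),
         call. = FALSE)
  }
  if ("feature_id" %in% names(df)) {
    dup <- df$feature_id[duplicated(df$feature_id)]
    if (length(dup) > 0) {
      stop("duplicate feature ids: ",
           paste(utils::head(unique(dup), 5), collapse = ", "),
           call. = FALSE)
    }
    fid <- df$feature_id
  } else {
    fid <- sprintf("F%06d", seq_len(nrow(df)))
  }
  counts <- array(cnt, dim = c(nrow(df), length(concs), length(reps)))
  storage.mode(counts) <- "integer"
  peptides <- data.frame(
    sequence = df$sequence, feature_id = fid,
    control = if ("control" %in% names(df)) as.logical(df$control) else FALSE,
    cognate = if ("cognate" %in% names(df)) as.logical(df$cognate) else FALSE,
    stringsAsFactors = FALSE)
  structure(list(peptides = peptides, concentrations = concs,
                 counts = counts,
                 saturation_cap = as.integer(saturation_cap),
                 landscape = NULL),
            class = "array_dataset")
}

#' @rdname read_array_table
#' @param ds An `array_dataset` (see [simulate_binding()]).
#' @export
write_array_table <- function(ds, path, sep = "\t") {
  stopifnot(inherits(ds, "array_dataset"))
  nc <- length(ds$concentrations)
  nr <- dim(ds$counts)[3]
  cols <- as.vector(outer(seq_len(nc), seq_len(nr), function(j, r) {
    sprintf("c%s_r%d", format_conc(ds$concentrations[j]), r)
  }))
  flat <- matrix(ds$counts, nrow = dim(ds$counts)[1])
  colnames(flat) <- cols
  df <- cbind(ds$peptides[c("sequence", "feature_id", "control", "cognate")],
              as.data.frame(flat, check.names = FALSE))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# epibind v%s array table, cap=%d",
                     as.character(utils::packageVersion("epibind")),
                     ds$saturation_cap), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average replicates on the log10 scale
#'
#' Each binding-table cell is the arithmetic mean over replicates of the
#' log10 counts; no outliers are removed. Exact duplicate sequences are
#' collapsed by averaging their log values (the number collapsed is recorded
#' in the `duplicates_collapsed` attribute).
#'
#' @param ds An `array_dataset`.
#' @return A `binding_table`: sequences plus a peptide x concentration
#'   matrix of averaged log10 intensities, with per-cell provenance flags
#'   (`measured` initially).
#' @export
average_replicates <- function(ds) {
  stopifnot(inherits(ds, "array_dataset"))
  if (any(ds$counts < 1)) {
    stop("counts below 1 cannot be log-averaged", call. = FALSE)
  }
  lg <- log10(ds$counts)
  avg <- apply(lg, c(1, 2), mean)
  seqs <- ds$peptides$sequence
  ndup <- sum(duplicated(seqs))
  if (ndup > 0) {
    avg <- rowsum(avg, group = seqs, reorder = FALSE) /
      as.vector(table(factor(seqs, levels = unique(seqs))))
    seqs <- unique(seqs)
  }
  colnames(avg) <- sprintf("c%s", format_conc(ds$concentrations))
  flags <- matrix("measured", nrow(avg), ncol(avg),
                  dimnames = dimnames(avg))
  structure(list(sequence = seqs, log10_binding = avg, flags = flags,
                 concentrations = ds$concentrations,
                 saturation_cap = ds$saturation_cap,
                 duplicates_collapsed = ndup),
            class = "binding_table")
}

#' Correct detector saturation by linear extrapolation from lower
#' concentration
#'
#' Binding grows linearly with concentration in the unsaturated regime, so a
#' saturated value at one concentration is replaced by the value at the next
#' lower concentration plus log10 of the concentration ratio. Corrections
#' cascade upward in concentration; already-substituted cells are never
#' re-corrected (the operation is idempotent). A saturated cell at the
#' lowest concentration cannot be corrected and is flagged
#' `saturated_uncorrected` with a warning.
#'
#' @param bt A `binding_table`.
#' @param cap Detector ceiling in counts (default the table's cap). A cell
#'   saturates iff its averaged log10 value >= log10(cap) - 1e-9.
#' @return The corrected `binding_table` (flags updated).
#' @export
correct_saturation <- function(bt, cap = bt$saturation_cap) {
  stopifnot(inherits(bt, "binding_table"))
  thresh <- log10(cap) - 1e-9
  v <- bt$log10_binding
  fl <- bt$flags
  ratios <- bt$concentrations[-1] / bt$concentrations[-length(bt$concentrations)]
  low_sat <- v[, 1] >= thresh & fl[, 1] != "saturation_substituted"
  if (any(low_sat)) {
    warning(sum(low_sat),
            " cell(s) saturated at the lowest concentration left as-is")
    fl[low_sat, 1] <- "saturated_uncorrected"
  }
  for (j in seq_along(ratios) + 1L) {
    sat <- v[, j] >= thresh & fl[, j] != "saturation_substituted"
    usable <- v[, j - 1] < thresh | fl[, j - 1] == "saturation_substituted"
    fix <- sat & usable
    if (any(fix)) {
      v[fix, j] <- v[fix, j - 1] + log10(ratios[j - 1])
      fl[fix, j] <- "saturation_substituted"
    }
    if (any(sat & !usable)) fl[sat & !usable, j] <- "saturated_uncorrected"
  }
  bt$log10_binding <- v
  bt$flags <- fl
  bt
}

# subset a binding table's rows, preserving order and values
subset_binding_table <- function(bt, keep) {
  bt$sequence <- bt$sequence[keep]
  bt$log10_binding <- bt$log10_binding[keep, , drop = FALSE]
  bt$flags <- bt$flags[keep, , drop = FALSE]
  bt
}

#' Restrict a binding table to the modelled length range
#'
#' Only peptides of 5-11 residues are modelled: continuous epitopes fall in
#' that range and longer peptides bias the network toward higher predictions
#' simply by carrying more residues.
#'
#' @param bt A `binding_table`.
#' @param min_len,max_len Inclusive length bounds (defaults 5 and 11).
#' @return The filtered `binding_table`; retained values are unaltered.
#' @export
filter_by_length <- function(bt, min_len = 5L, max_len = 11L) {
  stopifnot(inherits(bt, "binding_table"))
  len <- nchar(bt$sequence)
  keep <- len >= min_len & len <= max_len
  if (!any(keep)) warning("no peptides left after length filtering")
  subset_binding_table(bt, keep)
}

#' Remove cognate epitope probes before training
#'
#' Models must never see the cognate sequences they are later asked to rank;
#' exact-match rows are removed.
#'
#' @param bt A `binding_table`.
#' @param cognates Character vector of sequences to remove.
#' @return The filtered `binding_table`, with the number of rows removed in
#'   attribute `n_removed`.
#' @export
exclude_cognates <- function(bt, cognates) {
  stopifnot(inherits(bt, "binding_table"))
  keep <- !(bt$sequence %in% cognates)
  out <- subset_binding_table(bt, keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' k-mer coverage of a peptide library
#'
#' Fraction of all 16^k possible k-mers over the library alphabet that occur
#' as a contiguous substring of at least one library sequence. Near-random
#' libraries of ~1e5 ~9-mers cover essentially all 4-mers and roughly half
#' of the 5-mers.
#'
#' @param sequences Character vector of peptides.
#' @param k k-mer length.
#' @param alphabet Alphabet (default [aa_alphabet()]).
#' @return Fraction in `[0, 1]`.
#' @export
kmer_coverage <- function(sequences, k, alphabet = aa_alphabet()) {
  stopifnot(k >= 1)
  lens <- nchar(sequences)
  if (all(lens < k)) {
    warning("k exceeds every sequence length; coverage is 0")
    return(0)
  }
  kmers <- unlist(lapply(sequences[lens >= k], function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1), k:n)
  }), use.names = FALSE)
  length(unique(kmers)) / length(alphabet)^k
}

#' Replicate-replicate Pearson correlations on log10 counts
#'
#' QC statistic: correlations are computed across all peptide x
#' concentration cells between replicate channels; pairs below the
#' acceptance threshold (default 0.95) are flagged.
#'
#' @param ds An `array_dataset`.
#' @param threshold Minimum acceptable pairwise correlation.
#' @return Symmetric replicate x replicate correlation matrix with unit
#'   diagonal; attribute `flagged` is a data frame of below-threshold pairs.
#' @export
replicate_correlation <- function(ds, threshold = 0.95) {
  stopifnot(inherits(ds, "array_dataset"))
  nr <- dim(ds$counts)[3]
  flat <- matrix(log10(ds$counts), ncol = nr)
  cm <- stats::cor(flat)
  dimnames(cm) <- list(sprintf("r%d", 1:nr), sprintf("r%d", 1:nr))
  idx <- which(upper.tri(cm) & cm < threshold, arr.ind = TRUE)
  attr(cm, "flagged") <- data.frame(rep_a = rownames(cm)[idx[, 1]],
                                    rep_b = colnames(cm)[idx[, 2]],
                                    correlation = cm[idx])
  cm
}

#' Write / read an averaged binding table
#'
#' TSV with a metadata comment line; column 1 `sequence`, one 6-decimal
#' fixed-point `c{conc}` column per concentration, and one `flag_c{conc}`
#' provenance column per concentration.
#'
#' @param bt A `binding_table`.
#' @param path File path.
#' @export
write_binding_table <- function(bt, path) {
  stopifnot(inherits(bt, "binding_table"))
  vals <- format(round(bt$log10_binding, 6), nsmall = 6, trim = TRUE)
  df <- data.frame(sequence = bt$sequence, vals,
                   stats::setNames(as.data.frame(bt$flags),
                                   paste0("flag_", colnames(bt$flags))),
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# epibind v%s binding table, cap=%d",
                     as.character(utils::packageVersion("epibind")),
                     bt$saturation_cap), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_binding_table
#' @export
read_binding_table <- function(path) {
  header <- readLines(path, n = 1)
  cap <- as.integer(sub(".*cap=(\\d+).*", "\\1", header))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  val_cols <- grep("^c[0-9.]+$", names(df), value = TRUE)
  concs <- as.numeric(sub("^c", "", val_cols))
  o <- order(concs)
  v <- as.matrix(df[val_cols[o]])
  fl <- as.matrix(df[paste0("flag_", val_cols[o])])
  colnames(fl) <- colnames(v)
  structure(list(sequence = df$sequence, log10_binding = v, flags = fl,
                 concentrations = concs[o],
                 saturation_cap = if (is.na(cap)) 65536L else cap,
                 duplicates_collapsed = 0L),
            class = "binding_table")
}
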