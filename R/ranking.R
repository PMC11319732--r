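#' Generate a random comparison library
#'
#' i.i.d. uniform letters over the alphabet; duplicates are permitted (the
#' comparison set models a random draw from sequence space, not an array).
#'
#' @param n Number of sequences.
#' @param length Sequence length (the cognate's length, typically 7).
#' @param alphabet Alphabet (default [aa_alphabet()]).
#' @param seed Integer seed.
#' @return Character vector of `n` sequences.
#' @export
random_library <- function(n, length, alphabet = aa_alphabet(), seed = 1L) {
  if (n == 0) return(character(0))
  with_seed(seed, random_peptides(rep.int(as.integer(length), n), alphabet))
}

# deterministic 31-ary string hash (mod 2^31-1); C++ for million-scale sets
sequence_hash <- function(sequences) {
  sequence_hash_cpp(sequences)
}

#' Rank sequences from a prediction matrix
#'
#' The ranking rule applied to every comparison: (1) rank all sequences by
#' descending predicted value at each concentration separately; (2) keep
#' each sequence's best (smallest) per-concentration rank; (3) re-rank the
#' best ranks into a strict 1..n ordering. Ties in step 3 are broken by the
#' sum of the per-concentration ranks (a sequence ranked well at several
#' concentrations beats one strong at a single concentration), then by a
#' deterministic sequence hash. Working on ranks alone keeps the final
#' ordering invariant under any strictly monotone per-concentration
#' transform of the predictions.
#'
#' @param pred Numeric matrix, one row per sequence, one column per
#'   concentration.
#' @param sequences Character vector (used only for the deterministic tie
#'   break).
#' @return List with `per_concentration` (n x n_conc matrix of descending
#'   ranks), `best_rank` and `final_rank` (permutation of 1..n).
#' @export
rank_sequences <- function(pred, sequences) {
  stopifnot(nrow(pred) == length(sequences))
  per_conc <- apply(pred, 2, function(v) rank(-v, ties.method = "min"))
  best <- do.call(pmin, as.data.frame(per_conc))
  ord <- order(best, rowSums(per_conc), sequence_hash(sequences))
  final <- integer(length(ord))
  final[ord] <- seq_along(ord)
  list(per_concentration = per_conc, best_rank = best, final_rank = final)
}

#' Rank a cognate epitope among random sequences
#'
#' The headline specificity statistic: the trained model (usually an
#' ensemble; member predictions are averaged before ranking) predicts
#' binding for the cognate and `n` random sequences of the same length, and
#' the cognate's position in the re-ranked ordering is reported. Percent
#' rank is `100 * rank / (n + 1)`.
#'
#' @param object A `binding_model` or `binding_ensemble`.
#' @param cognate Cognate epitope sequence (over the 16-letter alphabet;
#'   map natural sequences first with [map_missing_aa()]).
#' @param randoms Character vector of comparison sequences (see
#'   [random_library()]).
#' @param average `"predictions"` (default) averages ensemble member
#'   predictions before ranking; `"ranks"` ranks per member and averages
#'   the final ranks.
#' @return An object of class `rank_result`.
#' @export
rank_cognate <- function(object, cognate, randoms,
                         average = c("predictions", "ranks")) {
  average <- match.arg(average)
  assert_alphabet(cognate, "cognate")
  seqs <- c(cognate, randoms)
  one_pass <- function(pred) {
    rk <- rank_sequences(pred, seqs)
    list(per_concentration = rk$per_concentration[1, ],
         best_rank = rk$best_rank[1], final_rank = rk$final_rank[1])
  }
  if (average == "ranks" && inherits(object, "binding_ensemble")) {
    passes <- lapply(object$models,
                     function(m) one_pass(predict(m, seqs)))
    final <- mean(vapply(passes, `[[`, numeric(1), "final_rank"))
    res <- list(per_concentration = round(rowMeans(vapply(
      passes, `[[`, numeric(length(object$models[[1]]$concentrations)),
      "per_concentration"))),
      best_rank = mean(vapply(passes, `[[`, numeric(1), "best_rank")),
      final_rank = final)
  } else {
    res <- one_pass(predict(object, seqs))
  }
  structure(list(cognate = cognate, n_random = length(randoms),
                 per_concentration = res$per_concentration,
                 best_rank = res$best_rank, final_rank = res$final_rank,
                 percent_rank = 100 * res$final_rank /
                   (length(randoms) + 1),
                 average = average),
            class = "rank_result")
}

#' @export
print.rank_result <- function(x, ...) {
  cat(sprintf("Cognate %s: rank %s of %d (%.4f%%)\n", x$cognate,
              format(x$final_rank, big.mark = ","), x$n_random + 1,
              x$percent_rank))
  invisible(x)
}

#' Repeat the ranking experiment over models and random sets
#'
#' The full error model: an ensemble is trained per repeat (fresh
#' initialization seeds), evaluated against independent random sequence
#' sets, and the mean rank with its standard error over all runs is
#' reported. At full scale this is 12 models x 2 sets x 5 repeats.
#'
#' @param ensemble_factory Function `(seed) -> binding_model or
#'   binding_ensemble`; called once per repeat.
#' @param cognate Cognate epitope sequence.
#' @param n_random Random sequences per comparison set.
#' @param n_random_sets Independent random sets per repeat (default 2).
#' @param n_repeats Seed repeats (default 5).
#' @param seed Base seed; all per-run seeds derive from it.
#' @param average Passed to [rank_cognate()].
#' @return List with the per-run results data frame, `mean_rank`, `sem`
#'   and `percent_rank` (of the mean rank).
#' @export
repeat_rank <- function(ensemble_factory, cognate, n_random = 1e6,
                        n_random_sets = 2L, n_repeats = 5L, seed = 1L,
                        average = "predictions") {
  runs <- list()
  for (rep_i in seq_len(n_repeats)) {
    obj <- ensemble_factory(seed + 97L * rep_i)
    for (set_i in seq_len(n_random_sets)) {
      randoms <- random_library(n_random, nchar(cognate),
                                seed = seed + 1013L * rep_i + set_i)
      rr <- rank_cognate(obj, cognate, randoms, average = average)
      runs[[length(runs) + 1L]] <- data.frame(
        repeat_i = rep_i, set_i = set_i, final_rank = rr$final_rank,
        percent_rank = rr$percent_rank)
    }
  }
  df <- do.call(rbind, runs)
  m <- mean(df$final_rank)
  sem <- if (nrow(df) > 1) stats::sd(df$final_rank) / sqrt(nrow(df)) else 0
  list(runs = df, mean_rank = m, sem = sem,
       percent_rank = 100 * m / (n_random + 1))
}

#' Top-k sequences of a comparison set
#'
#' The k best-ranked sequences under the same re-ranking rule as
#' [rank_cognate()], with their per-concentration predictions - the
#' "predicted top binders" table.
#'
#' @param object A `binding_model` or `binding_ensemble`.
#' @param randoms Character vector of sequences to rank.
#' @param k Number of rows to return (default 20).
#' @return Data frame sorted by final rank with the per-concentration
#'   predicted log10 binding.
#' @export
top_k_table <- function(object, randoms, k = 20L) {
  pred <- predict(object, randoms)
  rk <- rank_sequences(pred, randoms)
  o <- order(rk$final_rank)[seq_len(min(k, length(randoms)))]
  data.frame(rank = rk$final_rank[o], sequence = randoms[o],
             pred[o, , drop = FALSE], row.names = NULL,
             check.names = FALSE)
}
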