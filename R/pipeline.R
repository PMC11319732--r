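#' The four cumulative ablation configurations
#'
#' Baseline (no transformation), +weighting, +shifting (weighting plus
#' register shifts), +composition (all three) - the ladder along which the
#' training-set transformations are evaluated.
#'
#' @param config Base [model_config()] supplying architecture and training
#'   hyperparameters; the three ablation flags are overridden per stage.
#' @return Named list of four `model_config` objects.
#' @export
ablation_configs <- function(config = model_config()) {
  stages <- list(
    baseline = c(FALSE, FALSE, FALSE),
    `+weighting` = c(TRUE, FALSE, FALSE),
    `+shifting` = c(TRUE, TRUE, FALSE),
    `+composition` = c(TRUE, TRUE, TRUE)
  )
  lapply(stages, function(fl) {
    cfg <- config
    cfg$weighting <- fl[1]
    cfg$shifting <- fl[2]
    cfg$composition <- fl[3]
    cfg
  })
}

#' Run the ablation ladder on one dataset
#'
#' Trains an ensemble per cumulative configuration (shared seeds and shared
#' random comparison sets across stages) and reports the cognate's mean
#' rank, SEM and percent rank per stage.
#'
#' @param bt A prepared `binding_table`.
#' @param cognate Cognate epitope sequence.
#' @param config Base [model_config()].
#' @param n_models Ensemble size per stage.
#' @param n_random Random comparison sequences per set.
#' @param n_random_sets,n_repeats Error-model grid (see [repeat_rank()]).
#' @param seed Base seed shared by all stages.
#' @return Data frame, one row per stage, plus attribute `results` holding
#'   the per-stage [repeat_rank()] outputs.
#' @export
run_ablation_ladder <- function(bt, cognate, config = model_config(),
                                n_models = 3L, n_random = 1e5,
                                n_random_sets = 1L, n_repeats = 1L,
                                seed = 1L) {
  cfgs <- ablation_configs(config)
  results <- lapply(cfgs, function(cfg) {
    factory <- function(s) {
      cfg2 <- cfg
      cfg2$seed <- as.integer(s)
      train_ensemble(bt, cfg2, n_models = n_models)
    }
    repeat_rank(factory, cognate, n_random = n_random,
                n_random_sets = n_random_sets, n_repeats = n_repeats,
                seed = seed)
  })
  df <- data.frame(
    stage = names(cfgs),
    weighting = vapply(cfgs, `[[`, logical(1), "weighting"),
    shifting = vapply(cfgs, `[[`, logical(1), "shifting"),
    composition = vapply(cfgs, `[[`, logical(1), "composition"),
    mean_rank = vapply(results, `[[`, numeric(1), "mean_rank"),
    sem = vapply(results, `[[`, numeric(1), "sem"),
    percent_rank = vapply(results, `[[`, numeric(1), "percent_rank"),
    row.names = NULL)
  attr(df, "results") <- results
  df
}

#' Robustness suite: similarity filtering and downsampling
#'
#' Retrains the full model on training sets with near-cognate sequences
#' removed (identity thresholds 6..2) and on uniformly downsampled
#' training sets, re-ranking the cognate each time.
#'
#' @param bt A prepared `binding_table`.
#' @param cognate Cognate epitope sequence (7-mer).
#' @param config Full-model [model_config()] (weighting + shifting +
#'   composition).
#' @param thresholds Maximum-identity thresholds to scan.
#' @param fractions Training-set fractions to scan.
#' @param n_models,n_random,seed As in [run_ablation_ladder()].
#' @return List of two data frames, `similarity` (threshold, n_removed,
#'   rank statistics) and `downsampling` (fraction, n_train, rank
#'   statistics).
#' @export
run_robustness_suite <- function(bt, cognate,
                                 config = model_config(weighting = TRUE,
                                                       shifting = TRUE,
                                                       composition = TRUE),
                                 thresholds = c(6L, 5L, 4L, 3L, 2L),
                                 fractions = c(1, 0.75, 0.5, 0.25, 0.12,
                                               0.06),
                                 n_models = 3L, n_random = 1e5,
                                 seed = 1L) {
  rank_on <- function(bt_sub) {
    factory <- function(s) {
      cfg <- config
      cfg$seed <- as.integer(s)
      train_ensemble(bt_sub, cfg, n_models = n_models)
    }
    repeat_rank(factory, cognate, n_random = n_random,
                n_random_sets = 1L, n_repeats = 1L, seed = seed)
  }
  sim <- lapply(thresholds, function(th) {
    bt_f <- filter_by_similarity(bt, cognate, th)
    r <- rank_on(bt_f)
    data.frame(max_common = th, n_removed = attr(bt_f, "n_removed"),
               n_train = length(bt_f$sequence), mean_rank = r$mean_rank,
               sem = r$sem, percent_rank = r$percent_rank)
  })
  down <- lapply(fractions, function(fr) {
    bt_f <- downsample(bt, fr, seed = seed + round(1000 * fr))
    r <- rank_on(bt_f)
    data.frame(fraction = fr, n_train = length(bt_f$sequence),
               mean_rank = r$mean_rank, sem = r$sem,
               percent_rank = r$percent_rank)
  })
  list(similarity = do.call(rbind, sim),
       downsampling = do.call(rbind, down))
}

#' Shuffle binding targets relative to sequences
#'
#' Randomization control: permutes the target rows so each sequence carries
#' another sequence's measured binding. A model trained on shuffled targets
#' should rank the cognate near 50%.
#'
#' @param bt A `binding_table`.
#' @param seed Integer seed.
#' @return The `binding_table` with permuted target rows.
#' @export
shuffle_targets <- function(bt, seed = 1L) {
  stopifnot(inherits(bt, "binding_table"))
  n <- length(bt$sequence)
  p <- with_seed(seed, sample.int(n))
  bt$log10_binding <- bt$log10_binding[p, , drop = FALSE]
  bt$flags <- bt$flags[p, , drop = FALSE]
  bt
}

#' Simulate a preset landscape and prepare its training table
#'
#' Convenience wrapper used by the acceptance suite and the analysis
#' scripts: generates the library, simulates the assay, and runs the
#' standard preprocessing chain.
#'
#' @param preset `"abundant-signal"` or `"scarce-signal"`.
#' @param n_peptides Library size (desk-scale default 30000; the arrays
#'   themselves hold ~1.2e5).
#' @param seed Integer seed driving library sampling and assay noise.
#' @return List with the `landscape`, the raw `dataset`, the prepared
#'   `binding_table` and the planted `cognate` motif.
#' @export
simulate_preset <- function(preset = c("abundant-signal", "scarce-signal"),
                            n_peptides = 30000L, seed = 1L) {
  preset <- match.arg(preset)
  landscape <- if (preset == "abundant-signal") {
    abundant_signal_landscape(seed = seed + 11L)
  } else {
    scarce_signal_landscape(seed = seed + 23L)
  }
  spec <- library_spec(n_peptides = n_peptides, seed = seed)
  lib <- generate_library(spec)
  ds <- simulate_binding(landscape, lib)
  bt <- prepare_binding_table(ds, cognates = landscape$motif)
  list(preset = preset, landscape = landscape, dataset = ds,
       binding_table = bt, cognate = landscape$motif)
}

#' End-to-end synthetic acceptance run
#'
#' Generates a preset landscape, runs the full pipeline and evaluates the
#' recovery properties: on the abundant-signal preset the planted cognate
#' must rank in the top 0.1% and the model substitution scan must correlate
#' with the generative truth (r > 0.8); on the scarce-signal preset the
#' full pipeline must rank the cognate at least 10x better than the
#' baseline configuration.
#'
#' @param preset `"abundant-signal"` or `"scarce-signal"`.
#' @param seed Integer seed.
#' @param n_peptides Library size.
#' @param n_models Ensemble size.
#' @param n_random Random comparison sequences.
#' @param config Base [model_config()].
#' @return List with the per-check data frame (`checks`), the underlying
#'   rank results and the simulated inputs; `all_pass` summarizes.
#' @export
run_synthetic_acceptance <- function(preset = c("abundant-signal",
                                                "scarce-signal"),
                                     seed = 1L, n_peptides = 30000L,
                                     n_models = 3L, n_random = 1e5,
                                     config = model_config()) {
  preset <- match.arg(preset)
  sim <- simulate_preset(preset, n_peptides = n_peptides, seed = seed)
  full_cfg <- ablation_configs(config)$`+composition`
  full_cfg$seed <- as.integer(seed + 301L)
  ens <- train_ensemble(sim$binding_table, full_cfg, n_models = n_models)
  randoms <- random_library(n_random, nchar(sim$cognate),
                            seed = seed + 7L)
  rr_full <- rank_cognate(ens, sim$cognate, randoms)
  checks <- list()
  extras <- list(full = rr_full)
  if (preset == "abundant-signal") {
    scan <- substitution_scan(ens, sim$cognate)
    truth <- true_substitution_matrix(sim$landscape, sim$cognate)
    r <- stats::cor(as.vector(unclass(scan)), as.vector(truth))
    checks$cognate_top_0.1pct <- data.frame(
      check = "cognate percent rank <= 0.1", value = rr_full$percent_rank,
      threshold = 0.1, pass = rr_full$percent_rank <= 0.1)
    checks$scan_correlation <- data.frame(
      check = "substitution scan vs truth r > 0.8", value = r,
      threshold = 0.8, pass = r > 0.8)
    extras$scan <- scan
    extras$truth <- truth
  } else {
    base_cfg <- ablation_configs(config)$baseline
    base_cfg$seed <- as.integer(seed + 301L)
    ens_base <- train_ensemble(sim$binding_table, base_cfg,
                               n_models = n_models)
    rr_base <- rank_cognate(ens_base, sim$cognate, randoms)
    checks$full_vs_baseline <- data.frame(
      check = "full percent rank <= baseline / 10",
      value = rr_base$percent_rank / rr_full$percent_rank,
      threshold = 10,
      pass = rr_full$percent_rank <= rr_base$percent_rank / 10)
    extras$baseline <- rr_base
  }
  checks_df <- do.call(rbind, c(checks, make.row.names = FALSE))
  list(preset = preset, checks = checks_df,
       all_pass = all(checks_df$pass), results = extras, inputs = sim)
}
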