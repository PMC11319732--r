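#' Configuration for the sequence-binding network
#'
#' The regressor is a fully connected network with 2 hidden layers of 250
#' ReLU units and a 4-column linear output (one per assay concentration),
#' trained with Adam on (weighted) mean squared error. The three ablation
#' flags correspond to the cumulative training-set transformations studied
#' with this architecture: binned up-weighting of high binders, register-
#' shift expansion, and composition-model subtraction. Input width follows
#' the shifting flag: 13 tokens (247 one-hot features) unshifted, 18 tokens
#' (342 features) with shifting.
#'
#' @param weighting Apply binned high-binder weighting ([weight_expand()]).
#' @param shifting Expand every pair to 6 register-shifted copies and
#'   predict by frame-max.
#' @param composition Train on residuals from the composition model and add
#'   the composition prediction back at predict time.
#' @param hidden Hidden layer sizes (default `c(250, 250)`).
#' @param epochs,learning_rate,minibatch Adam training hyperparameters
#'   (defaults 30, 1e-3, 128).
#' @param lr_decay Per-epoch exponential learning-rate decay factor
#'   (default 1, i.e. constant rate; values below 1 anneal the step size).
#' @param max_len Maximum peptide length (default 11).
#' @param n_frames Number of shift registers (default 6).
#' @param frame_max `"per_concentration"` (default) takes the maximum
#'   predicted value per concentration across frames; `"per_sequence"`
#'   picks the single frame achieving the overall maximum and reports its
#'   4 values.
#' @param add_composition_back With `composition`, report predictions on
#'   the total log10-binding scale (default) rather than residuals.
#' @param bin_width,min_bin_count,max_copies Weighting parameters, see
#'   [weight_expand()].
#' @param seed Integer seed for weight initialization, minibatch order and
#'   the weighting expansion.
#' @return An object of class `model_config`.
#' @export
model_config <- function(weighting = FALSE, shifting = FALSE,
                         composition = FALSE, hidden = c(250L, 250L),
                         epochs = 30L, learning_rate = 1e-3,
                         lr_decay = 1,
                         minibatch = 128L, max_len = 11L, n_frames = 6L,
                         frame_max = c("per_concentration", "per_sequence"),
                         add_composition_back = TRUE, bin_width = 0.2,
                         min_bin_count = 300L, max_copies = 100L,
                         seed = 1L) {
  stopifnot(length(hidden) == 2, all(hidden >= 1), epochs >= 1,
            learning_rate > 0, minibatch >= 1)
  structure(list(weighting = weighting, shifting = shifting,
                 composition = composition, hidden = as.integer(hidden),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 minibatch = as.integer(minibatch),
                 max_len = as.integer(max_len),
                 n_frames = as.integer(n_frames),
                 frame_max = match.arg(frame_max),
                 add_composition_back = add_composition_back,
                 bin_width = bin_width,
                 min_bin_count = as.integer(min_bin_count),
                 max_copies = as.integer(max_copies),
                 seed = as.integer(seed)),
            class = "model_config")
}

# stack framed (optionally shifted) peptides into a 0-based token matrix;
# returns list(tokens, reps) where reps is the per-input replication factor
encode_training_inputs <- function(sequences, config) {
  framed <- frame_peptide(sequences, config$max_len)
  if (config$shifting) {
    fr <- shift_frames(framed, config$n_frames)
    tokens <- encode_tokens(as.vector(fr)) # frame-major blocks of n rows
    list(tokens = tokens - 1L, n_copies = config$n_frames)
  } else {
    list(tokens = encode_tokens(framed) - 1L, n_copies = 1L)
  }
}

#' Train the sequence-binding network
#'
#' Trains one network on an averaged, saturation-corrected, length-filtered
#' binding table with the cognate probes already excluded. All four
#' concentrations are fitted at once as a 4-column target. Weighting enters
#' as per-example loss weights (expectation-identical to materialized
#' copies); shifting materializes the 6 register copies, each carrying the
#' same target and weight.
#'
#' @param bt A prepared `binding_table` (see [prepare_binding_table()]).
#' @param config A [model_config()].
#' @return An object of class `binding_model`: layer weights, the fitted
#'   composition model (if enabled), the config and the training loss curve.
#' @export
train_binding_model <- function(bt, config = model_config()) {
  stopifnot(inherits(bt, "binding_table"), inherits(config, "model_config"))
  n <- length(bt$sequence)
  if (n < 2) stop("need at least 2 training sequences", call. = FALSE)
  mult <- if (config$weighting) {
    weight_expand(bt, bin_width = config$bin_width,
                  min_bin_count = config$min_bin_count,
                  max_copies = config$max_copies,
                  seed = config$seed + 1000L)
  } else rep.int(1L, n)
  comp_model <- NULL
  targets <- bt$log10_binding
  if (config$composition) {
    comp_model <- fit_composition(bt$sequence, bt$log10_binding)
    targets <- targets - predict_composition(comp_model, bt$sequence)
  }
  enc <- encode_training_inputs(bt$sequence, config)
  Y <- targets[rep(seq_len(n), times = enc$n_copies), , drop = FALSE]
  w <- rep.int(as.numeric(mult), enc$n_copies)
  fit <- mlp_train_cpp(enc$tokens, Y, w, 19L, config$hidden[1],
                       config$hidden[2], config$learning_rate,
                       config$lr_decay, config$epochs, config$minibatch,
                       config$seed)
  if (!all(is.finite(fit$loss))) {
    stop("training diverged (non-finite loss); loss curve: ",
         paste(signif(fit$loss, 4), collapse = ", "), call. = FALSE)
  }
  structure(list(weights = fit[c("W1", "b1", "W2", "b2", "W3", "b3")],
                 config = config, composition_model = comp_model,
                 concentrations = bt$concentrations,
                 loss = as.numeric(fit$loss),
                 token_order = token_alphabet()),
            class = "binding_model")
}

#' Predict log10 binding for query sequences
#'
#' With shifting enabled each query is submitted in all 6 registers and the
#' highest predicted value is kept (per concentration by default). With
#' composition enabled the composition prediction is added back so outputs
#' are on the total log10-binding scale. Batched and safe for millions of
#' query sequences.
#'
#' @param object A `binding_model` or `binding_ensemble`.
#' @param sequences Character vector, lengths 5-11, over the 16-letter
#'   alphabet (map natural sequences first with [map_missing_aa()]).
#' @param total Add the composition component back (default from the
#'   config); set `FALSE` to obtain the network residual prediction.
#' @param ... Unused.
#' @return Numeric matrix, one row per sequence, one column per
#'   concentration.
#' @export
predict.binding_model <- function(object, sequences, total = NULL, ...) {
  config <- object$config
  enc <- encode_training_inputs(sequences, config)
  w <- object$weights
  raw <- mlp_forward_cpp(enc$tokens, w$W1, w$b1, w$W2, w$b2, w$W3, w$b3, 19L)
  n <- length(sequences)
  nc <- ncol(raw)
  if (config$shifting) {
    # rows are frame-major blocks: frame k occupies rows (k-1)*n + 1:n
    pred <- array(raw, dim = c(n, config$n_frames, nc))
    if (config$frame_max == "per_concentration") {
      out <- apply(pred, c(1, 3), max)
    } else {
      best <- max.col(apply(pred, c(1, 2), max), ties.method = "first")
      out <- t(vapply(seq_len(n), function(i) pred[i, best[i], ],
                      numeric(nc)))
    }
  } else {
    out <- raw
  }
  if (is.null(total)) total <- config$add_composition_back
  if (config$composition && isTRUE(total)) {
    out <- out + predict_composition(object$composition_model, sequences)
  }
  colnames(out) <- sprintf("c%s", format_conc(object$concentrations))
  rownames(out) <- NULL
  out
}

#' Train an ensemble of independently initialized networks
#'
#' Ensembling over random initializations stabilizes the ranking statistic;
#' the ensemble prediction is the arithmetic mean of the member predictions
#' at each concentration.
#'
#' @param bt A prepared `binding_table`.
#' @param config A [model_config()].
#' @param n_models Ensemble size (12 at full scale; desk-scale presets use
#'   3).
#' @param seeds Optional integer vector of per-model seeds (default
#'   `config$seed + 0:(n_models-1)`).
#' @return An object of class `binding_ensemble`.
#' @export
train_ensemble <- function(bt, config = model_config(), n_models = 12L,
                           seeds = NULL) {
  if (is.null(seeds)) seeds <- config$seed + seq_len(n_models) - 1L
  stopifnot(length(seeds) == n_models)
  models <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    train_binding_model(bt, cfg)
  })
  structure(list(models = models, config = config, seeds = as.integer(seeds)),
            class = "binding_ensemble")
}

#' @rdname predict.binding_model
#' @export
predict.binding_ensemble <- function(object, sequences, total = NULL, ...) {
  preds <- lapply(object$models, predict, sequences = sequences,
                  total = total)
  Reduce(`+`, preds) / length(preds)
}

#' k-fold cross-validation of the sequence-binding relationship
#'
#' Peptides are partitioned into disjoint folds; weighting, composition
#' fitting and shifting are applied inside each training fold only, so no
#' expanded copies leak across folds. Held-out predictions are compared to
#' the measured (total-scale) values.
#'
#' @param bt A prepared `binding_table`.
#' @param config A [model_config()].
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return Data frame with one row per fold x concentration: Pearson r of
#'   measured vs predicted held-out binding.
#' @export
cross_validate <- function(bt, config = model_config(), k = 10L,
                           seed = 1L) {
  n <- length(bt$sequence)
  stopifnot(k >= 2, n >= 2 * k)
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  res <- lapply(seq_len(k), function(f) {
    train_bt <- subset_binding_table(bt, fold != f)
    test_bt <- subset_binding_table(bt, fold == f)
    cfg <- config
    cfg$seed <- as.integer(config$seed + f)
    model <- train_binding_model(train_bt, cfg)
    pred <- predict(model, test_bt$sequence)
    data.frame(fold = f, concentration = bt$concentrations,
               pearson_r = vapply(seq_along(bt$concentrations), function(j) {
                 stats::cor(test_bt$log10_binding[, j], pred[, j])
               }, numeric(1)))
  })
  do.call(rbind, res)
}

#' Prepare an array dataset for model training
#'
#' The standard preprocessing chain: average replicates on the log scale,
#' correct detector saturation, restrict to 5-11-mers and remove the
#' cognate probes.
#'
#' @param ds An `array_dataset`.
#' @param cognates Cognate sequences to exclude (default: probes flagged
#'   cognate in the dataset).
#' @return A `binding_table` ready for [train_binding_model()].
#' @export
prepare_binding_table <- function(ds, cognates = NULL) {
  stopifnot(inherits(ds, "array_dataset"))
  if (is.null(cognates)) {
    cognates <- ds$peptides$sequence[ds$peptides$cognate]
  }
  bt <- average_replicates(ds)
  bt <- correct_saturation(bt)
  bt <- filter_by_length(bt)
  exclude_cognates(bt, cognates)
}

#' Save / load a trained model or ensemble
#'
#' The weight container round-trips bit-exactly; a human-readable metadata
#' JSON (config, seeds, token order, composition coefficients) is written
#' alongside under `<path>.meta.json`.
#'
#' @param model A `binding_model` or `binding_ensemble`.
#' @param path File path for the weight container.
#' @export
save_binding_model <- function(model, path) {
  stopifnot(inherits(model, "binding_model") ||
              inherits(model, "binding_ensemble"))
  saveRDS(model, path)
  cfg <- if (inherits(model, "binding_ensemble")) model$config else
    model$config
  meta <- list(class = class(model)[1], config = unclass(cfg),
               token_order = paste(token_alphabet(), collapse = ""),
               seeds = if (inherits(model, "binding_ensemble"))
                 model$seeds else cfg$seed)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_binding_model
#' @export
load_binding_model <- function(path) {
  readRDS(path)
}
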