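#' Up-weight scarce high-binding sequences by binned copying
#'
#' Antibody binding to a near-random library is dominated by background, so
#' the handful of informative high binders barely register in a squared-error
#' loss. To rebalance, peptides are binned by their log10 binding at the
#' reference concentration (highest, 8 nM, by default) in half-open bins
#' `[m*bin_width, (m+1)*bin_width)` anchored at 0. Bins holding at least
#' `min_bin_count` pairs are untouched; smaller bins are grown toward
#' `min_bin_count` by uniform sampling with replacement within the bin,
#' except that no single sequence-binding pair may exceed `max_copies`
#' total copies. Multiplicities (not materialized copies) are returned so
#' the expansion composes cheaply with register shifting.
#'
#' @param bt A `binding_table` (averaged, saturation-corrected).
#' @param bin_width Bin width in log10 units (default 0.2).
#' @param min_bin_count Target bin occupancy (default 300).
#' @param max_copies Per-pair multiplicity cap (default 100).
#' @param reference_concentration Concentration whose values define the
#'   bins; default the highest assayed.
#' @param seed Integer seed; expansion is deterministic given it.
#' @return Integer vector of multiplicities, one per table row (all >= 1).
#' @export
weight_expand <- function(bt, bin_width = 0.2, min_bin_count = 300L,
                          max_copies = 100L,
                          reference_concentration = NULL, seed = 1L) {
  stopifnot(inherits(bt, "binding_table"), bin_width > 0,
            min_bin_count >= 1, max_copies >= 1)
  n <- length(bt$sequence)
  if (n == 0) return(integer(0))
  if (is.null(reference_concentration)) {
    reference_concentration <- max(bt$concentrations)
  }
  j <- match(reference_concentration, bt$concentrations)
  if (is.na(j)) stop("reference concentration not in table", call. = FALSE)
  v <- bt$log10_binding[, j]
  bin <- floor(v / bin_width)
  mult <- rep.int(1L, n)
  with_seed(seed, {
    for (b in sort(unique(bin))) {
      members <- which(bin == b)
      deficit <- min_bin_count - length(members)
      while (deficit > 0L) {
        open <- members[mult[members] < max_copies]
        if (length(open) == 0L) break
        take <- min(deficit, length(open))
        pick <- open[sample.int(length(open), take, replace = TRUE)]
        add <- tabulate(match(pick, members), nbins = length(members))
        room <- max_copies - mult[members]
        add <- pmin(add, room)
        mult[members] <- mult[members] + add
        deficit <- min_bin_count - sum(mult[members])
      }
    }
  })
  mult
}

#' Fit the composition-dependent component of binding
#'
#' Ordinary least squares of log10 binding on the 16-element residue-count
#' vector plus an intercept, fitted independently per concentration. The
#' fitted component captures order-independent binding (net charge,
#' hydrophobicity and the like); subtracting it leaves the
#' sequence-specific residual for the network to model.
#'
#' @param sequences Character vector of peptides.
#' @param binding Numeric matrix of log10 binding, one column per
#'   concentration (a `binding_table`'s `log10_binding`).
#' @return A `composition_model`: 17 x n_conc coefficient matrix
#'   (intercept + one coefficient per amino acid) and per-concentration R^2.
#' @export
fit_composition <- function(sequences, binding) {
  if (is.null(dim(binding))) binding <- cbind(binding)
  stopifnot(length(sequences) == nrow(binding))
  if (is.null(colnames(binding))) {
    colnames(binding) <- sprintf("y%d", seq_len(ncol(binding)))
  }
  X <- cbind(`(Intercept)` = 1, composition_matrix(sequences))
  if (qr(X)$rank < ncol(X)) {
    warning("composition design is rank deficient; ",
            "using the minimum-norm least-squares solution")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    coef <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% binding) / sv$d[pos])
  } else {
    coef <- qr.solve(X, binding)
  }
  rownames(coef) <- colnames(X)
  fitted <- X %*% coef
  ss_res <- colSums((binding - fitted)^2)
  ss_tot <- colSums(sweep(binding, 2, colMeans(binding))^2)
  r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, NA_real_)
  colnames(coef) <- colnames(binding)
  structure(list(coefficients = coef, r_squared = r2),
            class = "composition_model")
}

#' Predict composition-dependent binding for sequences
#'
#' `intercept + sum(coef[aa] * count(aa))` per concentration, using the
#' coefficients learned on the training set.
#'
#' @param model A `composition_model`.
#' @param sequences Character vector of peptides.
#' @return Numeric matrix, one row per sequence, one column per
#'   concentration.
#' @export
predict_composition <- function(model, sequences) {
  stopifnot(inherits(model, "composition_model"))
  X <- cbind(`(Intercept)` = 1, composition_matrix(sequences))
  X %*% model$coefficients
}

#' Subtract / restore the composition component of a binding table
#'
#' `subtract_composition` replaces each cell by its residual from the
#' composition model prediction for that row; `add_composition` is the exact
#' inverse.
#'
#' @param model A `composition_model`.
#' @param bt A `binding_table`.
#' @return The transformed `binding_table`.
#' @export
subtract_composition <- function(model, bt) {
  stopifnot(inherits(bt, "binding_table"))
  pred <- predict_composition(model, bt$sequence)
  bt$log10_binding <- bt$log10_binding - pred
  attr(bt, "composition_subtracted") <- TRUE
  bt
}

#' @rdname subtract_composition
#' @export
add_composition <- function(model, bt) {
  stopifnot(inherits(bt, "binding_table"))
  pred <- predict_composition(model, bt$sequence)
  bt$log10_binding <- bt$log10_binding + pred
  attr(bt, "composition_subtracted") <- FALSE
  bt
}

#' Serialize / restore a composition model as JSON
#'
#' @param model A `composition_model`.
#' @param path File path.
#' @export
write_composition_model <- function(model, path) {
  stopifnot(inherits(model, "composition_model"))
  jsonlite::write_json(
    list(coefficients = as.data.frame(model$coefficients),
         terms = rownames(model$coefficients),
         r_squared = model$r_squared),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_composition_model
#' @export
read_composition_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  coef <- as.matrix(x$coefficients)
  rownames(coef) <- x$terms
  structure(list(coefficients = coef, r_squared = x$r_squared),
            class = "composition_model")
}

#' Write a weighting manifest for audit
#'
#' Records, per training pair, the multiplicity assigned by
#' [weight_expand()] together with the reference-concentration value the
#' binning used.
#'
#' @param bt The `binding_table` that was weighted.
#' @param multiplicities Integer vector from [weight_expand()].
#' @param path Output TSV path.
#' @param reference_concentration Concentration used for binning (default
#'   the highest assayed).
#' @export
write_weight_manifest <- function(bt, multiplicities, path,
                                  reference_concentration = NULL) {
  stopifnot(inherits(bt, "binding_table"),
            length(multiplicities) == length(bt$sequence))
  if (is.null(reference_concentration)) {
    reference_concentration <- max(bt$concentrations)
  }
  j <- match(reference_concentration, bt$concentrations)
  df <- data.frame(sequence = bt$sequence,
                   reference_log10 = bt$log10_binding[, j],
                   multiplicity = as.integer(multiplicities))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
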