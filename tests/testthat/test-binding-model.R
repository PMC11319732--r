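# small hidden layers where the architecture is not what is under test
tiny_cfg <- function(...) {
  args <- utils::modifyList(list(hidden = c(32L, 32L), epochs = 8L,
                                 minibatch = 64L), list(...))
  do.call(model_config, args)
}

tiny_table <- function(n = 300, seed = 1, sd = 0.4) {
  set.seed(seed)
  seqs <- unique(epibind:::random_peptides(sample(5:11, n, TRUE)))
  make_bt(seqs, matrix(rnorm(4 * length(seqs), 3, sd), ncol = 4))
}

test_that("a constant-target table is fitted to the constant", {
  bt <- tiny_table(n = 300, seed = 2, sd = 0)
  bt$log10_binding[] <- 2.9
  # Adam's per-step movement is ~learning_rate regardless of gradient
  # size, so convergence to a constant needs a traversable step budget
  # and an annealed rate to kill the late-phase jitter
  m <- train_binding_model(bt, tiny_cfg(hidden = c(128L, 128L),
                                        epochs = 300L,
                                        learning_rate = 5e-3,
                                        lr_decay = 0.98, minibatch = 16L,
                                        seed = 3L))
  pred <- predict(m, bt$sequence)
  expect_lt(max(abs(pred - 2.9)), 1e-2)
})

test_that("training is deterministic given the seed", {
  bt <- tiny_table()
  cfg <- model_config(epochs = 2L, seed = 11L)
  m1 <- train_binding_model(bt, cfg)
  m2 <- train_binding_model(bt, cfg)
  expect_identical(m1$weights, m2$weights)
  cfg2 <- cfg
  cfg2$seed <- 12L
  m3 <- train_binding_model(bt, cfg2)
  expect_false(identical(m1$weights, m3$weights))
})

test_that("prediction without shifting is the single-frame forward pass", {
  bt <- tiny_table(seed = 4)
  m <- train_binding_model(bt, tiny_cfg(epochs = 2L, seed = 5L))
  qs <- bt$sequence[1:20]
  tok <- encode_tokens(frame_peptide(qs)) - 1L
  w <- m$weights
  raw <- epibind:::mlp_forward_cpp(tok, w$W1, w$b1, w$W2, w$b2, w$W3, w$b3,
                                   19L)
  expect_equal(unname(predict(m, qs)), raw, tolerance = 1e-12)
})

test_that("shifted models predict the per-concentration frame maximum", {
  bt <- tiny_table(seed = 6)
  m <- train_binding_model(bt, tiny_cfg(epochs = 2L, shifting = TRUE,
                                        seed = 7L))
  qs <- bt$sequence[1:15]
  fr <- shift_frames(frame_peptide(qs))
  w <- m$weights
  per_frame <- lapply(1:6, function(k) {
    epibind:::mlp_forward_cpp(encode_tokens(fr[, k]) - 1L, w$W1, w$b1,
                              w$W2, w$b2, w$W3, w$b3, 19L)
  })
  expect_equal(unname(predict(m, qs)), Reduce(pmax, per_frame),
               tolerance = 1e-12)
  # per-sequence mode returns one frame's values, never above the frame max
  m$config$frame_max <- "per_sequence"
  p2 <- unname(predict(m, qs))
  expect_true(all(p2 <= Reduce(pmax, per_frame) + 1e-12))
  expect_equal(apply(p2, 1, max), apply(Reduce(pmax, per_frame), 1, max),
               tolerance = 1e-12)
})

test_that("ensemble prediction is exactly the mean of member predictions", {
  bt <- tiny_table(seed = 8)
  cfg <- tiny_cfg(epochs = 2L, seed = 20L)
  ens <- train_ensemble(bt, cfg, n_models = 3L)
  qs <- bt$sequence[1:10]
  member_mean <- Reduce(`+`, lapply(ens$models, predict, sequences = qs)) / 3
  expect_equal(predict(ens, qs), member_mean, tolerance = 1e-15)

  # n = 1 reduces to a single training run with the same seed
  ens1 <- train_ensemble(bt, cfg, n_models = 1L)
  m <- train_binding_model(bt, cfg)
  expect_identical(ens1$models[[1]]$weights, m$weights)
  expect_equal(ens1$seeds, cfg$seed)
})

test_that("composition-enabled models decompose exactly", {
  bt <- tiny_table(seed = 9)
  m <- train_binding_model(bt, tiny_cfg(epochs = 2L, composition = TRUE,
                                        seed = 21L))
  qs <- bt$sequence[1:10]
  total <- predict(m, qs)
  resid <- predict(m, qs, total = FALSE)
  expect_equal(total - resid,
               unname(predict_composition(m$composition_model, qs)),
               tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a noise-free landscape is learned to high fidelity", {
  la <- binding_landscape("PLEEVLN", rep(0.55, 7),
                          composition_coeffs = abundant_signal_landscape()
                          $composition_coeffs,
                          gain = 2, noise_sigma = 0, seed = 30)
  lib <- generate_library(library_spec(n_peptides = 30000, seed = 31))
  ds <- simulate_binding(la, lib)
  bt <- prepare_binding_table(ds, cognates = la$motif)
  hold <- seq_len(2000)
  bt_test <- epibind:::subset_binding_table(bt, hold)
  bt_train <- epibind:::subset_binding_table(bt, -hold)
  cfg <- model_config(weighting = TRUE, shifting = TRUE,
                      composition = TRUE, epochs = 30L, seed = 32L)
  m <- train_binding_model(bt_train, cfg)

  # training sequences: prediction ~ log10 mu
  p_train <- predict(m, bt_train$sequence)
  r_train <- cor(p_train[, 4], bt_train$log10_binding[, 4])
  expect_gt(r_train, 0.99)

  # held-out above-background probes
  motif_term <- epibind:::best_overlap_score_cpp(bt_test$sequence,
                                                 la$motif, la$match_energy)
  hi <- motif_term >= 1.5
  expect_gt(sum(hi), 10)
  p_test <- predict(m, bt_test$sequence[hi])
  r_test <- cor(p_test[, 4], bt_test$log10_binding[hi, 4])
  expect_gt(r_test, 0.95)
})

test_that("cross-validation keeps folds disjoint and detects signal", {
  la <- abundant_signal_landscape(seed = 40)
  lib <- generate_library(library_spec(n_peptides = 12000, seed = 41))
  bt <- prepare_binding_table(simulate_binding(la, lib),
                              cognates = la$motif)
  cfg <- model_config(hidden = c(128L, 128L), epochs = 12L,
                      weighting = TRUE, shifting = TRUE, seed = 42L)
  cv <- cross_validate(bt, cfg, k = 2L, seed = 43L)
  expect_equal(nrow(cv), 2 * 4)
  r8 <- cv$pearson_r[cv$concentration == 8]
  expect_true(all(r8 > 0.5))
  # predictability rises with concentration (more signal above background)
  rbar <- tapply(cv$pearson_r, cv$concentration, mean)
  expect_true(all(diff(rbar) > 0))

  # shuffled targets carry no learnable sequence signal
  cv0 <- cross_validate(shuffle_targets(bt, seed = 44), cfg, k = 2L,
                        seed = 43L)
  expect_lt(max(abs(cv0$pearson_r)), 0.2)
})

test_that("models and ensembles round-trip through serialization", {
  bt <- tiny_table(seed = 10)
  m <- train_binding_model(bt, tiny_cfg(epochs = 2L, composition = TRUE,
                                        seed = 50L))
  path <- tempfile(fileext = ".rds")
  save_binding_model(m, path)
  m2 <- load_binding_model(path)
  expect_identical(m2$weights, m$weights)
  expect_equal(predict(m2, bt$sequence[1:5]), predict(m, bt$sequence[1:5]))
  expect_true(file.exists(paste0(path, ".meta.json")))
})

test_that("prediction rejects residues outside the library alphabet", {
  bt <- tiny_table(seed = 12)
  m <- train_binding_model(bt, tiny_cfg(epochs = 2L, seed = 60L))
  expect_error(predict(m, "KLISEED"), "map_missing_aa")
  expect_silent(predict(m, map_missing_aa("KLISEED")))
})
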