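# shared small training fixture: strongly separable synthetic sequences
fixture_env <- new.env()
model_fixture <- function() {
  if (is.null(fixture_env$fx)) {
    ds <- generate_dataset(synth_spec(n = 60, length_range = c(40, 120),
                                      effect_size = 2, seed = 71))
    X <- encode_physchem(ds)
    sel <- sort(fscore_rank(X, ds$label)[1:40])
    embm <- train_skipgram(build_corpus(ds, 3), window = 2, dim = 12,
                           seed = 1, epochs = 2)
    H <- hybrid_features(X, sel, embed_dataset(ds, embm),
                         phys19_matrix(ds, reference = ds))
    scaler <- solupred:::fit_scaler(H)
    fixture_env$fx <- list(ds = ds, H = H,
                           Hs = solupred:::scale_features(H, scaler),
                           y = ds$label)
  }
  fixture_env$fx
}

test_that("stratified folds are balanced, disjoint, and seeded", {
  ds <- generate_dataset(synth_spec(n = 57, length_range = c(30, 60),
                                    seed = 51))
  folds <- split_10fold(ds, seed = 5)
  expect_length(folds, 114L)
  expect_setequal(unique(folds), 1:10)
  per_fold <- table(folds, ds$label)
  # per-fold class counts are within one of perfect proportionality
  expect_lte(diff(range(per_fold[, "1"])), 1L)
  expect_lte(diff(range(per_fold[, "0"])), 1L)
  expect_identical(split_10fold(ds, seed = 5), folds)
  expect_false(identical(split_10fold(ds, seed = 6), folds))
  # 20 samples, 10 per class: every fold gets exactly one of each
  ds20 <- generate_dataset(synth_spec(n = 10, length_range = c(30, 40),
                                      seed = 52))
  f20 <- split_10fold(ds20, seed = 1)
  expect_true(all(table(f20, ds20$label) == 1L))
  expect_error(split_10fold(ds20[1:8, ], seed = 1), "at least 10")
})

test_that("fold training learns separable data and honors early stopping", {
  fx <- model_fixture()
  folds <- split_10fold(fx$ds, seed = 2, k = 5)
  net <- network_config(lstm_units = 16, fc1_units = 16, fc2_units = 8,
                        learning_rate = 5e-3, max_epochs = 40, patience = 6,
                        batch_size = 16, seed = 3)
  fit <- train_fold(fx$Hs, fx$y, which(folds != 1), which(folds == 1), net)
  expect_lte(fit$epochs_run, net$max_epochs)
  expect_lte(fit$best_epoch, fit$epochs_run)
  expect_gt(fit$val_acc, 0.6)
  expect_identical(nrow(fit$history), fit$epochs_run)
  # fold-disjointness is enforced
  expect_error(train_fold(fx$Hs, fx$y, 1:50, 50:60, net), "overlap")
  expect_error(train_fold(fx$Hs, rep(1L, length(fx$y)), which(folds != 1),
                          which(folds == 1), net), "single-class")
  # deterministic retrain
  fit2 <- train_fold(fx$Hs, fx$y, which(folds != 1), which(folds == 1), net)
  expect_identical(fit$weights, fit2$weights)
})

test_that("random hyperparameter search logs trials and returns the argmax", {
  fx <- model_fixture()
  folds <- split_10fold(fx$ds, seed = 2)
  base <- network_config(max_epochs = 3, patience = 2, batch_size = 32,
                         seed = 5)
  tuned <- tune_hyperparams(fx$Hs, fx$y, which(folds != 1), which(folds == 1),
                            budget = 3, seed = 9, base = base,
                            units_grid = c(8L, 12L), fc_grid = c(6L, 8L))
  expect_identical(nrow(tuned$trials), 3L)
  expect_gte(max(tuned$trials$val_acc), median(tuned$trials$val_acc))
  best_row <- which.max(tuned$trials$val_acc)
  expect_identical(tuned$config$lstm_units, tuned$trials$lstm_units[best_row])
  one <- tune_hyperparams(fx$Hs, fx$y, which(folds != 1), which(folds == 1),
                          budget = 1, seed = 9, base = base,
                          units_grid = 8L, fc_grid = 6L)
  expect_identical(nrow(one$trials), 1L)
  expect_error(tune_hyperparams(fx$Hs, fx$y, 1:10, 11:20, budget = 0),
               "budget")
})

test_that("soft voting averages member probabilities and applies the threshold", {
  fx <- model_fixture()
  net <- network_config(lstm_units = 8, fc1_units = 8, fc2_units = 4,
                        learning_rate = 3e-3, max_epochs = 4, patience = 2,
                        batch_size = 32, seed = 1)
  ens <- train_ensemble(fx$ds, selection = "fscore", n_select = 40,
                        k = 3, window = 2, emb_dim = 12, emb_epochs = 2,
                        net = net, n_folds = 10, seed = 4)
  pr <- ensemble_predict(ens, fx$H)
  expect_equal(pr$probability, rowMeans(pr$members))  # brute-force mean
  expect_true(all(pr$probability >= apply(pr$members, 1, min) - 1e-12))
  expect_true(all(pr$probability <= apply(pr$members, 1, max) + 1e-12))
  expect_identical(pr$label, as.integer(pr$probability >= 0.4))
  expect_true(all(pr$members >= 0 & pr$members <= 1))
  # an ensemble of identical members predicts like any single member
  ens_same <- ens
  ens_same$members <- rep(ens$members[1], 3)
  pr_same <- ensemble_predict(ens_same, fx$H)
  expect_equal(pr_same$probability, pr_same$members[, 1])
  # a 0.5 mean probability clears the 0.4 threshold
  expect_identical(as.integer(0.5 >= ens$threshold), 1L)
  # schema mismatch is a clean error naming columns
  bad <- fx$H[, -3]
  expect_error(ensemble_predict(ens, bad), "schema mismatch")
  fixture_env$ens <- ens
})

test_that("permutation importance is zero for constants, top for the signal, and seeded", {
  fx <- model_fixture()
  ens <- fixture_env$ens
  X <- fx$H
  X[, "PHYS.length"] <- 300  # constant column
  imp <- permutation_importance(ens, X, fx$y, metric = "auc", r = 2,
                                seed = 6)
  expect_identical(imp$importance[imp$feature == "PHYS.length"], 0)
  imp2 <- permutation_importance(ens, X, fx$y, metric = "auc", r = 2,
                                 seed = 6)
  expect_identical(imp$importance, imp2$importance)
  # compositional families carry the planted signal
  top <- imp$family[seq_len(10)]
  expect_gt(sum(top %in% c("AAC", "CTDC", "APAAC", "PHYS19", "QSOrder")), 0)
})

test_that("model bundles survive the save/load round trip", {
  fx <- model_fixture()
  ens <- fixture_env$ens
  dir <- file.path(tempdir(), "bundle_test")
  save_model_bundle(ens, dir)
  back <- load_model_bundle(dir)
  expect_identical(back$schema, ens$schema)
  expect_equal(back$threshold, ens$threshold)
  expect_equal(back$selected, ens$selected)
  pr1 <- ensemble_predict(ens, fx$H)
  pr2 <- ensemble_predict(back, fx$H)
  expect_equal(pr1$probability, pr2$probability, tolerance = 1e-12)
  pred <- predict_solubility(back, fx$ds)
  expect_identical(names(pred), c("id", "probability", "label"))
  expect_identical(pred$id, fx$ds$id)
})
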