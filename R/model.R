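#' LSTM network configuration
#'
#' Architecture: the hybrid feature vector is unrolled as one timestep per
#' feature (length-1 input at each step) into a single LSTM layer, then
#' two ReLU fully connected layers, dropout, and a 2-class softmax.
#' Training uses Adam on categorical cross-entropy with early stopping on
#' validation loss (best-epoch weights restored).
#'
#' @param lstm_units LSTM hidden units.
#' @param fc1_units,fc2_units Units of the two ReLU layers.
#' @param dropout_rate Dropout before the output layer, in `[0, 1)`.
#' @param learning_rate Adam learning rate.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param batch_size Minibatch size.
#' @param seed Integer seed (weight init, shuffling, dropout).
#' @return A `network_config` list.
#' @export
network_config <- function(lstm_units = 32L, fc1_units = 32L,
                           fc2_units = 16L, dropout_rate = 0.3,
                           learning_rate = 1e-3, max_epochs = 200L,
                           patience = 10L, batch_size = 64L, seed = 1L) {
  stopifnot(lstm_units >= 1L, fc1_units >= 1L, fc2_units >= 1L,
            dropout_rate >= 0, dropout_rate < 1, learning_rate > 0,
            max_epochs >= 1L, patience >= 1L, batch_size >= 1L)
  structure(list(lstm_units = as.integer(lstm_units),
                 fc1_units = as.integer(fc1_units),
                 fc2_units = as.integer(fc2_units),
                 dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Stratified k-fold split
#'
#' @param dataset A labeled [solu_dataset()] (or any 0/1 vector via
#'   `labels`).
#' @param seed Integer seed.
#' @param k Number of folds (default 10).
#' @return Integer fold assignment (1..k) per record; per-fold class
#'   counts differ from perfect proportionality by at most one sample.
#' @export
split_10fold <- function(dataset, seed = 1L, k = 10L) {
  y <- if (inherits(dataset, "solu_dataset")) dataset$label else dataset
  if (anyNA(y)) stop("all records must be labeled")
  if (length(y) < k) stop("need at least ", k, " samples for ", k, " folds")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  stratified_folds(y, k, seed)
}

#' Train one fold model
#'
#' @param X Hybrid feature matrix (samples x features), already scaled.
#' @param y 0/1 labels.
#' @param train_idx,val_idx Disjoint row index vectors.
#' @param net A [network_config()].
#' @return A `solu_fold_model`: weights, train/validation accuracy, best
#'   epoch and the per-epoch history.
#' @export
train_fold <- function(X, y, train_idx, val_idx, net = network_config()) {
  if (length(intersect(train_idx, val_idx)))
    stop("training and validation folds overlap")
  if (length(unique(y[train_idx])) < 2L) stop("single-class training fold")
  fit <- slp_lstm_train(X[train_idx, , drop = FALSE],
                        as.integer(y[train_idx]),
                        X[val_idx, , drop = FALSE],
                        as.integer(y[val_idx]),
                        net$lstm_units, net$fc1_units, net$fc2_units,
                        net$dropout_rate, net$learning_rate,
                        net$max_epochs, net$patience, net$batch_size,
                        net$seed)
  structure(c(fit, list(net = net)), class = "solu_fold_model")
}

#' Soluble-class probabilities of one fold model
#'
#' @param object A `solu_fold_model`.
#' @param newdata Scaled hybrid feature matrix.
#' @param ... Unused.
#' @return Numeric vector of P(soluble).
#' @export
predict.solu_fold_model <- function(object, newdata, ...) {
  slp_lstm_predict(newdata, object$weights)[, 2L]
}

#' Random search over the four tuned hyperparameters
#'
#' Samples LSTM units, the two fully connected widths, and the learning
#' rate (log-uniform), trains each candidate on one train/validation
#' split, and returns the configuration with the best validation
#' accuracy plus the full trial log.
#'
#' @param X,y,train_idx,val_idx As in [train_fold()].
#' @param budget Number of sampled configurations (>= 1).
#' @param seed Integer seed.
#' @param base A [network_config()] supplying the non-tuned fields.
#' @param units_grid,fc_grid,lr_range Search space.
#' @return List with `config` (best [network_config()]) and `trials`
#'   (data frame with one row per trial).
#' @export
tune_hyperparams <- function(X, y, train_idx, val_idx, budget = 10L,
                             seed = 1L, base = network_config(),
                             units_grid = c(32L, 64L, 128L),
                             fc_grid = c(16L, 32L, 64L),
                             lr_range = c(1e-4, 1e-2)) {
  if (budget < 1L) stop("budget must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draws <- data.frame(
    lstm_units = sample(units_grid, budget, replace = TRUE),
    fc1_units = sample(fc_grid, budget, replace = TRUE),
    fc2_units = sample(fc_grid, budget, replace = TRUE),
    learning_rate = exp(runif(budget, log(lr_range[1]), log(lr_range[2]))))
  draws$val_acc <- NA_real_
  configs <- vector("list", budget)
  for (i in seq_len(budget)) {
    cfg <- base
    cfg$lstm_units <- draws$lstm_units[i]
    cfg$fc1_units <- draws$fc1_units[i]
    cfg$fc2_units <- draws$fc2_units[i]
    cfg$learning_rate <- draws$learning_rate[i]
    fit <- train_fold(X, y, train_idx, val_idx, cfg)
    draws$val_acc[i] <- fit$val_acc
    configs[[i]] <- cfg
  }
  list(config = configs[[which.max(draws$val_acc)]], trials = draws)
}

#' Soft-voting ensemble prediction
#'
#' The ensemble probability is the mean of the member models'
#' soluble-class probabilities; the label is soluble when the probability
#' is at least the stored decision threshold (default 0.4).
#'
#' @param ens A `solu_ensemble` (see [train_ensemble()]).
#' @param X Hybrid feature matrix with the ensemble's column schema
#'   (unscaled; the stored scaler is applied), or a matrix already
#'   prepared with `scaled = TRUE`.
#' @param scaled Set if `X` is already standardized.
#' @return List with `probability` and `label` vectors and the per-member
#'   probability matrix `members`.
#' @export
ensemble_predict <- function(ens, X, scaled = FALSE) {
  stopifnot(inherits(ens, "solu_ensemble"))
  if (!identical(colnames(X), ens$schema)) {
    missing_ <- setdiff(ens$schema, colnames(X))
    extra <- setdiff(colnames(X), ens$schema)
    stop("feature schema mismatch; missing: ",
         paste(head(missing_, 5), collapse = ", "),
         if (length(extra)) paste0("; extra: ",
                                   paste(head(extra, 5), collapse = ", ")))
  }
  if (!scaled) X <- scale_features(X, ens$scaler)
  probs <- vapply(ens$members, predict, numeric(nrow(X)), newdata = X)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  p <- rowMeans(probs)
  list(probability = p, label = as.integer(p >= ens$threshold),
       members = probs)
}

#' Permutation feature importance
#'
#' Metric drop when each feature column is shuffled, averaged over `r`
#' repeats; positive values mean the model relies on the feature.
#'
#' @param ens A `solu_ensemble`.
#' @param X Unscaled hybrid feature matrix (ensemble schema).
#' @param y 0/1 labels.
#' @param metric `"auc"` or `"acc"`.
#' @param r Permutation repeats per feature.
#' @param seed Integer seed.
#' @return Data frame (feature, family, importance) sorted by descending
#'   importance.
#' @export
permutation_importance <- function(ens, X, y, metric = c("auc", "acc"),
                                   r = 5L, seed = 1L) {
  metric <- match.arg(metric)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  score <- function(M) {
    pr <- ensemble_predict(ens, M)
    if (metric == "auc") roc_auc(pr$probability, y)$auc
    else mean(pr$label == y)
  }
  base <- score(X)
  imp <- vapply(seq_len(ncol(X)), function(j) {
    drops <- vapply(seq_len(r), function(.) {
      Xp <- X
      Xp[, j] <- Xp[sample.int(nrow(X)), j]
      base - score(Xp)
    }, 0)
    mean(drops)
  }, 0)
  fam <- feature_families(X)
  out <- data.frame(feature = colnames(X),
                    family = if (is.null(fam)) NA_character_ else
                      unname(fam[colnames(X)]),
                    importance = imp, stringsAsFactors = FALSE)
  out[order(-out$importance), ]
}
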