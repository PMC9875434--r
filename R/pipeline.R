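## End-to-end orchestration: featurize -> select -> embed -> train ->
## predict, with a persistable ensemble bundle.

fit_scaler <- function(X) {
  ctr <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s < 1e-12] <- 1
  list(center = ctr, scale = s)
}

scale_features <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}

#' Assemble the hybrid feature matrix
#'
#' Fixed layout: the selected physicochemical descriptor columns, then
#' the embedding columns, then the 19 global features. With the default
#' 100-feature selection and a 100-dimensional embedding the hybrid
#' vector has width 219.
#'
#' @param physchem [encode_physchem()] matrix.
#' @param selected Integer indices of the selected physicochemical
#'   columns.
#' @param emb [embed_dataset()] matrix.
#' @param p19 [phys19_matrix()] matrix.
#' @return Numeric matrix with a `families` attribute.
#' @export
hybrid_features <- function(physchem, selected, emb, p19) {
  stopifnot(nrow(physchem) == nrow(emb), nrow(emb) == nrow(p19))
  H <- cbind(physchem[, selected, drop = FALSE], emb, p19)
  fam <- c(feature_families(physchem)[selected],
           feature_families(emb), feature_families(p19))
  attr(H, "families") <- setNames(unname(fam), colnames(H))
  stopifnot(!anyNA(H), all(is.finite(H)))
  H
}

#' Train the soft-voting LSTM ensemble on a labeled dataset
#'
#' Full training pipeline: five-family physicochemical encoding,
#' descriptor-subset selection (genetic algorithm, F-score ranking, or a
#' caller-supplied index set), skip-gram embedding trained on these
#' sequences only, the 19 global features, z-score standardization, a
#' stratified k-fold split, and one LSTM per fold with the held-out fold
#' as its validation set. Member probabilities are soft-voted at the
#' stored threshold.
#'
#' @param dataset A labeled [solu_dataset()].
#' @param spec A [descriptor_spec()].
#' @param selection `"ga"`, `"fscore"`, or an integer vector of
#'   physicochemical column indices.
#' @param n_select Number of descriptor columns to keep.
#' @param k,window,emb_dim,emb_epochs Embedding settings.
#' @param net A [network_config()].
#' @param ga_cfg A [ga_config()] (used when `selection = "ga"`).
#' @param threshold Ensemble decision threshold (default 0.4).
#' @param n_folds Fold count (default 10).
#' @param seed Master seed: folds, selection and per-member training
#'   seeds derive from it.
#' @param tm_table,identity_table Optional precomputed feature tables
#'   (see [phys19_matrix()]).
#' @return A `solu_ensemble` with members, scaler, schema, embedding
#'   model, selected indices, per-fold report and identity reference.
#' @export
train_ensemble <- function(dataset, spec = descriptor_spec(),
                           selection = "fscore", n_select = 100L,
                           k = 3L, window = 2L, emb_dim = 100L,
                           emb_epochs = 10L, net = network_config(),
                           ga_cfg = NULL, threshold = 0.4, n_folds = 10L,
                           seed = 1L, tm_table = NULL,
                           identity_table = NULL) {
  if (anyNA(dataset$label)) stop("training dataset must be fully labeled")
  y <- dataset$label
  physchem <- encode_physchem(dataset, spec)

  if (is.numeric(selection)) {
    selected <- as.integer(selection)
  } else if (identical(selection, "ga")) {
    if (is.null(ga_cfg))
      ga_cfg <- ga_config(chrom_len = n_select, seed = seed)
    pop <- init_population(ga_cfg, ncol(physchem))
    selected <- ga_evolve(pop, physchem, y, ga_cfg)$best
  } else if (identical(selection, "fscore")) {
    selected <- sort(fscore_rank(physchem, y)[seq_len(n_select)])
  } else stop("unknown selection method")

  corpus <- build_corpus(dataset, k)
  embm <- train_skipgram(corpus, window = window, dim = emb_dim,
                         seed = seed, epochs = emb_epochs)
  emb <- embed_dataset(dataset, embm)
  p19 <- phys19_matrix(dataset, tm_table = tm_table,
                       identity_table = identity_table,
                       reference = dataset)
  H <- hybrid_features(physchem, selected, emb, p19)
  scaler <- fit_scaler(H)
  Hs <- scale_features(H, scaler)

  folds <- split_10fold(dataset, seed = seed, k = n_folds)
  members <- vector("list", n_folds)
  report <- data.frame(model = seq_len(n_folds), train_acc = NA_real_,
                       val_acc = NA_real_, best_epoch = NA_integer_)
  for (f in seq_len(n_folds)) {
    cfg <- net
    cfg$seed <- net$seed + f
    fit <- train_fold(Hs, y, which(folds != f), which(folds == f), cfg)
    members[[f]] <- fit
    report$train_acc[f] <- fit$train_acc
    report$val_acc[f] <- fit$val_acc
    report$best_epoch[f] <- fit$best_epoch
  }

  ref_cap <- 500L
  ref_idx <- unique(as.integer(seq(1L, nrow(dataset),
                                   length.out = min(ref_cap, nrow(dataset)))))
  structure(list(members = members, threshold = threshold,
                 schema = colnames(H), scaler = scaler,
                 families = feature_families(H),
                 embedding = embm, selected = selected, spec = spec,
                 net = net, n_folds = as.integer(n_folds),
                 seed = as.integer(seed), fold_report = report,
                 reference = dataset[ref_idx, c("id", "sequence")]),
            class = "solu_ensemble")
}

#' @export
print.solu_ensemble <- function(x, ...) {
  cat(sprintf("<solu_ensemble> %d LSTM fold models, %d features, threshold %.2f\n",
              length(x$members), length(x$schema), x$threshold))
  cat(sprintf("  mean train ACC %.4f, mean validation ACC %.4f\n",
              mean(x$fold_report$train_acc), mean(x$fold_report$val_acc)))
  invisible(x)
}

#' Featurize a dataset with an ensemble's frozen encoders
#'
#' @param ens A `solu_ensemble`.
#' @param dataset A [solu_dataset()].
#' @param tm_table,identity_table Optional precomputed tables.
#' @return Unscaled hybrid feature matrix in the ensemble's schema.
#' @export
featurize_for <- function(ens, dataset, tm_table = NULL,
                          identity_table = NULL) {
  physchem <- encode_physchem(dataset, ens$spec)
  emb <- embed_dataset(dataset, ens$embedding)
  ref <- solu_dataset(ens$reference$id, ens$reference$sequence)
  p19 <- phys19_matrix(dataset, tm_table = tm_table,
                       identity_table = identity_table, reference = ref)
  hybrid_features(physchem, ens$selected, emb, p19)
}

#' Predict solubility for new sequences
#'
#' @param ens A trained `solu_ensemble`.
#' @param dataset A [solu_dataset()] (labels, if any, are ignored).
#' @param ... Passed to [featurize_for()].
#' @return Data frame (id, probability, label).
#' @export
predict_solubility <- function(ens, dataset, ...) {
  H <- featurize_for(ens, dataset, ...)
  pr <- ensemble_predict(ens, H)
  data.frame(id = dataset$id, probability = pr$probability,
             label = pr$label, stringsAsFactors = FALSE)
}

#' Write predictions as TSV
#'
#' Probabilities are printed with six fixed decimals so identical runs
#' produce byte-identical files.
#'
#' @param pred [predict_solubility()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  out <- data.frame(id = pred$id,
                    probability = sprintf("%.6f", pred$probability),
                    label = pred$label)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save / load an ensemble bundle
#'
#' The bundle directory holds JSON metadata (threshold, seeds, schema,
#' selected indices, scaler, fold report), the member weights, and the
#' embedding model as text.
#'
#' @param ens A `solu_ensemble`.
#' @param dir Bundle directory (created if needed).
#' @return `dir` invisibly (`save`); the ensemble (`load`).
#' @export
save_model_bundle <- function(ens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "solu_ensemble/1", threshold = ens$threshold,
               schema = ens$schema, families = as.list(ens$families),
               selected = ens$selected,
               spec = unclass(ens$spec), net = unclass(ens$net),
               n_folds = ens$n_folds, seed = ens$seed,
               scaler = ens$scaler, fold_report = ens$fold_report,
               reference = ens$reference)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  flat <- function(m) {
    m <- as.matrix(m)
    list(nrow = nrow(m), ncol = ncol(m), data = as.vector(m))
  }
  jsonlite::write_json(lapply(ens$members, function(m)
    list(weights = lapply(m$weights, flat), train_acc = m$train_acc,
         val_acc = m$val_acc, best_epoch = m$best_epoch)),
    file.path(dir, "members.json"), digits = NA, auto_unbox = TRUE)
  save_embedding(ens$embedding, file.path(dir, "embedding"))
  invisible(dir)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  members_raw <- jsonlite::read_json(file.path(dir, "members.json"),
                                     simplifyVector = FALSE)
  as_net <- function(l) do.call(network_config, l[names(formals(network_config))])
  members <- lapply(members_raw, function(m) {
    w <- lapply(m$weights, function(x)
      matrix(unlist(x$data), x$nrow, x$ncol))
    structure(list(weights = w, train_acc = m$train_acc,
                   val_acc = m$val_acc, best_epoch = m$best_epoch),
              class = "solu_fold_model")
  })
  spec <- do.call(descriptor_spec,
                  meta$spec[c("apaac_lambda", "apaac_weight",
                              "qso_nlag", "qso_weight")])
  structure(list(members = members, threshold = meta$threshold,
                 schema = meta$schema,
                 scaler = list(center = setNames(meta$scaler$center, meta$schema),
                               scale = setNames(meta$scaler$scale, meta$schema)),
                 families = unlist(meta$families),
                 embedding = load_embedding(file.path(dir, "embedding")),
                 selected = meta$selected, spec = spec,
                 net = as_net(meta$net), n_folds = meta$n_folds,
                 seed = meta$seed, fold_report = meta$fold_report,
                 reference = meta$reference),
            class = "solu_ensemble")
}
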