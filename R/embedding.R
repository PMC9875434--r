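#' Build an overlapping k-mer corpus
#'
#' Each sequence becomes one "sentence": its `n - k + 1` overlapping
#' k-mers at stride 1, in order.
#'
#' @param dataset A [solu_dataset()].
#' @param k k-mer length (2-6, the meaningful range for protein k-mers).
#' @return A `kmer_corpus` list with `sentences` (list of character
#'   vectors, named by record id), `k`, and `vocabulary` (sorted unique
#'   k-mers).
#' @export
build_corpus <- function(dataset, k = 3L) {
  k <- as.integer(k)
  if (k < 2L || k > 6L) stop("k must be in 2..6")
  short <- nchar(dataset$sequence) < k
  if (any(short))
    stop("sequence(s) shorter than k=", k, ": ",
         paste(head(dataset$id[short], 5), collapse = ", "))
  sentences <- lapply(dataset$sequence, function(s) {
    starts <- seq_len(nchar(s) - k + 1L)
    substring(s, starts, starts + k - 1L)
  })
  names(sentences) <- dataset$id
  out <- list(sentences = sentences, k = k,
              vocabulary = sort(unique(unlist(sentences, use.names = FALSE))))
  class(out) <- "kmer_corpus"
  out
}

#' Train a skip-gram k-mer embedding
#'
#' Skip-gram with negative sampling over the k-mer corpus, implemented in
#' compiled code: every observed k-mer is kept (min-count 1; protein
#' k-mer vocabularies are small), negative samples are drawn from the
#' unigram distribution raised to 0.75, and the learning rate decays
#' linearly. Training is seeded and single-threaded, so identical inputs
#' give bit-identical vectors.
#'
#' @param corpus A [build_corpus()] result.
#' @param window Context window size `w` (1-7).
#' @param dim Embedding dimension (default 100).
#' @param seed Integer seed.
#' @param epochs Training epochs (default 10).
#' @param negative Negative samples per positive pair (default 5).
#' @param alpha Initial learning rate.
#' @return A `solu_embedding` list: `vectors` (vocabulary x dim matrix,
#'   rownames the k-mers), `k`, `window`, `dim`, `seed`.
#' @export
train_skipgram <- function(corpus, window = 2L, dim = 100L, seed = 1L,
                           epochs = 10L, negative = 5L, alpha = 0.025) {
  stopifnot(inherits(corpus, "kmer_corpus"))
  if (window < 1L || window > 7L) stop("window must be in 1..7")
  if (!length(corpus$vocabulary)) stop("empty vocabulary")
  sent_idx <- lapply(corpus$sentences, function(s)
    match(s, corpus$vocabulary) - 1L)
  vec <- slp_skipgram_train(sent_idx, length(corpus$vocabulary),
                            as.integer(dim), as.integer(window),
                            as.integer(epochs), as.integer(negative),
                            alpha, as.integer(seed))
  rownames(vec) <- corpus$vocabulary
  colnames(vec) <- paste0("EMB.", seq_len(dim))
  out <- list(vectors = vec, k = corpus$k, window = as.integer(window),
              dim = as.integer(dim), seed = as.integer(seed))
  class(out) <- "solu_embedding"
  out
}

#' @export
print.solu_embedding <- function(x, ...) {
  cat(sprintf("<solu_embedding> %d k-mers (k=%d) -> %dD, window %d, seed %d\n",
              nrow(x$vectors), x$k, x$dim, x$window, x$seed))
  invisible(x)
}

#' Embed one sequence as the mean of its k-mer vectors
#'
#' k-mers absent from the training vocabulary are skipped and the mean is
#' taken over the known ones (skip-and-renormalize); if every k-mer is
#' out-of-vocabulary the zero vector is returned with a warning.
#'
#' @param seq Cleaned amino-acid sequence with `nchar(seq) >= k`.
#' @param model A [train_skipgram()] model.
#' @return Numeric vector of length `model$dim`.
#' @export
embed_sequence <- function(seq, model) {
  stopifnot(inherits(model, "solu_embedding"))
  n <- nchar(seq)
  if (n < model$k) stop("sequence shorter than k=", model$k)
  starts <- seq_len(n - model$k + 1L)
  kmers <- substring(seq, starts, starts + model$k - 1L)
  idx <- match(kmers, rownames(model$vectors))
  idx <- idx[!is.na(idx)]
  if (!length(idx)) {
    warning("all k-mers out of vocabulary; returning zero vector")
    return(setNames(numeric(model$dim), colnames(model$vectors)))
  }
  colMeans(model$vectors[idx, , drop = FALSE])
}

#' Embed every sequence of a dataset
#'
#' @param dataset A [solu_dataset()].
#' @param model A [train_skipgram()] model.
#' @return Numeric matrix (records x dim) with a `families` attribute
#'   (`"EMB"`).
#' @export
embed_dataset <- function(dataset, model) {
  m <- t(vapply(dataset$sequence, embed_sequence, numeric(model$dim),
                model = model, USE.NAMES = FALSE))
  rownames(m) <- dataset$id
  attr(m, "families") <- setNames(rep("EMB", ncol(m)), colnames(m))
  m
}

#' Grid search over k-mer length and context window
#'
#' Trains one embedding per `(k, w)` pair, embeds the dataset, and scores
#' it with `eval_fn` (any function mapping an embedded matrix and labels
#' to an accuracy-like number, e.g. a cross-validated downstream
#' classifier). Returns the full score table and the argmax pair.
#'
#' @param dataset A labeled [solu_dataset()].
#' @param k_range Candidate k-mer lengths (supported range 2:6).
#' @param w_range Candidate windows (1:7).
#' @param eval_fn `function(X, y) -> numeric(1)`.
#' @param dim,seed,epochs Passed to [train_skipgram()].
#' @return List with `best_k`, `best_w`, and `table`
#'   (`k`, `w`, `score`; one row per grid cell).
#' @export
grid_search_kw <- function(dataset, k_range = 2:6, w_range = 1:7, eval_fn,
                           dim = 100L, seed = 1L, epochs = 10L) {
  y <- dataset$label
  if (anyNA(y)) stop("grid search needs a fully labeled dataset")
  grid <- expand.grid(k = k_range, w = w_range)
  score <- vapply(seq_len(nrow(grid)), function(i) {
    corp <- build_corpus(dataset, grid$k[i])
    mod <- train_skipgram(corp, window = grid$w[i], dim = dim, seed = seed,
                          epochs = epochs)
    eval_fn(embed_dataset(dataset, mod), y)
  }, 0)
  grid$score <- score
  best <- which.max(score)
  list(best_k = grid$k[best], best_w = grid$w[best], table = grid)
}

#' Save / load an embedding model as versioned text
#'
#' The model is written as a JSON metadata header file plus a TSV of
#' per-k-mer vectors.
#'
#' @param model A `solu_embedding`.
#' @param path Base path; writes `<path>.json` and `<path>.tsv`.
#' @return `path` invisibly (`save`); the model (`load`).
#' @export
save_embedding <- function(model, path) {
  jsonlite::write_json(list(format = "solu_embedding/1",
                            k = model$k, window = model$window,
                            dim = model$dim, seed = model$seed),
                       paste0(path, ".json"), auto_unbox = TRUE)
  tab <- data.frame(kmer = rownames(model$vectors), model$vectors,
                    check.names = FALSE)
  write.table(tab, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname save_embedding
#' @export
load_embedding <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  tab <- read.delim(paste0(path, ".tsv"), check.names = FALSE)
  vec <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(vec) <- tab[[1L]]
  out <- list(vectors = vec, k = meta$k, window = meta$window,
              dim = meta$dim, seed = meta$seed)
  class(out) <- "solu_embedding"
  out
}
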