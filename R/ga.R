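## Genetic-algorithm wrapper feature selection on the physicochemical
## feature matrix, plus the F-score ranking + sequential-forward-search
## baseline.

#' GA configuration
#'
#' Defaults follow the published protocol: 200 chromosomes of 100 genes,
#' 500 generations, per-individual mutation probability 0.0003. Tournament
#' size 3 and single-chromosome elitism are this package's choices (the
#' protocol leaves them open); elitism makes best fitness monotone.
#'
#' @param pop_size Number of chromosomes.
#' @param chrom_len Genes (selected features) per chromosome.
#' @param generations Number of generations.
#' @param mutation_prob Per-individual mutation probability; when an
#'   individual mutates, one random gene is replaced by a random unused
#'   feature index. Set `per_gene_mutation = TRUE` to apply the
#'   probability per gene instead.
#' @param tournament_size Tournament size for parent selection.
#' @param elitism Chromosomes copied unchanged into the next generation.
#' @param fitness_cv_folds Cross-validation folds inside the fitness
#'   function.
#' @param classifier Base fitness classifier: `"svm"` (linear SVM),
#'   `"dlda"` (diagonal linear discriminant, fast closed form), `"lda"`,
#'   `"logistic"`, or a `function(Xtr, ytr, Xte) -> scores`.
#' @param per_gene_mutation See `mutation_prob`.
#' @param seed Integer seed for the whole run.
#' @return A `ga_config` list.
#' @export
ga_config <- function(pop_size = 200L, chrom_len = 100L, generations = 500L,
                      mutation_prob = 0.0003, tournament_size = 3L,
                      elitism = 1L, fitness_cv_folds = 5L,
                      classifier = "svm", per_gene_mutation = FALSE,
                      seed = 1L) {
  stopifnot(pop_size > 1L, chrom_len >= 1L, generations >= 1L,
            mutation_prob >= 0, mutation_prob <= 1, tournament_size >= 1L,
            fitness_cv_folds >= 2L, elitism >= 0L)
  out <- list(pop_size = as.integer(pop_size),
              chrom_len = as.integer(chrom_len),
              generations = as.integer(generations),
              mutation_prob = mutation_prob,
              tournament_size = as.integer(tournament_size),
              elitism = as.integer(elitism),
              fitness_cv_folds = as.integer(fitness_cv_folds),
              classifier = classifier,
              per_gene_mutation = isTRUE(per_gene_mutation),
              seed = as.integer(seed))
  class(out) <- "ga_config"
  out
}

# stratified fold assignment, reproducible from seed
stratified_folds <- function(y, k, seed) {
  if (length(unique(y)) < 2L) stop("both classes must be present")
  fold <- integer(length(y))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (cl in sort(unique(y))) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# base classifiers: function(Xtr, ytr, Xte) -> numeric scores for class 1
fitness_classifier <- function(classifier) {
  if (is.function(classifier)) return(classifier)
  switch(classifier,
    dlda = function(Xtr, ytr, Xte) {
      m1 <- colMeans(Xtr[ytr == 1L, , drop = FALSE])
      m0 <- colMeans(Xtr[ytr == 0L, , drop = FALSE])
      v <- (colSums(sweep(Xtr[ytr == 1L, , drop = FALSE], 2, m1)^2) +
            colSums(sweep(Xtr[ytr == 0L, , drop = FALSE], 2, m0)^2)) /
        (nrow(Xtr) - 2L)
      v[v < 1e-12] <- 1e-12
      w <- (m1 - m0) / v
      drop(Xte %*% w) - sum(w * (m1 + m0) / 2)
    },
    lda = function(Xtr, ytr, Xte) {
      fit <- suppressWarnings(MASS::lda(Xtr, grouping = factor(ytr)))
      predict(fit, Xte)$posterior[, "1"]
    },
    svm = function(Xtr, ytr, Xte) {
      fit <- e1071::svm(Xtr, factor(ytr), kernel = "linear", scale = FALSE)
      # libsvm's decision-value sign depends on training order; orient it
      # so that larger values mean class 1
      dv_tr <- drop(attr(predict(fit, Xtr, decision.values = TRUE),
                         "decision.values"))
      flip <- mean(dv_tr[ytr == 1L]) < mean(dv_tr[ytr == 0L])
      dv <- drop(attr(predict(fit, Xte, decision.values = TRUE),
                      "decision.values"))
      if (flip) -dv else dv
    },
    logistic = function(Xtr, ytr, Xte) {
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, Xtr), ytr, family = stats::binomial()))
      drop(cbind(1, Xte) %*% fit$coefficients)
    },
    stop("unknown fitness classifier: ", classifier))
}

# cross-validated accuracy (+AUC attribute) of the base classifier on the
# selected columns
cv_score <- function(X, y, folds, clf) {
  scores <- numeric(length(y))
  for (f in sort(unique(folds))) {
    te <- folds == f
    scores[te] <- clf(X[!te, , drop = FALSE], y[!te], X[te, , drop = FALSE])
  }
  # probability-like scores threshold at 0.5, margin/logit scores at 0
  cut <- if (min(scores) >= 0 && max(scores) <= 1) 0.5 else 0
  pred <- as.integer(scores >= cut)
  acc <- mean(pred == y)
  attr(acc, "auc") <- roc_auc(scores, y)$auc
  acc
}

#' GA fitness of a feature subset
#'
#' Cross-validated classification accuracy of the base classifier on the
#' chromosome's columns; the fold AUC is attached as attribute `"auc"`
#' (used to pick the final subset across generations).
#'
#' @param chrom Integer vector of feature (column) indices.
#' @param X Feature matrix.
#' @param y 0/1 labels.
#' @param config A [ga_config()].
#' @param folds Optional precomputed fold assignment (defaults to
#'   stratified folds from `config$seed`).
#' @return Numeric accuracy with attribute `auc`.
#' @export
ga_fitness <- function(chrom, X, y, config = ga_config(), folds = NULL) {
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (max(chrom) > ncol(X) || min(chrom) < 1L)
    stop("chromosome indices outside feature matrix")
  if (is.null(folds))
    folds <- stratified_folds(y, config$fitness_cv_folds, config$seed)
  cv_score(X[, chrom, drop = FALSE], y, folds,
           fitness_classifier(config$classifier))
}

#' Initialize a GA population
#'
#' @param config A [ga_config()].
#' @param n_features Number of available feature columns.
#' @param seed Seed (defaults to `config$seed`).
#' @return A `ga_population` list: `members` (list of integer gene
#'   vectors), `generation = 0`.
#' @export
init_population <- function(config, n_features, seed = config$seed) {
  if (config$chrom_len > n_features)
    stop("chromosome length exceeds number of features")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  members <- replicate(config$pop_size,
                       sample.int(n_features, config$chrom_len),
                       simplify = FALSE)
  structure(list(members = members, generation = 0L,
                 n_features = as.integer(n_features)),
            class = "ga_population")
}

valid_chromosome <- function(genes, chrom_len, n_features) {
  length(genes) == chrom_len && !anyDuplicated(genes) &&
    all(genes >= 1L & genes <= n_features)
}

two_point_crossover <- function(p1, p2) {
  len <- length(p1)
  cut <- sort(sample.int(len, 2L))
  mid <- (cut[1] + 1L):cut[2]
  c1 <- p1; c1[mid] <- p2[mid]
  c2 <- p2; c2[mid] <- p1[mid]
  list(c1, c2)
}

repair_duplicates <- function(genes, n_features) {
  dup <- duplicated(genes)
  if (!any(dup)) return(genes)
  pool <- setdiff(seq_len(n_features), genes[!dup])
  genes[dup] <- sample(pool, sum(dup))
  genes
}

#' Evolve a population and return the best feature subset
#'
#' Runs tournament selection, two-point crossover (with duplicate-gene
#' repair), and mutation for `config$generations` generations, evaluating
#' every chromosome with [ga_fitness()]. The returned subset is the best
#' chromosome of the generation with the highest recorded AUC; the full
#' per-generation history is included.
#'
#' @param pop A [init_population()] result.
#' @param X Feature matrix.
#' @param y 0/1 labels.
#' @param config A [ga_config()].
#' @return List with `best` (integer gene vector), `best_fitness`,
#'   `best_auc`, `best_generation`, and `history` (data frame:
#'   generation, best_fitness, best_auc, genes).
#' @export
ga_evolve <- function(pop, X, y, config = ga_config()) {
  stopifnot(inherits(pop, "ga_population"))
  nf <- pop$n_features
  folds <- stratified_folds(y, config$fitness_cv_folds, config$seed)
  clf <- fitness_classifier(config$classifier)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed + 1L)

  members <- pop$members
  evaluate <- function(genes) cv_score(X[, genes, drop = FALSE], y, folds, clf)
  hist_fit <- hist_auc <- numeric(config$generations)
  hist_genes <- character(config$generations)
  best_overall <- NULL; best_overall_auc <- -Inf
  best_overall_fit <- NA_real_; best_gen <- NA_integer_

  for (gen in seq_len(config$generations)) {
    scored <- lapply(members, evaluate)
    fits <- vapply(scored, as.numeric, 0)
    aucs <- vapply(scored, function(f) attr(f, "auc"), 0)
    b <- which.max(fits)
    hist_fit[gen] <- fits[b]
    hist_auc[gen] <- aucs[b]
    hist_genes[gen] <- paste(sort(members[[b]]), collapse = ",")
    if (aucs[b] > best_overall_auc) {
      best_overall <- members[[b]]; best_overall_auc <- aucs[b]
      best_overall_fit <- fits[b]; best_gen <- gen
    }
    if (gen == config$generations) break

    pick <- function() {
      cand <- sample.int(length(members), config$tournament_size,
                         replace = TRUE)
      cand[which.max(fits[cand])]
    }
    nxt <- vector("list", config$pop_size)
    n_elite <- min(config$elitism, config$pop_size)
    if (n_elite > 0L) {
      elite_idx <- order(fits, decreasing = TRUE)[seq_len(n_elite)]
      nxt[seq_len(n_elite)] <- members[elite_idx]
    }
    i <- n_elite + 1L
    while (i <= config$pop_size) {
      kids <- two_point_crossover(members[[pick()]], members[[pick()]])
      for (kid in kids) {
        if (i > config$pop_size) break
        kid <- repair_duplicates(kid, nf)
        if (config$per_gene_mutation) {
          hit <- which(runif(length(kid)) < config$mutation_prob)
          for (h in hit) kid[h] <- sample(setdiff(seq_len(nf), kid), 1L)
        } else if (runif(1) < config$mutation_prob) {
          h <- sample.int(length(kid), 1L)
          kid[h] <- sample(setdiff(seq_len(nf), kid), 1L)
        }
        stopifnot(valid_chromosome(kid, config$chrom_len, nf))
        nxt[[i]] <- kid
        i <- i + 1L
      }
    }
    members <- nxt
  }
  list(best = sort(best_overall), best_fitness = best_overall_fit,
       best_auc = best_overall_auc, best_generation = best_gen,
       history = data.frame(generation = seq_len(config$generations),
                            best_fitness = hist_fit, best_auc = hist_auc,
                            genes = hist_genes, stringsAsFactors = FALSE))
}

#' Write a GA run's artifacts
#'
#' @param result A [ga_evolve()] result.
#' @param history_path TSV for the per-generation history.
#' @param subset_path JSON for the selected feature index list.
#' @return `subset_path`, invisibly.
#' @export
write_ga_result <- function(result, history_path, subset_path) {
  write.table(result$history, history_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(indices = result$best,
                            fitness = result$best_fitness,
                            auc = result$best_auc,
                            generation = result$best_generation),
                       subset_path, auto_unbox = TRUE, digits = NA)
  invisible(subset_path)
}

#' Rank features by Fisher F-score
#'
#' Classical per-feature F-score: squared deviations of the class means
#' from the overall mean over the summed within-class variances. A
#' feature with zero within-class variance but separated means scores
#' `Inf` (ranked first); a zero-total-variance feature scores 0 (ranked
#' last).
#'
#' @param X Feature matrix.
#' @param y 0/1 labels (both classes present).
#' @return Integer vector of column indices in descending score order,
#'   with the scores as attribute `"scores"` (in column order).
#' @export
fscore_rank <- function(X, y) {
  if (length(unique(y)) < 2L) stop("both classes must be present")
  i1 <- y == 1L; i0 <- !i1
  m <- colMeans(X)
  m1 <- colMeans(X[i1, , drop = FALSE]); m0 <- colMeans(X[i0, , drop = FALSE])
  v1 <- apply(X[i1, , drop = FALSE], 2, var)
  v0 <- apply(X[i0, , drop = FALSE], 2, var)
  num <- (m1 - m)^2 + (m0 - m)^2
  den <- v1 + v0
  score <- ifelse(den == 0, ifelse(num > 0, Inf, 0), num / den)
  score[apply(X, 2, var) == 0] <- 0
  rank_idx <- order(score, decreasing = TRUE)
  attr(rank_idx, "scores") <- score
  rank_idx
}

#' Sequential forward search over a ranked feature list
#'
#' Adds features in ranked order, scoring each prefix with the
#' cross-validated fitness classifier, and returns the prefix with the
#' maximum AUC together with the per-size score curve.
#'
#' @param ranked Integer vector of feature indices, best first.
#' @param X Feature matrix.
#' @param y 0/1 labels.
#' @param max_k Largest prefix length to score.
#' @param config A [ga_config()] (classifier + CV settings).
#' @return List with `best` (indices), `best_auc`, and `curve`
#'   (data frame: k, accuracy, auc).
#' @export
sfs_select <- function(ranked, X, y, max_k = length(ranked),
                       config = ga_config()) {
  if (!length(ranked)) stop("ranked feature list is empty")
  max_k <- min(max_k, length(ranked))
  folds <- stratified_folds(y, config$fitness_cv_folds, config$seed)
  clf <- fitness_classifier(config$classifier)
  accs <- aucs <- numeric(max_k)
  for (k in seq_len(max_k)) {
    a <- cv_score(X[, ranked[seq_len(k)], drop = FALSE], y, folds, clf)
    accs[k] <- as.numeric(a); aucs[k] <- attr(a, "auc")
  }
  kbest <- which.max(aucs)
  list(best = ranked[seq_len(kbest)], best_auc = aucs[kbest],
       curve = data.frame(k = seq_len(max_k), accuracy = accs, auc = aucs))
}
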