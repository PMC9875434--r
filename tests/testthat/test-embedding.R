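test_that("k-mer corpus enumerates stride-1 windows", {
  ds <- solu_dataset(c("a", "b"), c("ACDEF", "MKTAYI"))
  corp <- build_corpus(ds, 3)
  expect_identical(corp$sentences$a, c("ACD", "CDE", "DEF"))
  expect_identical(lengths(corp$sentences), c(a = 3L, b = 4L))
  set.seed(4)
  gen <- generate_dataset(synth_spec(n = 10, length_range = c(20, 40), seed = 4))
  corp2 <- build_corpus(gen, 4)
  brute <- unique(unlist(lapply(gen$sequence, function(s)
    sapply(seq_len(nchar(s) - 3), function(i) substr(s, i, i + 3)))))
  expect_setequal(corp2$vocabulary, brute)
  expect_error(build_corpus(solu_dataset("x", "AC"), 3), "shorter than k")
  expect_error(build_corpus(ds, 9), "k must be")
})

test_that("skip-gram training is seeded-deterministic and context-aware", {
  sents <- c(replicate(60, "DWAWD"), replicate(60, "DWCWD"),
             replicate(60, "KYKYKYK"))
  ds <- solu_dataset(sprintf("s%03d", seq_along(sents)), sents)
  corp <- build_corpus(ds, 2)
  m <- train_skipgram(corp, window = 2, dim = 16, seed = 5, epochs = 30)
  expect_identical(dim(m$vectors), c(length(corp$vocabulary), 16L))
  m2 <- train_skipgram(corp, window = 2, dim = 16, seed = 5, epochs = 30)
  expect_identical(m$vectors, m2$vectors)
  # WA and WC always share contexts; KY never shares theirs
  cos <- function(a, b) sum(m$vectors[a, ] * m$vectors[b, ]) /
    sqrt(sum(m$vectors[a, ]^2) * sum(m$vectors[b, ]^2))
  expect_gt(cos("WA", "WC"), cos("WA", "KY"))
})

test_that("sequence embedding is the mean of its k-mer vectors", {
  gen <- generate_dataset(synth_spec(n = 15, length_range = c(20, 50), seed = 6))
  corp <- build_corpus(gen, 3)
  m <- train_skipgram(corp, window = 2, dim = 8, seed = 2, epochs = 5)
  # homopolymer: a single repeated k-mer, embedding equals that vector
  poly <- strrep("A", 12)
  if ("AAA" %in% rownames(m$vectors)) {
    expect_equal(unname(embed_sequence(poly, m)),
                 unname(m$vectors["AAA", ]))
    # concatenation invariance holds exactly for homopolymers
    expect_equal(embed_sequence(strrep("A", 24), m),
                 embed_sequence(poly, m))
  }
  s <- gen$sequence[1]
  starts <- seq_len(nchar(s) - 2)
  km <- substring(s, starts, starts + 2)
  brute <- colMeans(m$vectors[km, , drop = FALSE])
  expect_equal(embed_sequence(s, m), brute)
  E <- embed_dataset(gen, m)
  expect_identical(dim(E), c(15L * 2L, 8L))
  expect_error(embed_sequence("AC", m), "shorter than k")
  expect_warning(z <- embed_sequence("WWWWWW", m), "out of vocabulary")
  expect_equal(unname(z), rep(0, 8))
})

test_that("grid search scores every cell and finds a planted order-level signal", {
  ds <- solu_dataset(c("a", "b"), c("ACDEFGH", "MKTAYIK"), c(1L, 0L))
  fixed <- function(X, y) 0.5
  gs <- grid_search_kw(ds, k_range = 2:3, w_range = 1:2, eval_fn = fixed,
                       dim = 4, epochs = 1)
  expect_identical(nrow(gs$table), 4L)
  gs1 <- grid_search_kw(ds, k_range = 3, w_range = 2, eval_fn = fixed,
                        dim = 4, epochs = 1)
  expect_equal(c(gs1$best_k, gs1$best_w), c(3, 2))

  # order-2 Markov classes: identical pair statistics, distinct triplets;
  # only k = 3 can embed the signal
  gen_markov <- function(n, len, flip, seed) {
    set.seed(seed)
    vapply(seq_len(n), function(i) {
      x <- sample(c("A", "C"), 2, replace = TRUE)
      for (t in 3:len) {
        keep <- runif(1) < 0.85
        same <- xor(flip, !keep)
        x <- c(x, if (same) x[t - 2] else setdiff(c("A", "C"), x[t - 2]))
      }
      paste(x, collapse = "")
    }, "")
  }
  mk <- solu_dataset(sprintf("m%03d", 1:80),
                     c(gen_markov(40, 60, FALSE, 1), gen_markov(40, 60, TRUE, 2)),
                     c(rep(1L, 40), rep(0L, 40)))
  evalfn <- function(X, y) {
    folds <- solupred:::stratified_folds(y, 3, 99)
    as.numeric(solupred:::cv_score(X, y, folds,
                                   solupred:::fitness_classifier("dlda")))
  }
  gs2 <- grid_search_kw(mk, k_range = 2:3, w_range = 2, eval_fn = evalfn,
                        dim = 16, seed = 3, epochs = 10)
  expect_identical(gs2$best_k, 3L)
})

test_that("embedding models survive the text round trip", {
  gen <- generate_dataset(synth_spec(n = 5, length_range = c(20, 30), seed = 13))
  m <- train_skipgram(build_corpus(gen, 3), window = 2, dim = 6, seed = 1,
                      epochs = 2)
  base <- file.path(tempdir(), "embtest")
  save_embedding(m, base)
  back <- load_embedding(base)
  expect_equal(back$vectors, m$vectors, tolerance = 1e-6)
  expect_identical(back$k, m$k)
  expect_identical(back$window, m$window)
})
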