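test_that("population initialization is valid, seeded, and respects bounds", {
  cfg <- ga_config(pop_size = 20, chrom_len = 10, generations = 5, seed = 3)
  pop <- init_population(cfg, 50)
  expect_length(pop$members, 20L)
  for (m in pop$members) {
    expect_length(m, 10L)
    expect_identical(anyDuplicated(m), 0L)
    expect_true(all(m >= 1 & m <= 50))
  }
  expect_identical(init_population(cfg, 50)$members, pop$members)
  # chromosome length equal to the feature count selects everything
  cfg2 <- ga_config(pop_size = 3, chrom_len = 8, generations = 1)
  pop2 <- init_population(cfg2, 8)
  for (m in pop2$members) expect_setequal(m, 1:8)
  expect_error(init_population(ga_config(chrom_len = 100), 50), "exceeds")
})

test_that("fitness is near chance on null data and high on planted signal", {
  cfg <- ga_config(chrom_len = 5, fitness_cv_folds = 3, classifier = "dlda",
                   seed = 7)
  set.seed(7)
  null_accs <- replicate(30, {
    X <- matrix(rnorm(200 * 5), 200, 5)
    y <- rep(0:1, 100)
    as.numeric(ga_fitness(1:5, X, y, cfg))
  })
  expect_lt(abs(mean(null_accs) - 0.5), 0.05)
  sim <- generate_feature_matrix(n = 300, p = 20, n_informative = 5,
                                 effect_size = 3, seed = 5)
  fit <- ga_fitness(sim$informative, sim$X, sim$y,
                    ga_config(chrom_len = 5, classifier = "dlda",
                              fitness_cv_folds = 3, seed = 5))
  expect_gt(as.numeric(fit), 0.95)
  expect_gt(attr(fit, "auc"), 0.95)
  # identical on repeat with the same seed
  fit2 <- ga_fitness(sim$informative, sim$X, sim$y,
                     ga_config(chrom_len = 5, classifier = "dlda",
                               fitness_cv_folds = 3, seed = 5))
  expect_identical(as.numeric(fit), as.numeric(fit2))
  expect_error(ga_fitness(1:5, sim$X, rep(1, 300), cfg), "both classes")
})

test_that("every base fitness classifier separates an easy planted signal", {
  sim <- generate_feature_matrix(n = 120, p = 8, n_informative = 4,
                                 effect_size = 3, seed = 13)
  for (clf in c("dlda", "lda", "svm", "logistic")) {
    cfg <- ga_config(chrom_len = 8, classifier = clf,
                     fitness_cv_folds = 3, seed = 13)
    fit <- ga_fitness(1:8, sim$X, sim$y, cfg)
    expect_gt(as.numeric(fit), 0.9, label = paste("accuracy of", clf))
    expect_gt(attr(fit, "auc"), 0.9, label = paste("AUC of", clf))
  }
})

test_that("evolution preserves chromosome validity and is monotone with elitism", {
  # toy separable problem keeps fitness evaluation cheap
  sim <- generate_feature_matrix(n = 120, p = 40, n_informative = 6,
                                 effect_size = 2, seed = 9)
  cfg <- ga_config(pop_size = 16, chrom_len = 8, generations = 12,
                   classifier = "dlda", fitness_cv_folds = 3, seed = 9)
  res <- ga_evolve(init_population(cfg, 40), sim$X, sim$y, cfg)
  expect_length(res$best, 8L)
  expect_identical(anyDuplicated(res$best), 0L)
  expect_identical(nrow(res$history), 12L)
  # elitism of one makes the per-generation best fitness non-decreasing
  expect_true(all(diff(res$history$best_fitness) >= -1e-12))
  # reproducible end to end
  res2 <- ga_evolve(init_population(cfg, 40), sim$X, sim$y, cfg)
  expect_identical(res$best, res2$best)
  expect_identical(res$history$best_auc, res2$history$best_auc)
})

test_that("crossover without mutation only recombines parental genes", {
  set.seed(1)
  p1 <- sample.int(50, 10); p2 <- sample.int(50, 10)
  kids <- solupred:::two_point_crossover(p1, p2)
  for (kid in kids) expect_true(all(kid %in% c(p1, p2)))
  # duplicate repair restores validity without touching unique genes
  broken <- c(1L, 2L, 2L, 3L)
  fixed <- solupred:::repair_duplicates(broken, 10)
  expect_identical(anyDuplicated(fixed), 0L)
  expect_true(all(c(1L, 2L, 3L) %in% fixed))
})

test_that("F-score ranking matches a hand-computed table and handles edge cases", {
  y <- c(0, 0, 0, 1, 1, 1)
  X <- cbind(lab = y,                         # identical to the label
             good = c(0, 1, 0, 9, 10, 11),    # strong separation
             weak = c(1, 2, 3, 3, 2, 2),
             flat = rep(4, 6),                # zero variance
             noise = c(5, 1, 3, 2, 4, 6))
  r <- fscore_rank(X, y)
  sc <- attr(r, "scores")
  expect_identical(r[1], 1L)        # label column: infinite score, first
  expect_identical(r[2], 2L)
  expect_identical(r[length(r)], 4L)  # zero-variance column last
  expect_identical(sc[[4]], 0)
  # hand-computed classical F-score for column "good"
  m1 <- mean(c(9, 10, 11)); m0 <- mean(c(0, 1, 0)); m <- mean(X[, "good"])
  expect_equal(sc[[2]],
               ((m1 - m)^2 + (m0 - m)^2) / (var(c(9, 10, 11)) + var(c(0, 1, 0))))
  set.seed(2)
  Xn <- matrix(rnorm(100 * 4), 100, 4)
  yn <- rep(0:1, 50)
  expect_true(all(attr(fscore_rank(Xn, yn), "scores") < 0.2))
})

test_that("sequential forward search returns the AUC-maximal prefix", {
  sim <- generate_feature_matrix(n = 200, p = 10, n_informative = 3,
                                 effect_size = 2.5, seed = 4)
  cfg <- ga_config(classifier = "dlda", fitness_cv_folds = 3, seed = 4)
  ranked <- fscore_rank(sim$X, sim$y)
  expect_true(all(sim$informative %in% ranked[1:3]))
  res <- sfs_select(ranked, sim$X, sim$y, max_k = 8, config = cfg)
  expect_identical(nrow(res$curve), 8L)
  expect_true(all(sim$informative %in% res$best))
  one <- sfs_select(ranked, sim$X, sim$y, max_k = 1, config = cfg)
  expect_identical(one$best, ranked[1])
})
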