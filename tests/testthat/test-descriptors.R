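test_that("amino-acid and dipeptide composition match their definitions", {
  a <- aac("AAAA")
  expect_equal(unname(a[["AAC.A"]]), 1)
  expect_equal(sum(a), 1)
  expect_equal(unname(aac(paste(AA20, collapse = ""))),
               rep(0.05, 20))
  d <- dpc("AAAA")
  expect_equal(unname(d[["DPC.AA"]]), 1)
  d2 <- dpc("ACAC")
  expect_equal(unname(d2[["DPC.AC"]]), 2 / 3)
  expect_equal(unname(d2[["DPC.CA"]]), 1 / 3)
  expect_error(dpc("A"), "length")
  expect_error(aac(""), "empty|non-empty")
})

test_that("CTD composition gives per-property fractions that sum to one", {
  gr <- ctdc_groupings()
  expect_length(gr, 13L)
  # a sequence drawn entirely from group 1 of the first property
  g1 <- names(gr[[1]])[gr[[1]] == 1L]
  v <- ctdc(paste(rep(g1[1], 10), collapse = ""))
  expect_equal(unname(v[1:3]), c(1, 0, 0))
  set.seed(5)
  v2 <- ctdc(random_seq(120))
  sums <- tapply(v2, rep(seq_len(13), each = 3), sum)
  expect_equal(as.numeric(sums), rep(1, 13), tolerance = 1e-12)
})

test_that("APAAC has the stated dimension, sums to one, and matches the formula oracle", {
  expect_length(apaac("ACDEFG", lambda = 1), 22L)
  expect_length(apaac("ACDEFGHIKL", lambda = 4), 28L)
  set.seed(11)
  s <- random_seq(60)
  v <- apaac(s, lambda = 3, weight = 0.05)
  expect_equal(sum(v), 1, tolerance = 1e-12)
  expect_equal(unname(v), oracle_apaac(s, 3, 0.05), tolerance = 1e-10)
  expect_error(apaac("ACD", lambda = 3), "exceed lambda")
})

test_that("quasi-sequence-order has the stated dimension and zero self-distance couplings", {
  expect_length(qsorder("ACDEF", nlag = 1), 42L)
  v <- qsorder(strrep("A", 30), nlag = 3)
  expect_equal(unname(v[41:46]), rep(0, 6))  # d(A,A) = 0
  set.seed(12)
  s <- random_seq(80)
  expect_equal(unname(qsorder(s, nlag = 3, weight = 0.1)),
               oracle_qsorder(s, 3, 0.1, physchem_distance_matrix(),
                              grantham_matrix()),
               tolerance = 1e-10)
  expect_error(qsorder("AC", nlag = 3), "exceed nlag")
})

test_that("combined encoding has the contract widths and deterministic values", {
  ds <- generate_dataset(synth_spec(n = 5, length_range = c(30, 60),
                                    seed = 3))
  X <- encode_physchem(ds)
  expect_identical(ncol(X), 523L)
  # dimension formula: 20 + 400 + 39 + (20 + 2*lambda) + (40 + 2*nlag)
  expect_identical(ncol(encode_physchem(ds, descriptor_spec(apaac_lambda = 0))),
                   521L)
  expect_identical(descriptor_spec(apaac_lambda = 0)$dimension, 521L)
  expect_equal(unname(rowSums(X[, 1:20])), rep(1, nrow(X)))
  fam <- feature_families(X)
  expect_identical(as.integer(table(fam)[c("AAC", "DPC", "CTDC", "APAAC", "QSOrder")]),
                   c(20L, 400L, 39L, 22L, 42L))
  expect_identical(X, encode_physchem(ds))  # bit-identical repeat
})

test_that("permuting a sequence fixes composition features but moves order terms", {
  set.seed(21)
  s <- random_seq(100)
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(aac(s), aac(perm))
  expect_equal(ctdc(s), ctdc(perm))
  expect_false(isTRUE(all.equal(dpc(s), dpc(perm))))
  expect_false(isTRUE(all.equal(apaac(s, 3), apaac(perm, 3))))
  expect_false(isTRUE(all.equal(qsorder(s, 3), qsorder(perm, 3))))
})
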