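# Reference values for the global properties were computed independently
# with Biopython's ProtParam on the same fixtures and frozen here.

test_that("global physicochemical features match independent references", {
  v <- phys19("FWY")
  expect_equal(unname(v[["PHYS.aromaticity"]]), 1)
  expect_equal(unname(phys19("KK")[["PHYS.gravy"]]), -3.9)  # Kyte-Doolittle K
  gg <- phys19("GG")
  expect_equal(unname(gg[["PHYS.mol_weight"]]), 132.1179, tolerance = 1e-6)
  expect_equal(unname(gg[["PHYS.instability"]]), 66.7, tolerance = 1e-6)

  s <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  w <- phys19(s)
  expect_equal(unname(w[["PHYS.mol_weight"]]), 3935.5547, tolerance = 1e-3)
  expect_equal(unname(w[["PHYS.pI"]]), 9.987974, tolerance = 1e-3)
  expect_equal(unname(w[["PHYS.gravy"]]), -0.403030, tolerance = 1e-6)
  expect_equal(unname(w[["PHYS.instability"]]), 53.5485, tolerance = 1e-3)
  expect_equal(unname(w[["PHYS.charge_pH7"]]), 2.591934, tolerance = 1e-3)
  u <- phys19(paste(AA20, collapse = ""))
  expect_equal(unname(u[["PHYS.pI"]]), 6.784552, tolerance = 1e-3)
  expect_equal(unname(u[["PHYS.ext_reduced"]]), 5500 + 1490)
  expect_identical(names(w), solupred:::PHYS19_NAMES)
})

test_that("transmembrane caller flags hydrophobic stretches and charged N-termini", {
  tmseq <- paste0("MKKR", strrep("I", 25), "KDES")
  tm <- tm_features(tmseq)
  expect_gte(tm[["PHYS.tm_residues"]], 19)
  expect_identical(unname(tm[["PHYS.n_term_inside"]]), 1)
  soluble <- strrep("KDES", 20)
  tm2 <- tm_features(soluble)
  expect_identical(unname(tm2[["PHYS.tm_residues"]]), 0)
  expect_lt(tm2[["PHYS.tm_expected"]], 1)
})

test_that("identity provider returns containment in [0,1], 1 for an exact duplicate", {
  ds <- generate_dataset(synth_spec(n = 10, length_range = c(40, 60), seed = 8))
  ref <- solu_dataset(c("r1", ds$id[2]), c(ds$sequence[1], "ACDEFGHIKLMNPQRSTVWY"))
  idn <- identity_to_reference(ds, ref)
  expect_equal(idn[1], 1)              # record 1 duplicated in reference
  expect_true(all(idn >= 0 & idn <= 1))
  # self-matches by id are excluded
  self_ref <- ds
  idn2 <- identity_to_reference(ds, self_ref)
  expect_true(all(idn2 < 1))
})

test_that("the 19-feature matrix is complete and uses the flagged sentinel without a provider", {
  ds <- generate_dataset(synth_spec(n = 6, length_range = c(30, 50), seed = 9))
  expect_warning(m <- phys19_matrix(ds), "sentinel")
  expect_identical(dim(m), c(12L, 19L))
  expect_true(all(is.finite(m)))
  expect_true(all(m[, "PHYS.identity"] == -1))
  m2 <- phys19_matrix(ds, reference = ds)
  expect_true(all(m2[, "PHYS.identity"] >= 0))
  # precomputed tables take precedence
  tmtab <- data.frame(id = ds$id, a = 1, b = 2, c = 0)
  idtab <- data.frame(id = ds$id, identity = 0.25)
  m3 <- phys19_matrix(ds, tm_table = tmtab, identity_table = idtab)
  expect_true(all(m3[, "PHYS.tm_residues"] == 1))
  expect_true(all(m3[, "PHYS.identity"] == 0.25))
  expect_error(phys19_matrix(ds, identity_table = idtab[-1, , drop = FALSE]),
               "missing id")
})
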