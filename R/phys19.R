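## 19 global sequence features: 15 sequence-level physicochemical
## properties, 3 transmembrane-topology features from a built-in
## hydropathy-window caller (or a precomputed table), and 1 maximum
## identity-to-reference feature.

PHYS19_NAMES <- c("PHYS.length", "PHYS.mol_weight", "PHYS.pI", "PHYS.gravy",
                  "PHYS.aromaticity", "PHYS.instability", "PHYS.flexibility",
                  "PHYS.helix_frac", "PHYS.turn_frac", "PHYS.sheet_frac",
                  "PHYS.charged_frac", "PHYS.charge_pH7", "PHYS.ext_reduced",
                  "PHYS.ext_oxidized", "PHYS.lysine_frac",
                  "PHYS.tm_residues", "PHYS.tm_expected",
                  "PHYS.n_term_inside", "PHYS.identity")

# Bjellqvist pK sets (as used by common protein-parameter calculators)
PK_POS <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
PK_NEG <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
PK_NTERM <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44, E = 7.7)
PK_CTERM <- c(D = 4.55, E = 4.75)

protein_charge <- function(counts, first, last, pH) {
  pos <- PK_POS
  neg <- PK_NEG
  if (first %in% names(PK_NTERM)) pos[["Nterm"]] <- PK_NTERM[[first]]
  if (last %in% names(PK_CTERM)) neg[["Cterm"]] <- PK_CTERM[[last]]
  n_of <- function(aa) if (aa %in% c("Nterm", "Cterm")) 1 else counts[[aa]]
  positive <- sum(vapply(names(pos), function(aa)
    n_of(aa) / (10^(pH - pos[[aa]]) + 1), 0))
  negative <- sum(vapply(names(neg), function(aa)
    n_of(aa) / (10^(neg[[aa]] - pH) + 1), 0))
  positive - negative
}

isoelectric_point <- function(counts, first, last) {
  lo <- 4.05; hi <- 12; pH <- 7.775
  while (hi - lo > 1e-4) {
    if (protein_charge(counts, first, last, pH) > 0) lo <- pH else hi <- pH
    pH <- (lo + hi) / 2
  }
  pH
}

# mean windowed Vihinen flexibility; symmetric 9-residue window with
# weights (0.25, 0.4375, 0.625, 0.8125, 1, ...)/5.25. Sequences shorter
# than 9 residues fall back to the unweighted mean.
mean_flexibility <- function(flex_vals) {
  n <- length(flex_vals)
  if (n < 9L) return(mean(flex_vals))
  w <- c(0.25, 0.4375, 0.625, 0.8125, 1, 0.8125, 0.625, 0.4375, 0.25)
  sc <- stats::filter(flex_vals, w / 5.25, sides = 2)
  mean(sc[!is.na(sc)])
}

#' Built-in transmembrane-topology features
#'
#' A hydropathy-window transmembrane caller: Kyte-Doolittle means over
#' 19-residue windows, candidate windows those with mean above `cutoff`.
#' Returns the number of residues covered by candidate windows
#' (`tm_residues`), a soft expected-window count
#' `sum(plogis(2 * (mean - cutoff)))` (`tm_expected`), and an
#' N-terminus-inside indicator from the positive-inside rule (1 if the net
#' K+R-D-E charge of the first 30 residues is positive).
#'
#' @param seq Cleaned amino-acid sequence.
#' @param cutoff Window-mean hydropathy threshold (default 1.6).
#' @return Named numeric vector
#'   `(PHYS.tm_residues, PHYS.tm_expected, PHYS.n_term_inside)`.
#' @export
tm_features <- function(seq, cutoff = 1.6) {
  idx <- seq_index(seq)
  kd <- aa_properties()$kd[idx]
  n <- length(idx)
  win <- min(19L, n)
  cs <- c(0, cumsum(kd))
  starts <- seq_len(n - win + 1L)
  m <- (cs[starts + win] - cs[starts]) / win
  hit <- which(m > cutoff)
  covered <- unique(unlist(lapply(hit, function(s) s:(s + win - 1L))))
  head30 <- idx[seq_len(min(30L, n))]
  net <- sum(AA_ALPHABET[head30] %in% c("K", "R")) -
    sum(AA_ALPHABET[head30] %in% c("D", "E"))
  c(PHYS.tm_residues = length(covered),
    PHYS.tm_expected = sum(stats::plogis(2 * (m - cutoff))),
    PHYS.n_term_inside = as.numeric(net > 0))
}

#' 19 global physicochemical features of one sequence
#'
#' The 15 sequence-level properties are length, average molecular weight,
#' isoelectric point (Bjellqvist pK set, bisection on 4.05-12),
#' Kyte-Doolittle gravy, aromaticity (F/W/Y fraction), instability index
#' (dipeptide weight sum scaled by 10/L), mean windowed flexibility,
#' helix/turn/sheet-former fractions, charged-residue (K/R/D/E) fraction,
#' net charge at pH 7, molar extinction coefficients (reduced and with
#' cystines), and lysine fraction. Three transmembrane features come from
#' `tm` (precomputed, or [tm_features()] when `NULL`); the identity
#' feature is passed in (or the sentinel `-1` when no provider is
#' available -- see [phys19_matrix()]).
#'
#' @param seq Cleaned amino-acid sequence.
#' @param tm Optional precomputed length-3 numeric vector.
#' @param identity Max identity/similarity to a reference set in `[0, 1]`,
#'   or `-1` sentinel.
#' @return Named numeric vector of length 19.
#' @export
phys19 <- function(seq, tm = NULL, identity = -1) {
  idx <- seq_index(seq)
  n <- length(idx)
  p <- aa_properties()
  counts <- setNames(tabulate(idx, 20L), AA_ALPHABET)
  f <- counts / n
  first <- AA_ALPHABET[idx[1L]]
  last <- AA_ALPHABET[idx[n]]
  mw <- sum(counts * p$mw_free) - (n - 1) * 18.0153
  instab <- if (n >= 2L)
    sum(diwv_matrix()[cbind(idx[-n], idx[-1L])]) * 10 / n else 0
  vals <- c(
    PHYS.length = n,
    PHYS.mol_weight = mw,
    PHYS.pI = isoelectric_point(counts, first, last),
    PHYS.gravy = mean(p$kd[idx]),
    PHYS.aromaticity = sum(f[AA_AROMATIC]),
    PHYS.instability = instab,
    PHYS.flexibility = mean_flexibility(p$flex[idx]),
    PHYS.helix_frac = sum(f[c("V", "I", "Y", "F", "W", "L")]),
    PHYS.turn_frac = sum(f[c("N", "P", "G", "S")]),
    PHYS.sheet_frac = sum(f[c("E", "M", "A", "L")]),
    PHYS.charged_frac = sum(f[AA_CHARGED]),
    PHYS.charge_pH7 = protein_charge(counts, first, last, 7),
    PHYS.ext_reduced = 5500 * counts[["W"]] + 1490 * counts[["Y"]],
    PHYS.ext_oxidized = 5500 * counts[["W"]] + 1490 * counts[["Y"]] +
      125 * (counts[["C"]] %/% 2L),
    PHYS.lysine_frac = f[["K"]]
  )
  if (is.null(tm)) tm <- tm_features(seq)
  out <- c(vals, setNames(as.numeric(tm), PHYS19_NAMES[16:18]),
           PHYS.identity = as.numeric(identity))
  stopifnot(identical(names(out), PHYS19_NAMES))
  out
}

# k-mer incidence matrix (sparse) over sequences; used by the identity
# provider
kmer_incidence <- function(seqs, k = 3L) {
  km <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) character(0) else
      unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  })
  vocab <- sort(unique(unlist(km)))
  i <- rep(seq_along(km), lengths(km))
  j <- match(unlist(km), vocab)
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(km), length(vocab)))
}

#' Maximum k-mer containment identity against a reference set
#'
#' Fallback identity provider: for each query, the maximum over reference
#' sequences of `|kmers(query) intersect kmers(ref)| / |kmers(query)|`
#' (k = 3). A query also present in the reference (matched by id) ignores
#' itself.
#'
#' @param dataset Query [solu_dataset()].
#' @param reference Reference [solu_dataset()].
#' @param k k-mer size.
#' @param reference_cap Use at most this many (evenly spaced) reference
#'   sequences, keeping cost bounded on large sets.
#' @return Numeric vector in `[0, 1]`, one value per query record.
#' @export
identity_to_reference <- function(dataset, reference, k = 3L,
                                  reference_cap = 500L) {
  ref <- reference
  if (nrow(ref) > reference_cap) {
    keep <- unique(as.integer(seq(1L, nrow(ref), length.out = reference_cap)))
    ref <- ref[keep, , drop = FALSE]
  }
  all_seqs <- c(dataset$sequence, ref$sequence)
  inc <- kmer_incidence(all_seqs, k)
  nq <- nrow(dataset)
  q <- inc[seq_len(nq), , drop = FALSE]
  r <- inc[nq + seq_len(nrow(ref)), , drop = FALSE]
  shared <- as.matrix(q %*% Matrix::t(r))
  self <- outer(dataset$id, ref$id, "==")
  shared[self] <- -Inf
  denom <- pmax(Matrix::rowSums(q), 1)
  out <- apply(shared, 1L, max) / denom
  out[!is.finite(out)] <- 0
  pmin(pmax(out, 0), 1)
}

#' 19-feature matrix for a dataset
#'
#' Computes [phys19()] per record. Transmembrane features come from
#' `tm_table` (a data frame keyed by `id` with three feature columns, e.g.
#' read from a precomputed topology-predictor run) or from the built-in
#' [tm_features()] caller. The identity feature comes from
#' `identity_table` (id-keyed), or [identity_to_reference()] against
#' `reference`; with neither, the flagged sentinel `-1` is used and a
#' warning is raised (the feature is never silently zeroed).
#'
#' @param dataset A [solu_dataset()].
#' @param tm_table Optional data frame (`id` + 3 numeric columns).
#' @param identity_table Optional data frame (`id` + 1 numeric column).
#' @param reference Optional reference [solu_dataset()] for the fallback
#'   identity provider.
#' @return Numeric matrix (rows = records) with 19 named columns and a
#'   `families` attribute (`"PHYS19"`).
#' @export
phys19_matrix <- function(dataset, tm_table = NULL, identity_table = NULL,
                          reference = NULL) {
  ident <- rep(-1, nrow(dataset))
  if (!is.null(identity_table)) {
    m <- match(dataset$id, identity_table[[1L]])
    if (anyNA(m)) stop("identity_table missing id(s): ",
                       paste(head(dataset$id[is.na(m)], 5), collapse = ", "))
    ident <- as.numeric(identity_table[[2L]][m])
  } else if (!is.null(reference)) {
    ident <- identity_to_reference(dataset, reference)
  } else {
    warning("no identity provider; PHYS.identity set to sentinel -1")
  }
  tm_rows <- NULL
  if (!is.null(tm_table)) {
    m <- match(dataset$id, tm_table[[1L]])
    if (anyNA(m)) stop("tm_table missing id(s): ",
                       paste(head(dataset$id[is.na(m)], 5), collapse = ", "))
    tm_rows <- as.matrix(tm_table[m, -1L, drop = FALSE])
  }
  rows <- lapply(seq_len(nrow(dataset)), function(i) {
    phys19(dataset$sequence[i],
           tm = if (is.null(tm_rows)) NULL else tm_rows[i, ],
           identity = ident[i])
  })
  m <- do.call(rbind, rows)
  rownames(m) <- dataset$id
  attr(m, "families") <- setNames(rep("PHYS19", ncol(m)), colnames(m))
  m
}
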