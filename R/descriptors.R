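## Five physicochemical descriptor families. All operate on cleaned
## sequences (uppercase, 20 canonical letters) and return named numeric
## vectors with frozen column order, so feature matrices built by
## different runs are column-compatible.

seq_index <- function(seq) {
  idx <- match(strsplit(seq, "")[[1]], AA_ALPHABET)
  if (anyNA(idx)) stop("sequence contains non-canonical residues; clean it first")
  idx
}

#' Amino-acid composition (20D)
#'
#' Frequency of each canonical residue, alphabetical column order.
#'
#' @param seq Cleaned amino-acid sequence.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aac <- function(seq) {
  idx <- seq_index(seq)
  if (!length(idx)) stop("empty sequence")
  setNames(tabulate(idx, 20L) / length(idx), paste0("AAC.", AA_ALPHABET))
}

#' Dipeptide composition (400D)
#'
#' Frequency of each ordered adjacent residue pair among the `n - 1`
#' dipeptides of a length-`n` sequence.
#'
#' @inheritParams aac
#' @return Named numeric vector of length 400 summing to 1.
#' @export
dpc <- function(seq) {
  idx <- seq_index(seq)
  n <- length(idx)
  if (n < 2L) stop("dipeptide composition needs length >= 2")
  pair <- (idx[-n] - 1L) * 20L + idx[-1L]
  nm <- paste0("DPC.", rep(AA_ALPHABET, each = 20L), rep(AA_ALPHABET, 20L))
  setNames(tabulate(pair, 400L) / (n - 1L), nm)
}

#' CTD composition (39D)
#'
#' For each of the 13 packaged physicochemical groupings
#' ([ctdc_groupings()]), the fraction of residues falling in groups 1, 2
#' and 3.
#'
#' @inheritParams aac
#' @param groupings Optional alternative groupings (same structure as
#'   [ctdc_groupings()]).
#' @return Named numeric vector of length `3 * length(groupings)`; each
#'   property's triple sums to 1.
#' @export
ctdc <- function(seq, groupings = ctdc_groupings()) {
  idx <- seq_index(seq)
  if (!length(idx)) stop("empty sequence")
  out <- unlist(lapply(names(groupings), function(p) {
    g <- groupings[[p]]
    if (length(g) != 20L || anyNA(g[AA_ALPHABET]))
      stop("grouping '", p, "' is missing residues")
    setNames(tabulate(g[AA_ALPHABET][idx], 3L) / length(idx),
             paste0("CTDC.", p, ".G", 1:3))
  }))
  out
}

#' Amphiphilic pseudo-amino-acid composition (20 + 2*lambda D)
#'
#' Chou's APAAC: 20 composition terms plus, for each lag `j = 1..lambda`,
#' one hydrophobicity and one hydrophilicity sequence-order correlation
#' term. Both scales are standardized over the 20 residues
#' (`(h - mean) / sqrt(sum((h - mean)^2) / 20)`). With relative residue
#' frequencies `f` and correlation factors `tau`, entry `u <= 20` is
#' `f_u / (1 + w * sum(tau))` and entry `20 + j` is
#' `w * tau_j / (1 + w * sum(tau))`, so the whole vector sums to 1.
#'
#' @inheritParams aac
#' @param lambda Number of correlation lags (>= 0); requires
#'   `nchar(seq) > lambda`.
#' @param weight Weighting factor `w` for the order terms (default 0.05).
#' @return Named numeric vector of length `20 + 2 * lambda` summing to 1.
#' @export
apaac <- function(seq, lambda = 1L, weight = 0.05) {
  idx <- seq_index(seq)
  n <- length(idx)
  if (lambda < 0L) stop("lambda must be >= 0")
  if (n <= lambda) stop("sequence length must exceed lambda")
  p <- aa_properties()
  std <- function(h) (h - mean(h)) / sqrt(sum((h - mean(h))^2) / 20)
  h1 <- std(p$hphob)[idx]
  h2 <- std(p$hphil)[idx]
  tau <- numeric(2L * lambda)
  if (lambda > 0L) for (j in seq_len(lambda)) {
    i <- seq_len(n - j)
    tau[2L * j - 1L] <- sum(h1[i] * h1[i + j]) / (n - j)
    tau[2L * j]      <- sum(h2[i] * h2[i + j]) / (n - j)
  }
  f <- tabulate(idx, 20L) / n
  denom <- 1 + weight * sum(tau)
  nm <- c(paste0("APAAC.", AA_ALPHABET),
          if (lambda > 0L)
            paste0("APAAC.", rep(c("Hb", "Hl"), lambda), ".lag",
                   rep(seq_len(lambda), each = 2L)))
  setNames(c(f / denom, weight * tau / denom), nm)
}

#' Quasi-sequence-order descriptor (40 + 2*nlag D)
#'
#' For each of two residue distance matrices -- the packaged
#' physicochemical distance ([physchem_distance_matrix()]) and the
#' Grantham chemical distance ([grantham_matrix()]) -- computes 20
#' composition terms and `nlag` sequence-order-coupling terms. The
#' coupling term at lag `d` is `tau_d = sum_i dist(r_i, r_{i+d})^2`; with
#' relative frequencies `f`, composition entries are
#' `f_u / (1 + w * sum(tau))` and coupling entries
#' `w * tau_d / (1 + w * sum(tau))`.
#'
#' @inheritParams aac
#' @param nlag Maximum lag (>= 1); requires `nchar(seq) > nlag`.
#' @param weight Weighting factor `w` (default 0.1).
#' @param dist_phys,dist_chem Optional replacement 20 x 20 distance
#'   matrices (dimnames must be the one-letter codes).
#' @return Named numeric vector of length `40 + 2 * nlag`.
#' @export
qsorder <- function(seq, nlag = 1L, weight = 0.1,
                    dist_phys = physchem_distance_matrix(),
                    dist_chem = grantham_matrix()) {
  idx <- seq_index(seq)
  n <- length(idx)
  if (nlag < 1L) stop("nlag must be >= 1")
  if (n <= nlag) stop("sequence length must exceed nlag")
  f <- tabulate(idx, 20L) / n
  one <- function(dmat, tag) {
    dmat <- dmat[AA_ALPHABET, AA_ALPHABET]
    tau <- vapply(seq_len(nlag), function(d) {
      i <- seq_len(n - d)
      sum(dmat[cbind(idx[i], idx[i + d])]^2)
    }, 0)
    denom <- 1 + weight * sum(tau)
    setNames(c(f / denom, weight * tau / denom),
             paste0("QSO.", tag, ".", c(AA_ALPHABET, paste0("lag", seq_len(nlag)))))
  }
  sw <- one(dist_phys, "SW")
  gr <- one(dist_chem, "GR")
  c(sw[1:20], gr[1:20], sw[20L + seq_len(nlag)], gr[20L + seq_len(nlag)])
}

#' Descriptor parameter set
#'
#' Bundles the tunable parameters of the two order-aware descriptor
#' families. The defaults (`lambda = 1`, `nlag = 1`) give the canonical
#' 523-dimensional combined width: `20 + 400 + 39 + (20 + 2*lambda) +
#' (40 + 2*nlag)`.
#'
#' @param apaac_lambda APAAC lag count (>= 0).
#' @param apaac_weight APAAC order-term weight (> 0).
#' @param qso_nlag Quasi-sequence-order maximum lag (>= 1).
#' @param qso_weight Quasi-sequence-order weight (> 0).
#' @return A `descriptor_spec` list with a `dimension` field.
#' @export
descriptor_spec <- function(apaac_lambda = 1L, apaac_weight = 0.05,
                            qso_nlag = 1L, qso_weight = 0.1) {
  stopifnot(apaac_lambda >= 0L, qso_nlag >= 1L,
            apaac_weight > 0, qso_weight > 0)
  out <- list(apaac_lambda = as.integer(apaac_lambda),
              apaac_weight = apaac_weight,
              qso_nlag = as.integer(qso_nlag),
              qso_weight = qso_weight)
  out$dimension <- 20L + 400L + 39L + (20L + 2L * out$apaac_lambda) +
    (40L + 2L * out$qso_nlag)
  class(out) <- "descriptor_spec"
  out
}

#' Encode a dataset with the five physicochemical descriptor families
#'
#' Concatenates AAC, DPC, CTD composition, APAAC and quasi-sequence-order
#' blocks in that fixed order; with the default [descriptor_spec()] the
#' result has 523 columns.
#'
#' @param dataset A [solu_dataset()].
#' @param spec A [descriptor_spec()].
#' @return A numeric matrix (rows = records, rownames = ids) with a
#'   `families` attribute mapping each column to its descriptor family.
#' @export
encode_physchem <- function(dataset, spec = descriptor_spec()) {
  stopifnot(inherits(spec, "descriptor_spec"))
  need <- min_required_length(k = 1L, spec$apaac_lambda, spec$qso_nlag)
  short <- nchar(dataset$sequence) < need
  if (any(short))
    stop("sequence(s) too short for descriptor parameters (need >= ", need,
         "): ", paste(head(dataset$id[short], 5), collapse = ", "))
  rows <- lapply(seq_len(nrow(dataset)), function(i) {
    tryCatch(
      c(aac(dataset$sequence[i]),
        dpc(dataset$sequence[i]),
        ctdc(dataset$sequence[i]),
        apaac(dataset$sequence[i], spec$apaac_lambda, spec$apaac_weight),
        qsorder(dataset$sequence[i], spec$qso_nlag, spec$qso_weight)),
      error = function(e)
        stop("record '", dataset$id[i], "': ", conditionMessage(e),
             call. = FALSE))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- dataset$id
  stopifnot(ncol(m) == spec$dimension, !anyNA(m), all(is.finite(m)))
  fam <- c(rep("AAC", 20L), rep("DPC", 400L), rep("CTDC", 39L),
           rep("APAAC", 20L + 2L * spec$apaac_lambda),
           rep("QSOrder", 40L + 2L * spec$qso_nlag))
  attr(m, "families") <- setNames(fam, colnames(m))
  m
}

#' Column-to-family map of a feature matrix
#'
#' @param x A matrix produced by [encode_physchem()], [phys19_matrix()],
#'   [embed_dataset()] or [hybrid_features()].
#' @return Named character vector (column -> family).
#' @export
feature_families <- function(x) attr(x, "families")
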