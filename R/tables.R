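#' Packaged amino-acid property scales
#'
#' Returns the residue-level property table shipped with the package:
#' Kyte-Doolittle hydropathy (`kd`), Vihinen flexibility (`flex`), the
#' hydrophobicity (`hphob`) and Hopp-Woods hydrophilicity (`hphil`) scales
#' used by the amphiphilic pseudo-amino-acid composition, side-chain mass
#' (`side_mass`), average molecular weight of the free amino acid
#' (`mw_free`), and Grantham's composition/polarity/volume values.
#'
#' @return A data frame with one row per canonical amino acid, rownames the
#'   one-letter codes.
#' @export
aa_properties <- function() {
  if (is.null(.slp_env$aa_prop)) {
    tab <- read.delim(slp_extdata("aa_properties.tsv"), stringsAsFactors = FALSE)
    rownames(tab) <- tab$letter
    stopifnot(setequal(tab$letter, AA_ALPHABET))
    .slp_env$aa_prop <- tab[AA_ALPHABET, ]
  }
  .slp_env$aa_prop
}

#' CTD composition property groupings
#'
#' The 13 three-group residue partitions (seven hydrophobicity scales,
#' normalized van der Waals volume, polarity, polarizability, charge,
#' secondary structure and solvent accessibility) used by the CTD
#' composition descriptor. Each grouping partitions the 20 canonical
#' residues into exactly three non-empty groups.
#'
#' @param path Optional path to an alternative TSV
#'   (columns `property`, `group1`, `group2`, `group3`) overriding the
#'   packaged table.
#' @return A named list; each element is a length-20 integer vector in
#'   `{1,2,3}` named by amino-acid letter.
#' @export
ctdc_groupings <- function(path = NULL) {
  if (is.null(path) && !is.null(.slp_env$ctdc)) return(.slp_env$ctdc)
  tab <- read.delim(if (is.null(path)) slp_extdata("ctdc_groups.tsv") else path,
                    stringsAsFactors = FALSE)
  groups <- lapply(seq_len(nrow(tab)), function(i) {
    g <- integer(20)
    names(g) <- AA_ALPHABET
    for (j in 1:3) {
      letters_j <- strsplit(tab[[paste0("group", j)]][i], "")[[1]]
      g[letters_j] <- j
    }
    if (any(g == 0L) || length(unique(g)) != 3L)
      stop("grouping '", tab$property[i],
           "' does not partition the 20 residues into 3 non-empty groups")
    n <- nchar(paste0(tab$group1[i], tab$group2[i], tab$group3[i]))
    if (n != 20L) stop("grouping '", tab$property[i], "' lists ", n, " letters")
    g
  })
  names(groups) <- tab$property
  if (is.null(path)) .slp_env$ctdc <- groups
  groups
}

#' Grantham chemical distance matrix
#'
#' Computed from Grantham (1974) composition, polarity and volume values
#' with the published coefficients (alpha = 1.833, beta = 0.1018,
#' gamma = 0.000399), scaled so the mean distance over distinct residue
#' pairs is 100.
#'
#' @return A symmetric 20 x 20 matrix with zero diagonal, dimnames the
#'   one-letter codes.
#' @export
grantham_matrix <- function() {
  if (!is.null(.slp_env$grantham)) return(.slp_env$grantham)
  p <- aa_properties()
  d2 <- outer(p$grantham_c, p$grantham_c, "-")^2 * 1.833 +
        outer(p$grantham_p, p$grantham_p, "-")^2 * 0.1018 +
        outer(p$grantham_v, p$grantham_v, "-")^2 * 0.000399
  d <- sqrt(d2)
  dimnames(d) <- list(AA_ALPHABET, AA_ALPHABET)
  d <- d * 100 / mean(d[upper.tri(d)])
  .slp_env$grantham <- d
  d
}

#' Physicochemical residue distance matrix
#'
#' A reconstruction of the Schneider-Wrede style physicochemical distance:
#' Euclidean distance over the standardized hydrophobicity, hydrophilicity
#' and side-chain-mass scales, rescaled to `[0, 1]`. The original published
#' table is not redistributed here; supply `matrix` to
#' [qsorder()] to use it instead.
#'
#' @return A symmetric 20 x 20 matrix in `[0, 1]` with zero diagonal.
#' @export
physchem_distance_matrix <- function() {
  if (!is.null(.slp_env$swdist)) return(.slp_env$swdist)
  p <- aa_properties()
  z <- scale(as.matrix(p[, c("hphob", "hphil", "side_mass")]))
  d <- as.matrix(stats::dist(z))
  dimnames(d) <- list(AA_ALPHABET, AA_ALPHABET)
  d <- d / max(d)
  .slp_env$swdist <- d
  d
}

# dipeptide instability weights (Guruprasad et al.), 20 x 20 matrix [a, b]
# for the ordered pair ab
diwv_matrix <- function() {
  if (!is.null(.slp_env$diwv)) return(.slp_env$diwv)
  tab <- read.delim(slp_extdata("diwv.tsv"), stringsAsFactors = FALSE)
  m <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  m[cbind(tab$a, tab$b)] <- tab$value
  .slp_env$diwv <- m
  m
}
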