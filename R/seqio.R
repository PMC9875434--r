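#' Protein dataset container
#'
#' A `solu_dataset` is a data frame with columns `id` (unique), `sequence`
#' (validated, uppercase, canonical 20-letter alphabet) and `label`
#' (integer 1 = soluble, 0 = insoluble, or `NA` when unlabeled).
#'
#' @param id Character vector of record identifiers.
#' @param sequence Character vector of amino-acid sequences (cleaned with
#'   [clean_sequence()]).
#' @param label Optional numeric/integer vector of 0/1 labels.
#' @param strict Passed to [clean_sequence()].
#' @return A `solu_dataset` object.
#' @export
solu_dataset <- function(id, sequence, label = NULL, strict = TRUE) {
  id <- as.character(id)
  if (anyDuplicated(id))
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (length(id) != length(sequence))
    stop("id and sequence lengths differ")
  sequence <- vapply(sequence, clean_sequence, "", strict = strict,
                     USE.NAMES = FALSE)
  if (is.null(label)) label <- rep(NA_integer_, length(id))
  label <- as.integer(label)
  if (any(!is.na(label) & !label %in% c(0L, 1L)))
    stop("labels must be 0 (insoluble) or 1 (soluble)")
  out <- data.frame(id = id, sequence = sequence, label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("solu_dataset", "data.frame")
  out
}

#' @export
print.solu_dataset <- function(x, ...) {
  cc <- class_counts(x)
  cat(sprintf("<solu_dataset> %d sequences (soluble %d, insoluble %d, unlabeled %d)\n",
              nrow(x), cc[["1"]], cc[["0"]], cc[["NA"]]))
  cat(sprintf("  length range %d-%d\n",
              min(nchar(x$sequence)), max(nchar(x$sequence))))
  invisible(x)
}

#' Per-class record counts
#'
#' @param dataset A `solu_dataset`.
#' @return Named integer vector with counts for labels `"0"`, `"1"` and `"NA"`.
#' @export
class_counts <- function(dataset) {
  c("0" = sum(dataset$label %in% 0L),
    "1" = sum(dataset$label %in% 1L),
    "NA" = sum(is.na(dataset$label)))
}

#' Normalize a raw amino-acid sequence
#'
#' Uppercases, strips a terminal `*` (stop), and handles residues outside
#' the 20 canonical letters: in strict mode they are an error naming the
#' residue and its position; in lenient mode they are removed with a
#' warning. Whitespace is always removed. The operation is idempotent.
#'
#' @param raw Character scalar.
#' @param strict Reject non-canonical residues (default) instead of
#'   dropping them.
#' @return The cleaned sequence.
#' @export
clean_sequence <- function(raw, strict = TRUE) {
  if (length(raw) != 1L || is.na(raw)) stop("raw must be a single string")
  s <- toupper(gsub("[[:space:]]", "", raw))
  s <- sub("\\*$", "", s)
  if (!nzchar(s)) stop("sequence empty after cleaning")
  letters_ <- strsplit(s, "")[[1]]
  bad <- which(!letters_ %in% AA_ALPHABET)
  if (length(bad)) {
    if (strict)
      stop(sprintf("non-canonical residue '%s' at position %d",
                   letters_[bad[1]], bad[1]))
    warning(sprintf("removed %d non-canonical residue(s): %s",
                    length(bad),
                    paste(unique(letters_[bad]), collapse = ",")))
    s <- paste(letters_[-bad], collapse = "")
    if (!nzchar(s)) stop("sequence empty after cleaning")
  }
  s
}

#' Read a FASTA file into a dataset
#'
#' Parsing is delegated to [Biostrings::readAAStringSet()]; identifiers are
#' the first whitespace-delimited token of each header. Labels can come
#' from a `|1` / `|0` suffix on the identifier (`labels_in_header = TRUE`)
#' or from a two-column TSV sidecar (`id<TAB>label`).
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @param labels Optional path to a TSV label sidecar.
#' @param labels_in_header Parse trailing `|0`/`|1` off each id.
#' @param strict Passed to [clean_sequence()].
#' @return A [solu_dataset()].
#' @export
read_fasta <- function(path, labels = NULL, labels_in_header = FALSE,
                       strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (!length(nonblank)) stop("no sequences in ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop(sprintf("malformed FASTA: line %d of %s does not start a record",
                 nonblank[1], path))
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e)
                   stop("malformed FASTA in ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  if (!length(aa)) stop("no sequences in ", path)
  ids <- vapply(strsplit(names(aa), "[[:space:]]+"), `[`, "", 1L)
  lab <- rep(NA_integer_, length(ids))
  if (labels_in_header) {
    has <- grepl("\\|[01]$", ids)
    lab[has] <- as.integer(sub("^.*\\|", "", ids[has]))
    ids <- sub("\\|[01]$", "", ids)
  }
  ds <- solu_dataset(ids, as.character(aa), lab, strict = strict)
  if (!is.null(labels)) ds <- attach_labels(ds, labels)
  ds
}

#' Attach labels from a TSV sidecar
#'
#' @param dataset A `solu_dataset`.
#' @param path Two-column TSV (`id<TAB>label`), with or without a header row.
#' @return The dataset with labels filled in.
#' @export
attach_labels <- function(dataset, path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2L) stop("label sidecar must have two columns (id, label)")
  if (identical(tolower(tab[1, 1]), "id")) tab <- tab[-1, , drop = FALSE]
  unknown <- setdiff(tab[[1]], dataset$id)
  if (length(unknown))
    stop("label sidecar references unknown id(s): ",
         paste(head(unknown, 5), collapse = ", "))
  lab <- suppressWarnings(as.integer(tab[[2]]))
  if (any(is.na(lab) | !lab %in% c(0L, 1L)))
    stop("labels must be 0 or 1")
  dataset$label[match(tab[[1]], dataset$id)] <- lab
  dataset
}

#' Write a dataset to FASTA (and optionally a label sidecar)
#'
#' @param dataset A `solu_dataset`.
#' @param path Output FASTA path.
#' @param labels Optional path for a TSV label sidecar (only labeled
#'   records are written to it).
#' @param labels_in_header Append `|label` to each FASTA id instead.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(dataset, path, labels = NULL,
                        labels_in_header = FALSE) {
  ids <- dataset$id
  if (labels_in_header) {
    has <- !is.na(dataset$label)
    ids[has] <- paste0(ids[has], "|", dataset$label[has])
  }
  aa <- Biostrings::AAStringSet(setNames(dataset$sequence, ids))
  Biostrings::writeXStringSet(aa, path)
  if (!is.null(labels)) {
    keep <- !is.na(dataset$label)
    write.table(dataset[keep, c("id", "label")], labels, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# minimum usable sequence length for a given descriptor/embedding setting
min_required_length <- function(k = 3L, apaac_lambda = 1L, qso_nlag = 1L) {
  max(k, apaac_lambda + 1L, qso_nlag + 1L, 2L)
}
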