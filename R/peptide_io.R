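#' Read peptides or proteins from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file into a peptide table. Sequences
#' are uppercased; the record id is the first whitespace-delimited token of
#' the header line. Records containing any symbol outside the 20 standard
#' amino acids (e.g. `B`, `J`, `O`, `U`, `X`, `Z` or `*`) are dropped and
#' counted, mirroring the removal of non-amino-acid sequences during dataset
#' curation.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`, in file order. The
#'   number of dropped records is attached as attribute `"n_dropped"` and
#'   reported with a message when non-zero.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("failed to parse FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  keep <- is_valid_sequence(seqs)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " record(s) dropped: symbols outside the 20-letter ",
            "amino-acid alphabet")
  }
  if (!any(keep)) {
    stop("no valid records in '", path, "' (", n_dropped,
         " record(s) dropped)", call. = FALSE)
  }
  out <- tibble::tibble(id = ids[keep], sequence = unname(seqs[keep]))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write peptides to a FASTA file
#'
#' @param peptides Data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(peptides, path) {
  stopifnot(all(c("id", "sequence") %in% names(peptides)))
  set <- Biostrings::BStringSet(peptides$sequence)
  names(set) <- peptides$id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a labelled peptide table
#'
#' Reads a delimited text file of peptides with binary cell-penetration
#' labels (1 = CPP, 0 = non-CPP). Exact duplicate (sequence, label) rows are
#' collapsed; a sequence that appears with both labels is dropped entirely
#' (keeping either label would bias training) and the conflict is reported.
#' Sequences with symbols outside the standard alphabet are dropped and
#' counted.
#'
#' @param path Path to a tab- (or comma-) separated file with a header; it
#'   must contain columns `sequence` and `label`, and may contain `id`.
#' @param delim Field delimiter, default tab.
#' @return A tibble with columns `id`, `sequence`, `label`. Attributes
#'   `"n_conflicts"` and `"n_dropped"` carry the counts of label conflicts
#'   and of alphabet-invalid rows.
#' @export
read_peptide_table <- function(path, delim = "\t") {
  if (!file.exists(path)) stop("peptide table not found: ", path, call. = FALSE)
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(c("sequence", "label"), names(tab))
  if (length(missing) > 0) {
    stop("peptide table '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"id" %in% names(tab)) tab$id <- paste0("pep", seq_len(nrow(tab)))
  tab <- dplyr::mutate(tab,
                       sequence = toupper(as.character(.data$sequence)),
                       label = as.integer(.data$label))
  if (!all(tab$label %in% c(0L, 1L))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  ok <- is_valid_sequence(tab$sequence)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) dropped: invalid residues")
  }
  tab <- tab[ok, , drop = FALSE]

  # collapse exact duplicates, then remove sequences seen with both labels
  tab <- dplyr::distinct(tab, .data$sequence, .data$label, .keep_all = TRUE)
  conflicted <- tab |>
    dplyr::count(.data$sequence) |>
    dplyr::filter(.data$n > 1) |>
    dplyr::pull(.data$sequence)
  if (length(conflicted) > 0) {
    warning(length(conflicted), " sequence(s) with conflicting labels ",
            "dropped: ", paste(utils::head(conflicted, 3), collapse = ", "),
            call. = FALSE)
    tab <- dplyr::filter(tab, !.data$sequence %in% conflicted)
  }
  out <- tibble::as_tibble(tab[, c("id", "sequence", "label")])
  attr(out, "n_conflicts") <- length(conflicted)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write per-peptide scores to a TSV file
#'
#' Rows are written in input order with scores at fixed 6-decimal precision,
#' so identical inputs produce byte-identical files.
#'
#' @param scores Data frame with columns `id`, `sequence`, `score`
#'   (scores in \[0, 1\]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  stopifnot(all(c("id", "sequence", "score") %in% names(scores)))
  if (nrow(scores) > 0 &&
      (any(scores$score < 0) || any(scores$score > 1))) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  lines <- c("id\tsequence\tscore",
             sprintf("%s\t%s\t%.6f", scores$id, scores$sequence, scores$score))
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write scores to '", path, "'", call. = FALSE)
  invisible(path)
}

#' Read a score TSV written by [write_scores()]
#'
#' @param path Path to the score file.
#' @return A tibble with columns `id`, `sequence`, `score`.
#' @export
read_scores <- function(path) {
  readr::read_tsv(path, col_types = "ccd", progress = FALSE)
}
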