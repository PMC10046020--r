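#' Slice a sequence into overlapping fixed-width windows
#'
#' Extracts every `width`-residue substring of `sequence` at offsets
#' `0, step, 2*step, ...` For a sequence of length `L >= width` and step 1
#' this yields exactly `L - width + 1` windows. Offsets are 0-based (the
#' package's internal coordinate convention; user-facing reports are 1-based).
#'
#' @param sequence A single residue string.
#' @param width Window width (default 9, the model's input length).
#' @param step Offset increment between consecutive windows (default 1,
#'   maximally overlapping).
#' @return A tibble with columns `offset` (0-based integer) and `window`.
#'   Sequences shorter than `width` give zero rows; the caller decides
#'   whether to pad (see [pad_peptide()]).
#' @export
#' @examples
#' slice_windows("MLPGLALLLLAAWTARA")   # 17-mer -> 9 windows
slice_windows <- function(sequence, width = 9L, step = 1L) {
  stopifnot(length(sequence) == 1, width >= 1, step >= 1)
  L <- nchar(sequence)
  if (L < width) {
    return(tibble::tibble(offset = integer(0), window = character(0)))
  }
  offsets <- seq.int(0L, L - width, by = step)
  tibble::tibble(
    offset = as.integer(offsets),
    window = substring(sequence, offsets + 1L, offsets + width)
  )
}

#' Right-pad a short peptide to the model window width
#'
#' Peptides shorter than the window width are padded at the C-terminus with
#' `"-"` so that every model input has the same length. Right-padding keeps
#' the N-terminal register intact, which matters for signal-peptide-like
#' sequences.
#'
#' @param sequence A single residue string of length 1..`width`.
#' @param width Target width (default 9).
#' @param pad Padding symbol (default `"-"`).
#' @return The padded string of length `width`.
#' @export
#' @examples
#' pad_peptide("MLPGL")  # "MLPGL----"
pad_peptide <- function(sequence, width = 9L, pad = PAD) {
  stopifnot(length(sequence) == 1)
  L <- nchar(sequence)
  if (is.na(sequence) || L == 0) {
    stop("cannot pad an empty sequence", call. = FALSE)
  }
  if (L > width) {
    stop("sequence longer than width ", width,
         "; use slice_windows() instead", call. = FALSE)
  }
  paste0(sequence, strrep(pad, width - L))
}

# Windows for one peptide: sliced if long enough, one padded window otherwise.
peptide_windows <- function(sequence, width = 9L) {
  if (nchar(sequence) >= width) {
    slice_windows(sequence, width = width)
  } else {
    tibble::tibble(offset = 0L, window = pad_peptide(sequence, width = width))
  }
}

new_fragment_dataset <- function(fragments, counts) {
  structure(fragments, counts = counts,
            class = c("fragment_dataset", class(fragments)))
}

#' @export
print.fragment_dataset <- function(x, ...) {
  cts <- attr(x, "counts")
  cat("<fragment_dataset> ", nrow(x), " windows (",
      cts$n_positive, " positive, ", cts$n_curated_negative,
      " curated negative, ", cts$n_proteome_negative,
      " proteome negative)\n", sep = "")
  NextMethod()
}

#' Counts attached to a fragment dataset
#'
#' @param dataset A fragment dataset from [fragment_peptides()] or
#'   [build_proteome_negatives()].
#' @return A list of counts: retained fragments per class plus excluded
#'   peptides, window-label conflicts and skipped short proteins.
#' @export
fragment_counts <- function(dataset) attr(dataset, "counts")

#' Build a labelled 9-mer fragment dataset from curated peptides
#'
#' Slices every labelled peptide into overlapping 9-mers (step 1); peptides
#' shorter than 9 residues contribute one right-padded window. Duplicate
#' windows are removed globally (first occurrence kept); a window observed
#' under both labels is dropped from both classes and counted as a conflict.
#' Peptides outside the curated length range (default 5-38 residues, the
#' bounds of the curated CPP datasets) are excluded and reported; the gate
#' applies to training peptides only, not to scan targets.
#'
#' @param peptides Data frame with columns `id`, `sequence` and binary
#'   `label` (1 = CPP).
#' @param width Window width (default 9).
#' @param min_length,max_length Accepted peptide length range (default 5-38).
#' @return A `fragment_dataset`: a tibble with columns `window`, `label`,
#'   `source_id`, `offset` (0-based) and `origin = "curated"`, plus a
#'   `counts` attribute (see [fragment_counts()]).
#' @export
fragment_peptides <- function(peptides, width = 9L,
                              min_length = 5L, max_length = 38L) {
  stopifnot(all(c("id", "sequence", "label") %in% names(peptides)))
  if (anyNA(peptides$label)) {
    stop("all peptides must be labelled", call. = FALSE)
  }
  len <- nchar(peptides$sequence)
  in_range <- len >= min_length & len <= max_length
  n_excluded <- sum(!in_range)
  if (n_excluded > 0) {
    message(n_excluded, " peptide(s) outside the ", min_length, "-",
            max_length, " aa range excluded")
  }
  kept <- peptides[in_range, , drop = FALSE]

  frags <- purrr::pmap_dfr(
    list(kept$id, kept$sequence, kept$label),
    function(id, seq, label) {
      w <- peptide_windows(seq, width = width)
      w$label <- as.integer(label)
      w$source_id <- id
      w
    }
  )
  if (nrow(frags) == 0) {
    frags <- tibble::tibble(offset = integer(0), window = character(0),
                            label = integer(0), source_id = character(0))
  }

  # global dedup: one row per (window, label), then drop cross-label conflicts
  frags <- dplyr::distinct(frags, .data$window, .data$label,
                           .keep_all = TRUE)
  conflicted <- frags |>
    dplyr::count(.data$window) |>
    dplyr::filter(.data$n > 1) |>
    dplyr::pull(.data$window)
  frags <- dplyr::filter(frags, !.data$window %in% conflicted)

  out <- tibble::tibble(
    window = frags$window,
    label = frags$label,
    source_id = frags$source_id,
    offset = frags$offset,
    origin = "curated"
  )
  new_fragment_dataset(out, counts = list(
    n_positive = sum(out$label == 1L),
    n_curated_negative = sum(out$label == 0L),
    n_proteome_negative = 0L,
    n_conflicts = length(conflicted),
    n_excluded_peptides = n_excluded,
    n_skipped_proteins = 0L
  ))
}

#' Build a proteome-derived negative fragment set
#'
#' Extracts every 9-mer window from a set of reference proteins, removes
#' duplicates, labels all windows 0, and excludes any window that also occurs
#' among the positive training windows. Exact 9-mer identity is the default
#' dissimilarity filter; `exclude_hamming = 1` additionally excludes windows
#' within Hamming distance 1 of any positive window (a stricter notion of
#' "low similarity to known CPPs").
#'
#' @param proteins Data frame with columns `id` and `sequence`; entries
#'   shorter than `width` are skipped and counted.
#' @param positive_windows Character vector of positive window strings to
#'   exclude (may be empty).
#' @param width Window width (default 9).
#' @param exclude_hamming 0 (exact identity, default) or 1 (also exclude
#'   single-mismatch neighbours of positive windows).
#' @return A `fragment_dataset` with `label = 0` and `origin = "proteome"`.
#' @export
build_proteome_negatives <- function(proteins, positive_windows = character(0),
                                     width = 9L, exclude_hamming = 0L) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  if (nrow(proteins) == 0) stop("empty proteome", call. = FALSE)
  len <- nchar(proteins$sequence)
  skipped <- sum(len < width)
  usable <- proteins[len >= width, , drop = FALSE]
  if (nrow(usable) == 0) {
    stop("empty proteome: no protein reaches the window width ", width,
         call. = FALSE)
  }
  frags <- purrr::map2_dfr(usable$id, usable$sequence, function(id, seq) {
    w <- slice_windows(seq, width = width)
    w$source_id <- id
    w
  })
  frags <- dplyr::distinct(frags, .data$window, .keep_all = TRUE)

  excl <- unique(positive_windows)
  if (exclude_hamming >= 1L && length(excl) > 0) {
    excl <- unique(c(excl, hamming_neighbours(excl)))
  }
  frags <- dplyr::filter(frags, !.data$window %in% excl)

  out <- tibble::tibble(
    window = frags$window,
    label = 0L,
    source_id = frags$source_id,
    offset = frags$offset,
    origin = "proteome"
  )
  new_fragment_dataset(out, counts = list(
    n_positive = 0L,
    n_curated_negative = 0L,
    n_proteome_negative = nrow(out),
    n_conflicts = 0L,
    n_excluded_peptides = 0L,
    n_skipped_proteins = skipped
  ))
}

# All Hamming-distance-1 neighbours of a set of windows (same width).
hamming_neighbours <- function(windows) {
  alphabet <- aa_alphabet()
  width <- nchar(windows[1])
  out <- vector("list", width)
  for (p in seq_len(width)) {
    variants <- lapply(alphabet, function(a) {
      v <- windows
      substr(v, p, p) <- a
      v
    })
    out[[p]] <- unlist(variants, use.names = FALSE)
  }
  unique(unlist(out, use.names = FALSE))
}

#' Merge fragment datasets with global window deduplication
#'
#' Binds curated and proteome fragment datasets into one training set. When
#' the same window occurs in several datasets, the copy from the earliest
#' dataset wins (list curated fragments first so curated labels take
#' precedence over proteome negatives).
#'
#' @param ... `fragment_dataset` objects.
#' @return A merged `fragment_dataset`.
#' @export
merge_fragment_datasets <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) > 0)
  merged <- dplyr::distinct(dplyr::bind_rows(sets), .data$window,
                            .keep_all = TRUE)
  counts <- list(
    n_positive = sum(merged$label == 1L),
    n_curated_negative = sum(merged$label == 0L &
                               merged$origin == "curated"),
    n_proteome_negative = sum(merged$label == 0L &
                                merged$origin == "proteome"),
    n_conflicts = sum(vapply(sets, function(s)
      fragment_counts(s)$n_conflicts, numeric(1))),
    n_excluded_peptides = sum(vapply(sets, function(s)
      fragment_counts(s)$n_excluded_peptides, numeric(1))),
    n_skipped_proteins = sum(vapply(sets, function(s)
      fragment_counts(s)$n_skipped_proteins, numeric(1)))
  )
  new_fragment_dataset(tibble::as_tibble(merged), counts)
}

#' Write a fragment dataset to TSV (with a JSON sidecar of counts)
#'
#' @param dataset A `fragment_dataset`.
#' @param path Output TSV path; counts go to `<path>.counts.json`.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(dataset, path) {
  readr::write_tsv(
    dataset[, c("window", "label", "source_id", "offset", "origin")],
    path, progress = FALSE)
  jsonlite::write_json(fragment_counts(dataset),
                       paste0(path, ".counts.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a fragment dataset written by [write_fragments()]
#'
#' @param path TSV path.
#' @return A `fragment_dataset`.
#' @export
read_fragments <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  tab$label <- as.integer(tab$label)
  tab$offset <- as.integer(tab$offset)
  if (!"origin" %in% names(tab)) tab$origin <- "curated"
  sidecar <- paste0(path, ".counts.json")
  counts <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    list(n_positive = sum(tab$label == 1L),
         n_curated_negative = sum(tab$label == 0L),
         n_proteome_negative = 0L, n_conflicts = 0L,
         n_excluded_peptides = 0L, n_skipped_proteins = 0L)
  }
  new_fragment_dataset(tab, counts)
}
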