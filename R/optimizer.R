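#' Size of the substitution sequence space around a wild type
#'
#' Number of distinct sequences at Hamming distance 1..`K` from a fixed
#' length-`L` wild type over an alphabet of size `A`:
#' `sum_k choose(L, k) * (A - 1)^k`. The wild type itself is excluded. For a
#' 17-mer, up to 3 substitutions and the 20 amino acids this is 4,713,539
#' (approximately 4.71 million).
#'
#' @param L Wild-type length.
#' @param K Maximum number of substitutions (1..`L`).
#' @param A Alphabet size (default 20).
#' @return The exact count (double).
#' @export
#' @examples
#' count_mutants(17, 3)   # 4713539
count_mutants <- function(L, K, A = 20L) {
  stopifnot(L >= 1, A >= 2)
  if (K < 1 || K > L) stop("K must be in 1..L", call. = FALSE)
  sum(choose(L, seq_len(K)) * (A - 1)^seq_len(K))
}

# Residue options per position (alphabet minus the wild-type residue),
# in alphabet order.
mutant_options <- function(wt_chars, positions, alphabet) {
  lapply(positions, function(p) setdiff(alphabet, wt_chars[p]))
}

# All mutants for one position combination, in deterministic order: the
# first position's replacement varies slowest, the last fastest.
combo_chunk <- function(wt, wt_chars, positions, alphabet) {
  opts <- mutant_options(wt_chars, positions, alphabet)
  lens <- lengths(opts)
  n <- prod(lens)
  seqs <- rep.int(wt, n)
  subs <- character(n)
  for (j in seq_along(positions)) {
    inner <- if (j < length(positions)) prod(lens[(j + 1):length(lens)]) else 1L
    outer <- n / (lens[j] * inner)
    reps <- rep(rep(opts[[j]], each = inner), times = outer)
    substr(seqs, positions[j], positions[j]) <- reps
    piece <- paste0(wt_chars[positions[j]], positions[j], reps)
    subs <- if (j == 1) piece else paste(subs, piece, sep = "+")
  }
  tibble::tibble(sequence = seqs,
                 distance = length(positions),
                 subs = subs)
}

#' Stream the mutant sequence space in chunks
#'
#' Enumerates every distinct sequence within `max_subs` substitutions of the
#' wild type exactly once, in deterministic order (by distance, then by
#' position combination in lexicographic order, then by replacement residues
#' in alphabet order with the last position varying fastest). The wild type
#' never appears. Chunks — one per position combination — are passed to `f`,
#' so memory stays bounded regardless of space size.
#'
#' @param wt Wild-type residue string.
#' @param max_subs Maximum substitutions (default 3).
#' @param alphabet Residue alphabet (default the 20 standard amino acids).
#' @param f Optional callback receiving each chunk (a tibble with columns
#'   `sequence`, `distance`, `subs`); its return value is discarded.
#' @param limit Stop after streaming at least this many mutants (default
#'   unlimited).
#' @return Total number of mutants streamed, invisibly.
#' @export
stream_mutants <- function(wt, max_subs = 3L, alphabet = aa_alphabet(),
                           f = NULL, limit = Inf) {
  stopifnot(length(wt) == 1, max_subs >= 1, max_subs <= nchar(wt))
  wt_chars <- strsplit(wt, "", fixed = TRUE)[[1]]
  if (!all(wt_chars %in% alphabet)) {
    stop("wild type contains residues outside the alphabet", call. = FALSE)
  }
  L <- length(wt_chars)
  total <- 0
  for (k in seq_len(max_subs)) {
    combos <- utils::combn(L, k)
    for (ci in seq_len(ncol(combos))) {
      chunk <- combo_chunk(wt, wt_chars, combos[, ci], alphabet)
      if (!is.null(f)) f(chunk)
      total <- total + nrow(chunk)
      if (total >= limit) return(invisible(total))
    }
  }
  invisible(total)
}

#' Enumerate the mutant sequence space as a tibble
#'
#' Materializes the stream of [stream_mutants()]. Intended for spaces small
#' enough to hold in memory (use `limit`, or [stream_mutants()] /
#' [score_space()] for the full space of a long peptide).
#'
#' @inheritParams stream_mutants
#' @return A tibble with columns `sequence`, `distance` (Hamming distance to
#'   the wild type) and `subs` (substitutions encoded `"P3K+G4R"`: original
#'   residue, 1-based position, replacement).
#' @export
enumerate_mutants <- function(wt, max_subs = 3L, alphabet = aa_alphabet(),
                              limit = Inf) {
  chunks <- list()
  stream_mutants(wt, max_subs, alphabet,
                 f = function(ch) chunks[[length(chunks) + 1L]] <<- ch,
                 limit = limit)
  out <- dplyr::bind_rows(chunks)
  if (nrow(out) > limit) out <- out[seq_len(limit), , drop = FALSE]
  out
}

#' Substitutions between a wild type and equal-length variants
#'
#' @param wt Wild-type residue string.
#' @param sequences Character vector of sequences of the same length.
#' @return A tibble with one row per (sequence, substitution): columns
#'   `sequence`, `position` (1-based), `from`, `to`.
#' @export
mutant_substitutions <- function(wt, sequences) {
  wt_chars <- strsplit(wt, "", fixed = TRUE)[[1]]
  stopifnot(all(nchar(sequences) == length(wt_chars)))
  purrr::map_dfr(sequences, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    d <- which(ch != wt_chars)
    tibble::tibble(sequence = s, position = as.integer(d),
                   from = wt_chars[d], to = ch[d])
  })
}

#' Score the substitution sequence space of a wild-type peptide
#'
#' Streams the mutant space, scores every mutant with the whole-peptide
#' rule (mean ensemble score over its 9-mer windows), and keeps the mutants
#' at or above `threshold` plus a fixed-bin histogram (bin width 0.05 over
#' \[0, 1\]) of all scores.
#'
#' @param ensemble A `cpp_ensemble`.
#' @param wt Wild-type residue string (length >= 9).
#' @param max_subs Maximum substitutions (default 3).
#' @param threshold Survivor threshold on the score (default 0.8).
#' @param limit Score at most this many mutants (default unlimited; the
#'   full space of a 17-mer is ~4.7 million sequences, a batch-scale job).
#' @param alphabet Residue alphabet.
#' @return A `cpp_space_scan`: list with `$survivors` (tibble `sequence`,
#'   `distance`, `subs`, `score`, in enumeration order), `$histogram`
#'   (tibble `bin_lo`, `bin_hi`, `count`), `$n_scored`, `$wt`, `$wt_score`,
#'   `$threshold`.
#' @export
score_space <- function(ensemble, wt, max_subs = 3L, threshold = 0.8,
                        limit = Inf, alphabet = aa_alphabet()) {
  stopifnot(threshold >= 0, threshold <= 1, nchar(wt) >= 9)
  counts <- integer(20)
  survivors <- list()
  scored <- 0
  collect <- function(chunk) {
    if (scored >= limit) return(invisible(NULL))
    if (scored + nrow(chunk) > limit) {
      chunk <- chunk[seq_len(limit - scored), , drop = FALSE]
    }
    sc <- score_sequences_batch(ensemble, chunk$sequence)
    bin <- pmin(floor(sc / 0.05), 19) + 1L
    counts <<- counts + tabulate(bin, nbins = 20L)
    keep <- sc >= threshold
    if (any(keep)) {
      ch <- chunk[keep, , drop = FALSE]
      ch$score <- sc[keep]
      survivors[[length(survivors) + 1L]] <<- ch
    }
    scored <<- scored + nrow(chunk)
  }
  stream_mutants(wt, max_subs, alphabet, f = collect, limit = limit)
  surv <- dplyr::bind_rows(survivors)
  if (nrow(surv) == 0) {
    surv <- tibble::tibble(sequence = character(0), distance = integer(0),
                           subs = character(0), score = numeric(0))
  }
  structure(list(
    survivors = surv,
    histogram = tibble::tibble(
      bin_lo = seq(0, 0.95, by = 0.05),
      bin_hi = seq(0.05, 1, by = 0.05),
      count = as.integer(counts)
    ),
    n_scored = scored,
    wt = wt,
    wt_score = peptide_score(ensemble, wt),
    threshold = threshold
  ), class = "cpp_space_scan")
}

# Batched peptide scoring for equal-length sequences: one predict call for
# all windows of a chunk.
score_sequences_batch <- function(ensemble, sequences) {
  L <- nchar(sequences[1])
  if (L < 9L) {
    return(predict_windows(ensemble,
                           vapply(sequences, pad_peptide, character(1))))
  }
  nW <- L - 8L
  offs <- 0:(nW - 1L)
  wins <- unlist(lapply(offs, function(o) {
    substring(sequences, o + 1L, o + 9L)
  }), use.names = FALSE)
  # wins is grouped by offset: first all sequences at offset 0, etc.
  sc <- predict_windows(ensemble, wins)
  rowMeans(matrix(sc, nrow = length(sequences), ncol = nW))
}

#' @export
print.cpp_space_scan <- function(x, ...) {
  cat("<cpp_space_scan> wt ", x$wt, " (score ",
      sprintf("%.3f", x$wt_score), "): ", x$n_scored,
      " mutants scored, ", nrow(x$survivors), " >= ", x$threshold,
      "\n", sep = "")
  invisible(x)
}

#' Position frequency matrix of equal-length sequences
#'
#' Entry (r, j) is the fraction of sequences carrying residue r at position
#' j; every column sums to 1. This is the matrix behind a sequence logo of,
#' e.g., the surviving mutants of a sequence-space scan (raw frequencies,
#' no information-content scaling).
#'
#' @param sequences Character vector of equal-length residue strings.
#' @return A 20 x L matrix (rows = residues in alphabet order, columns =
#'   1-based positions) of class `cpp_pfm`, with attribute `n_sequences`.
#' @export
position_frequency_matrix <- function(sequences) {
  stopifnot(length(sequences) >= 1)
  L <- nchar(sequences[1])
  if (!all(nchar(sequences) == L)) {
    stop("sequences must all have the same length", call. = FALSE)
  }
  alphabet <- aa_alphabet()
  chars <- matrix(unlist(strsplit(sequences, "", fixed = TRUE),
                         use.names = FALSE),
                  ncol = L, byrow = TRUE)
  pfm <- vapply(seq_len(L), function(j) {
    tab <- table(factor(chars[, j], levels = alphabet))
    as.numeric(tab) / length(sequences)
  }, numeric(length(alphabet)))
  pfm <- matrix(pfm, nrow = length(alphabet), ncol = L,
                dimnames = list(alphabet, seq_len(L)))
  structure(pfm, n_sequences = length(sequences),
            class = c("cpp_pfm", "matrix", "array"))
}

#' Filter and rank surviving mutants by substitution rules
#'
#' Keeps survivors whose substitutions all fall on permitted positions and
#' introduce only permitted residues, then ranks by score (descending, ties
#' broken lexicographically by sequence). The defaults encode the
#' preferences read off the survivor logo of the signal-peptide
#' optimization: positions 3, 4 and 14, replaced by the cationic residues
#' K, R or H.
#'
#' @param scan A `cpp_space_scan` (or a survivors tibble with columns
#'   `sequence` and `score`).
#' @param wt Wild-type string (taken from the scan if omitted).
#' @param positions Permitted 1-based substitution positions.
#' @param residues Permitted replacement residues.
#' @return The filtered, ranked survivors tibble with a `rank` column; empty
#'   (with a warning) if nothing passes the rules.
#' @export
select_candidates <- function(scan, wt = NULL,
                              positions = c(3L, 4L, 14L),
                              residues = c("K", "R", "H")) {
  if (inherits(scan, "cpp_space_scan")) {
    if (is.null(wt)) wt <- scan$wt
    surv <- scan$survivors
  } else {
    surv <- scan
  }
  stopifnot(!is.null(wt), all(c("sequence", "score") %in% names(surv)))
  if (nrow(surv) == 0) {
    warning("no survivors to select from", call. = FALSE)
    return(dplyr::mutate(surv, rank = integer(0)))
  }
  subs <- mutant_substitutions(wt, surv$sequence)
  allowed_by_seq <- subs |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(ok = all(.data$position %in% positions &
                                .data$to %in% residues),
                     .groups = "drop")
  keep_seqs <- allowed_by_seq$sequence[allowed_by_seq$ok]
  out <- surv |>
    dplyr::filter(.data$sequence %in% keep_seqs) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$sequence) |>
    dplyr::mutate(rank = dplyr::row_number())
  if (nrow(out) == 0) warning("no survivors pass the selection rules",
                              call. = FALSE)
  out
}

#' Write the outputs of a sequence-space scan
#'
#' @param scan A `cpp_space_scan`.
#' @param dir Output directory (created if needed): writes `survivors.tsv`,
#'   `histogram.tsv` and `pfm.tsv` (rows = residues, columns = 1-based
#'   positions; computed from the survivors, or skipped when there are
#'   none).
#' @return `dir`, invisibly.
#' @export
write_space_scan <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  surv <- dplyr::mutate(scan$survivors, score = round(.data$score, 6))
  readr::write_tsv(surv, file.path(dir, "survivors.tsv"), progress = FALSE)
  readr::write_tsv(scan$histogram, file.path(dir, "histogram.tsv"),
                   progress = FALSE)
  if (nrow(scan$survivors) > 0) {
    pfm <- position_frequency_matrix(scan$survivors$sequence)
    out <- tibble::as_tibble(as.data.frame(unclass(pfm)),
                             .name_repair = ~ paste0("pos", seq_along(.x)))
    out <- dplyr::mutate(out, residue = rownames(pfm), .before = 1)
    readr::write_tsv(out, file.path(dir, "pfm.tsv"), progress = FALSE)
  }
  invisible(dir)
}
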