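#' Score one peptide
#'
#' The score of a peptide is the mean of the ensemble scores of all its
#' step-1 9-mer windows; peptides shorter than 9 residues are right-padded
#' to a single window. This is the final per-peptide prediction rule.
#'
#' @param ensemble A `cpp_ensemble`.
#' @param sequence A single residue string.
#' @return A score in \[0, 1\].
#' @export
peptide_score <- function(ensemble, sequence) {
  stopifnot(length(sequence) == 1)
  if (!is_valid_sequence(sequence)) {
    stop("invalid residues in sequence: ", sequence, call. = FALSE)
  }
  w <- peptide_windows(sequence)
  mean(predict_windows(ensemble, w$window))
}

#' Score a table of peptides
#'
#' Data-frame-first wrapper around [peptide_score()]: every peptide is
#' scored as the mean of its 9-mer window scores. All windows of all
#' peptides are scored in one batched pass.
#'
#' @param peptides Data frame with columns `id` and `sequence`.
#' @param ensemble A `cpp_ensemble`.
#' @return The input tibble with a `score` column appended (input order
#'   preserved).
#' @export
score_peptides <- function(peptides, ensemble) {
  stopifnot(all(c("id", "sequence") %in% names(peptides)))
  if (nrow(peptides) == 0) {
    return(dplyr::mutate(tibble::as_tibble(peptides), score = numeric(0)))
  }
  ok <- is_valid_sequence(peptides$sequence)
  if (!all(ok)) {
    stop("invalid residues in sequence(s): ",
         paste(utils::head(peptides$sequence[!ok], 3), collapse = ", "),
         call. = FALSE)
  }
  wins <- lapply(peptides$sequence, peptide_windows)
  n_per <- vapply(wins, nrow, integer(1))
  all_windows <- unlist(lapply(wins, `[[`, "window"), use.names = FALSE)
  scores <- predict_windows(ensemble, all_windows)
  grp <- rep(seq_len(nrow(peptides)), n_per)
  per_pep <- as.numeric(tapply(scores, grp, mean))
  dplyr::mutate(tibble::as_tibble(peptides), score = per_pep)
}

new_cpp_profile <- function(id, sequence, residues, windows) {
  structure(list(id = id, sequence = sequence,
                 residues = residues, windows = windows),
            class = "cpp_profile")
}

#' @export
print.cpp_profile <- function(x, ...) {
  cat("<cpp_profile> ", x$id, ": ", nchar(x$sequence), " residues, ",
      nrow(x$windows), " windows, mean score ",
      sprintf("%.3f", mean(x$residues$score)), "\n", sep = "")
  invisible(x)
}

#' Per-residue cell-penetration propensity profile
#'
#' The propensity of residue *i* is the mean of the ensemble scores of all
#' 9-mer windows that contain residue *i*. Interior residues (at least 9
#' windows' reach from both ends) average exactly 9 windows; terminal
#' residues average the windows that exist (down to a single window at each
#' end) — the sequence is not padded, so no artificial context is
#' fabricated. Sequences shorter than 9 residues yield a single padded
#' window whose score every residue shares.
#'
#' @param ensemble A `cpp_ensemble`.
#' @param sequence A single residue string.
#' @param id Identifier recorded in the profile (default `"query"`).
#' @return A `cpp_profile`: list with `$residues` (tibble `position`
#'   (1-based), `residue`, `score`, `n_windows`) and `$windows` (tibble
#'   `start` (1-based), `window`, `score`).
#' @export
residue_propensity <- function(ensemble, sequence, id = "query") {
  stopifnot(length(sequence) == 1)
  if (!is_valid_sequence(sequence)) {
    stop("invalid residues in sequence: ", sequence, call. = FALSE)
  }
  L <- nchar(sequence)
  res_chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (L < 9L) {
    w <- pad_peptide(sequence)
    s <- predict_windows(ensemble, w)
    residues <- tibble::tibble(position = seq_len(L), residue = res_chars,
                               score = rep(s, L), n_windows = 1L)
    windows <- tibble::tibble(start = 1L, window = w, score = s)
    return(new_cpp_profile(id, sequence, residues, windows))
  }
  sw <- slice_windows(sequence)
  wscore <- predict_windows(ensemble, sw$window)
  nW <- length(wscore)                      # L - 8
  cs <- c(0, cumsum(wscore))
  pos <- seq_len(L)
  lo <- pmax(0L, pos - 9L)                  # first covering offset (0-based)
  hi <- pmin(pos - 1L, L - 9L)              # last covering offset
  n_cov <- hi - lo + 1L
  rscore <- (cs[hi + 2L] - cs[lo + 1L]) / n_cov
  residues <- tibble::tibble(position = pos, residue = res_chars,
                             score = rscore, n_windows = n_cov)
  windows <- tibble::tibble(start = sw$offset + 1L, window = sw$window,
                            score = wscore)
  new_cpp_profile(id, sequence, residues, windows)
}

#' Scan a protein for cell-penetrating regions
#'
#' Applies [residue_propensity()] to a full-length protein; no training
#' length gate applies to scan targets.
#'
#' @param ensemble A `cpp_ensemble`.
#' @param protein Either a single residue string or a one-row data frame
#'   with columns `id` and `sequence`.
#' @param id Identifier when `protein` is a bare string.
#' @return A `cpp_profile`.
#' @export
scan_protein <- function(ensemble, protein, id = "protein") {
  if (is.data.frame(protein)) {
    stopifnot(nrow(protein) == 1)
    id <- protein$id[1]
    protein <- protein$sequence[1]
  }
  if (nchar(protein) < 9L) {
    stop("scan target shorter than the 9-residue window", call. = FALSE)
  }
  residue_propensity(ensemble, protein, id = id)
}

#' Call high-propensity regions from a profile
#'
#' Maximal runs of consecutive residues whose propensity reaches the
#' threshold, kept if at least `min_length` residues long. Coordinates are
#' 1-based inclusive. The defaults (threshold 0.8, minimum length 5) follow
#' the optimization cut-off and the minimum length of curated CPPs.
#'
#' @param profile A `cpp_profile`.
#' @param threshold Minimum per-residue score (default 0.8).
#' @param min_length Minimum region length in residues (default 5).
#' @return A tibble with columns `start`, `end`, `length`, `mean_score`,
#'   `subsequence`, sorted by `start`.
#' @export
call_regions <- function(profile, threshold = 0.8, min_length = 5L) {
  stopifnot(inherits(profile, "cpp_profile"),
            threshold >= 0, threshold <= 1, min_length >= 1)
  hits <- profile$residues$score >= threshold
  r <- rle(hits)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  starts <- starts[keep]
  ends <- ends[keep]
  if (length(starts) == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          length = integer(0), mean_score = numeric(0),
                          subsequence = character(0)))
  }
  tibble::tibble(
    start = as.integer(starts),
    end = as.integer(ends),
    length = as.integer(ends - starts + 1L),
    mean_score = vapply(seq_along(starts), function(k) {
      mean(profile$residues$score[starts[k]:ends[k]])
    }, numeric(1)),
    subsequence = substring(profile$sequence, starts, ends)
  )
}

#' Write a profile's per-residue and per-window tables
#'
#' @param profile A `cpp_profile`.
#' @param residue_path,window_path Output TSV paths (either may be `NULL`
#'   to skip).
#' @return The profile, invisibly.
#' @export
write_profile <- function(profile, residue_path, window_path = NULL) {
  if (!is.null(residue_path)) {
    out <- dplyr::mutate(profile$residues, id = profile$id,
                         .before = "position")
    readr::write_tsv(dplyr::mutate(out, score = round(.data$score, 6)),
                     residue_path, progress = FALSE)
  }
  if (!is.null(window_path)) {
    out <- dplyr::mutate(profile$windows, id = profile$id, .before = "start")
    readr::write_tsv(dplyr::mutate(out, score = round(.data$score, 6)),
                     window_path, progress = FALSE)
  }
  invisible(profile)
}
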