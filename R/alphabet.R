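#' The 20 standard amino acids
#'
#' One-letter codes of the 20 standard proteinogenic amino acids, in
#' alphabetical order. This is the residue alphabet used throughout the
#' package; the padding symbol `"-"` is added on top of it for model input
#' (see [aa_vocabulary()]).
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Model vocabulary: 20 amino acids plus the padding symbol
#'
#' The 21-symbol vocabulary consumed by the window classifiers. The padding
#' symbol `"-"` (used to right-pad peptides shorter than the window width)
#' gets its own embedding index; it is never masked.
#'
#' @return Named integer vector mapping each symbol to its embedding index
#'   (1-based; `"-"` is index 21).
#' @export
aa_vocabulary <- function() {
  syms <- c(aa_alphabet(), "-")
  stats::setNames(seq_along(syms), syms)
}

# Pad symbol used for short peptides.
PAD <- "-"

#' Check sequences against the standard amino-acid alphabet
#'
#' @param sequences Character vector of residue strings.
#' @param allow_pad Also accept the padding symbol `"-"`.
#' @return Logical vector: `TRUE` where the sequence is non-empty and uses
#'   only permitted symbols.
#' @export
is_valid_sequence <- function(sequences, allow_pad = FALSE) {
  alphabet <- aa_alphabet()
  if (allow_pad) alphabet <- c(alphabet, PAD)
  pattern <- paste0("^[", paste(alphabet, collapse = ""), "]+$")
  !is.na(sequences) & nzchar(sequences) & grepl(pattern, sequences)
}

# Encode windows (uppercase, fixed width, alphabet already validated) into an
# integer matrix of embedding indices, n x width.
encode_windows <- function(windows, width = 9L) {
  vocab <- aa_vocabulary()
  chars <- strsplit(windows, "", fixed = TRUE)
  bad <- lengths(chars) != width
  if (any(bad)) {
    stop("window(s) not of length ", width, ": ",
         paste(utils::head(windows[bad], 3), collapse = ", "), call. = FALSE)
  }
  idx <- vocab[unlist(chars, use.names = FALSE)]
  if (anyNA(idx)) {
    off <- windows[vapply(chars, function(ch) anyNA(vocab[ch]), logical(1))]
    stop("window(s) contain symbols outside the 21-symbol vocabulary: ",
         paste(utils::head(off, 3), collapse = ", "), call. = FALSE)
  }
  matrix(idx, ncol = width, byrow = TRUE)
}

# Deterministic per-stage seed derivation from one global seed. Stage names
# are hashed by character codes so independent stages get decoupled, stable
# RNG streams; result stays within the 32-bit integer range.
derive_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- as.double(seed %% 2147483647L)
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}
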