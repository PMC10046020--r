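#' Configuration for the synthetic peptide generator
#'
#' The generator emulates the compositional signature that separates known
#' cell-penetrating peptides from background sequence: positives are drawn
#' from a residue distribution enriched in cationic (K/R/H) and hydrophobic
#' (L/A/I/V/F/W/M) residues, negatives and mock-proteome proteins from a
#' uniform background over the 20 standard residues. The expected cationic
#' content of positives (0.35) versus background (0.15) gives downstream
#' classifiers a learnable signal without planting any fixed motif.
#'
#' @param n_pos,n_neg Numbers of positive / negative peptides (default 1000
#'   each, a desk-scale stand-in for curated CPP collections).
#' @param length_range Peptide length range, inclusive, within 5-38 residues.
#' @param cationic_enrichment Total probability mass on K, R, H in positives
#'   (default 0.35).
#' @param hydrophobic_mass Total probability mass on L, A, I, V, F, W, M in
#'   positives (default 0.40). The remaining mass is spread uniformly over
#'   the other residues.
#' @param n_proteins,protein_length_range Mock proteome size and protein
#'   length range (defaults 100 proteins of 80-300 residues).
#' @param motif Optional planted-motif mode: when `TRUE`, each positive
#'   additionally carries a fixed cationic patch (`"KRKRK"`) at a random
#'   offset, for context-sensitivity experiments (default `FALSE`).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_pos = 1000L, n_neg = 1000L,
                             length_range = c(5L, 38L),
                             cationic_enrichment = 0.35,
                             hydrophobic_mass = 0.40,
                             n_proteins = 100L,
                             protein_length_range = c(80L, 300L),
                             motif = FALSE,
                             seed = 1L) {
  stopifnot(
    n_pos >= 0, n_neg >= 0,
    length(length_range) == 2, length_range[1] >= 5, length_range[2] <= 38,
    length_range[1] <= length_range[2],
    cationic_enrichment > 0, cationic_enrichment < 1,
    hydrophobic_mass > 0, hydrophobic_mass < 1,
    cationic_enrichment + hydrophobic_mass < 1,
    n_proteins >= 0, protein_length_range[1] >= 9,
    protein_length_range[1] <= protein_length_range[2]
  )
  structure(list(
    n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
    length_range = as.integer(length_range),
    cationic_enrichment = cationic_enrichment,
    hydrophobic_mass = hydrophobic_mass,
    n_proteins = as.integer(n_proteins),
    protein_length_range = as.integer(protein_length_range),
    motif = isTRUE(motif),
    seed = as.integer(seed)
  ), class = "generator_config")
}

# Residue sampling distribution for positives: cationic mass on {K,R,H},
# hydrophobic mass on {L,A,I,V,F,W,M}, remainder uniform on the rest.
positive_residue_probs <- function(config) {
  alphabet <- aa_alphabet()
  cationic <- c("K", "R", "H")
  hydrophobic <- c("L", "A", "I", "V", "F", "W", "M")
  other <- setdiff(alphabet, c(cationic, hydrophobic))
  p <- stats::setNames(numeric(length(alphabet)), alphabet)
  p[cationic] <- config$cationic_enrichment / length(cationic)
  p[hydrophobic] <- config$hydrophobic_mass / length(hydrophobic)
  p[other] <- (1 - config$cationic_enrichment - config$hydrophobic_mass) /
    length(other)
  p
}

# sample() semantics change for length-1 x; this always samples elements.
sample_from <- function(x, n) {
  x[sample.int(length(x), n, replace = TRUE)]
}

sample_sequences <- function(n, lengths, probs) {
  alphabet <- names(probs)
  vapply(lengths[seq_len(n)], function(L) {
    paste(sample(alphabet, L, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
}

#' Generate a labelled synthetic peptide set
#'
#' Draws `n_pos` positive peptides from the enriched composition and `n_neg`
#' negatives from the uniform background; lengths are uniform over
#' `length_range`. Fully deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A tibble with columns `id`, `sequence`, `label`.
#' @export
generate_labelled_peptides <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_pos + config$n_neg == 0) {
    stop("n_pos + n_neg must be positive", call. = FALSE)
  }
  withr::local_seed(derive_seed(config$seed, "peptides"))
  lr <- config$length_range
  alphabet <- aa_alphabet()
  p_pos <- positive_residue_probs(config)
  p_bg <- stats::setNames(rep(1 / 20, 20), alphabet)

  len_pos <- sample_from(seq.int(lr[1], lr[2]), config$n_pos)
  pos <- sample_sequences(config$n_pos, len_pos, p_pos)
  if (config$motif && config$n_pos > 0) {
    patch <- "KRKRK"
    pos <- vapply(pos, function(s) {
      L <- nchar(s)
      at <- sample.int(max(L - nchar(patch) + 1L, 1L), 1L)
      end <- min(at + nchar(patch) - 1L, L)
      substr(s, at, end) <- substr(patch, 1L, end - at + 1L)
      s
    }, character(1), USE.NAMES = FALSE)
  }
  len_neg <- sample_from(seq.int(lr[1], lr[2]), config$n_neg)
  neg <- sample_sequences(config$n_neg, len_neg, p_bg)

  tibble::tibble(
    id = c(sprintf("pos%04d", seq_len(config$n_pos)),
           sprintf("neg%04d", seq_len(config$n_neg))),
    sequence = c(pos, neg),
    label = rep(c(1L, 0L), c(config$n_pos, config$n_neg))
  )
}

#' Generate a mock reference proteome
#'
#' Random-composition proteins (uniform over the 20 residues) standing in
#' for a reference proteome as a source of negative 9-mer windows. Lengths
#' are uniform over `protein_length_range`; deterministic given the seed.
#'
#' @param config A [generator_config()].
#' @return A tibble with columns `id`, `sequence`.
#' @export
generate_mock_proteome <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::local_seed(derive_seed(config$seed, "proteome"))
  plr <- config$protein_length_range
  p_bg <- stats::setNames(rep(1 / 20, 20), aa_alphabet())
  lens <- sample_from(seq.int(plr[1], plr[2]), config$n_proteins)
  tibble::tibble(
    id = sprintf("prot%04d", seq_len(config$n_proteins)),
    sequence = sample_sequences(config$n_proteins, lens, p_bg)
  )
}
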