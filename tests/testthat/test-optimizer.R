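test_that("the closed-form mutant count matches its defining sum", {
  expect_equal(count_mutants(17, 3, 20), 4713539)
  expect_equal(count_mutants(17, 3, 20),
               17 * 19 + choose(17, 2) * 19^2 + choose(17, 3) * 19^3)
  expect_equal(count_mutants(5, 2, 4), 5 * 3 + 10 * 9)
  expect_equal(count_mutants(1, 1, 2), 1)
  expect_error(count_mutants(5, 6, 20), "1..L")
  expect_error(count_mutants(5, 0, 20), "1..L")
})

test_that("closed form agrees with exhaustive enumeration over small spaces", {
  for (A in c(3L, 4L)) {
    alphabet <- aa_alphabet()[seq_len(A)]
    for (L in 2:5) {
      wt <- strrep(alphabet[1], L)
      all_strings <- do.call(expand.grid,
                             c(rep(list(alphabet), L),
                               stringsAsFactors = FALSE))
      seqs <- do.call(paste0, all_strings)
      dist <- vapply(seqs, function(s) {
        sum(strsplit(s, "")[[1]] != strsplit(wt, "")[[1]])
      }, numeric(1), USE.NAMES = FALSE)
      for (K in 1:min(3L, L)) {
        expect_equal(count_mutants(L, K, A), sum(dist >= 1 & dist <= K))
        enum <- enumerate_mutants(wt, K, alphabet)
        expect_equal(nrow(enum), sum(dist >= 1 & dist <= K))
        expect_setequal(enum$sequence, seqs[dist >= 1 & dist <= K])
      }
    }
  }
})

test_that("enumeration is exact, wild-type-free and deterministic", {
  enum <- enumerate_mutants("AC", 1L, c("A", "C", "D"))
  expect_setequal(enum$sequence, c("CC", "DC", "AA", "AD"))
  expect_equal(nrow(enum), count_mutants(2, 1, 3))

  set.seed(50)
  wt <- random_sequence(6)
  e1 <- enumerate_mutants(wt, 2L)
  e2 <- enumerate_mutants(wt, 2L)
  expect_identical(e1, e2)
  expect_false(wt %in% e1$sequence)
  expect_equal(anyDuplicated(e1$sequence), 0L)
  expect_true(all(e1$distance[order(seq_len(nrow(e1)))] ==
                    cummax(e1$distance)))  # ordered by distance

  # reconstruction: applying the recorded substitutions to the wild type
  # reproduces each mutant
  rebuilt <- vapply(seq_len(nrow(e1)), function(i) {
    s <- wt
    for (piece in strsplit(e1$subs[i], "+", fixed = TRUE)[[1]]) {
      pos <- as.integer(gsub("[A-Z]", "", piece))
      to <- substr(piece, nchar(piece), nchar(piece))
      from <- substr(piece, 1, 1)
      expect_equal(substr(s, pos, pos), from)
      substr(s, pos, pos) <- to
    }
    s
  }, character(1))
  expect_equal(rebuilt, e1$sequence)
  expect_equal(e1$distance,
               vapply(e1$sequence, function(s) {
                 sum(strsplit(s, "")[[1]] != strsplit(wt, "")[[1]])
               }, numeric(1), USE.NAMES = FALSE))

  expect_error(enumerate_mutants("ABC", 1L), "outside the alphabet")
})

test_that("streamed chunks cover the space exactly once", {
  wt <- "MLPGLALLL"
  seen <- character(0)
  n <- stream_mutants(wt, 2L, f = function(ch) {
    seen <<- c(seen, ch$sequence)
  })
  expect_equal(n, count_mutants(9, 2, 20))
  expect_length(seen, n)
  expect_equal(anyDuplicated(seen), 0L)
  # limit short-circuits the stream
  n_lim <- stream_mutants(wt, 2L, limit = 100)
  expect_gte(n_lim, 100)
  expect_lt(n_lim, count_mutants(9, 2, 20))
})

test_that("space scanning filters survivors exactly at the threshold", {
  ens <- untrained_ensemble()
  wt <- "MLPGLALLL"
  scan <- score_space(ens, wt, max_subs = 1L, threshold = 0.5)
  expect_equal(scan$n_scored, count_mutants(9, 1, 20))

  # oracle: score the full enumeration independently and filter
  enum <- enumerate_mutants(wt, 1L)
  oracle_scores <- vapply(enum$sequence,
                          function(s) peptide_score(ens, s),
                          numeric(1), USE.NAMES = FALSE)
  expect_setequal(scan$survivors$sequence,
                  enum$sequence[oracle_scores >= 0.5])
  idx <- match(scan$survivors$sequence, enum$sequence)
  expect_equal(scan$survivors$score, oracle_scores[idx], tolerance = 1e-12)

  # histogram sums to everything scored
  expect_equal(sum(scan$histogram$count), scan$n_scored)

  # monotonicity of the survivor set in the threshold
  lo <- score_space(ens, wt, max_subs = 1L, threshold = 0.3)
  expect_true(all(scan$survivors$sequence %in% lo$survivors$sequence))

  # degenerate scorers
  all_in <- score_space(constant_ensemble(0.9), wt, max_subs = 1L,
                        threshold = 0.8)
  expect_equal(nrow(all_in$survivors), all_in$n_scored)
  none <- score_space(constant_ensemble(0.1), wt, max_subs = 1L,
                      threshold = 0.8)
  expect_equal(nrow(none$survivors), 0L)
})

test_that("position frequency matrices tally residues exactly", {
  pfm1 <- position_frequency_matrix("MLPGL")
  expect_equal(dim(pfm1), c(20L, 5L))
  expect_equal(pfm1["M", 1], 1)
  expect_equal(colSums(pfm1), stats::setNames(rep(1, 5), 1:5))

  pfm2 <- position_frequency_matrix(c("AA", "AC"))
  expect_equal(pfm2["A", 1], 1)
  expect_equal(pfm2["A", 2], 0.5)
  expect_equal(pfm2["C", 2], 0.5)

  set.seed(51)
  seqs <- vapply(1:1000, function(i) random_sequence(7), character(1))
  pfm <- position_frequency_matrix(seqs)
  chars <- t(vapply(strsplit(seqs, ""), identity, character(7)))
  for (j in 1:7) {
    tally <- table(factor(chars[, j], levels = aa_alphabet())) / 1000
    expect_equal(unname(pfm[, j]), as.numeric(tally))
  }
  expect_true(all(abs(colSums(pfm) - 1) < 1e-9))
  expect_equal(attr(pfm, "n_sequences"), 1000L)

  expect_error(position_frequency_matrix(c("AA", "AAA")), "same length")
})

test_that("candidate selection enforces position and residue rules", {
  wt <- wt_signal_peptide()
  survivors <- tibble::tibble(
    sequence = c("MLKGLALLLLAAWTARA",   # P3K: allowed
                 "MLRGLALLLLAAWKARA",   # P3R + T14K: allowed
                 "MLPGLALLKLAAWTARA",   # L9K: wrong position
                 "MLDGLALLLLAAWTARA",   # P3D: wrong residue
                 "MLHGLALLLLAAWTARA"),  # P3H: allowed
    score = c(0.9, 0.95, 0.99, 0.99, 0.9)
  )
  picked <- select_candidates(survivors, wt)
  expect_equal(picked$sequence,
               c("MLRGLALLLLAAWKARA",
                 "MLHGLALLLLAAWTARA",   # ties at 0.9 break lexicographically
                 "MLKGLALLLLAAWTARA"))
  expect_equal(picked$rank, 1:3)

  none <- survivors[3:4, ]
  expect_warning(out <- select_candidates(none, wt), "no survivors")
  expect_equal(nrow(out), 0L)
})
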