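test_that("sliding windows match direct substring extraction", {
  w <- slice_windows("MLPGLALLLLAAWTARA")
  expect_equal(nrow(w), 9L)
  expect_equal(w$window[1], "MLPGLALLL")
  expect_equal(w$window[9], "LLAAWTARA")
  expect_equal(w$offset, 0:8)

  # width == length -> identity
  w1 <- slice_windows("MLPGLALLL")
  expect_equal(w1$window, "MLPGLALLL")

  # window count law against brute force for a range of lengths
  set.seed(1)
  for (L in c(9, 10, 17, 50, 123, 200)) {
    s <- random_sequence(L)
    w <- slice_windows(s)
    expect_equal(nrow(w), L - 8L)
    brute <- vapply(1:(L - 8), function(i) substr(s, i, i + 8), character(1))
    expect_equal(w$window, brute)
  }
})

test_that("first window plus trailing residues reconstructs the source", {
  set.seed(2)
  s <- random_sequence(40)
  w <- slice_windows(s)
  rebuilt <- paste0(w$window[1],
                    paste(substr(w$window[-1], 9, 9), collapse = ""))
  expect_equal(rebuilt, s)
})

test_that("padding is C-terminal and validates its inputs", {
  expect_equal(pad_peptide("MLPGL"), "MLPGL----")
  expect_equal(pad_peptide("MLPGLALLL"), "MLPGLALLL")
  expect_error(pad_peptide(""), "empty")
  expect_error(pad_peptide("MLPGLALLLL"), "longer")
  expect_equal(slice_windows("MLPGL")$window, character(0))
})

test_that("fragment datasets slice, pad, deduplicate and resolve conflicts", {
  peps <- tibble::tibble(
    id = c("p10", "p5"),
    sequence = c("MLPGLALLLL", "KRKRH"),
    label = c(1L, 1L)
  )
  ds <- fragment_peptides(peps)
  expect_equal(sum(ds$source_id == "p10"), 2L)        # 10 - 9 + 1
  expect_equal(ds$window[ds$source_id == "p5"], "KRKRH----")

  # two CPPs sharing a 9-mer: the window appears once
  shared <- tibble::tibble(
    id = c("a", "b"),
    sequence = c("MLPGLALLLL", "LPGLALLLLK"),  # share "LPGLALLLL"
    label = c(1L, 1L)
  )
  ds2 <- fragment_peptides(shared)
  expect_equal(anyDuplicated(ds2$window), 0L)
  expect_true("LPGLALLLL" %in% ds2$window)
  expect_equal(nrow(ds2), 3L)

  # a window in both a CPP and a non-CPP is dropped from both
  clash <- tibble::tibble(
    id = c("cpp", "non"),
    sequence = c("MLPGLALLL", "MLPGLALLL"),
    label = c(1L, 0L)
  )
  ds3 <- fragment_peptides(clash)
  expect_equal(nrow(ds3), 0L)
  expect_equal(fragment_counts(ds3)$n_conflicts, 1L)
})

test_that("the curated length gate excludes peptides outside 5-38 aa", {
  peps <- tibble::tibble(
    id = c("ok", "short", "long"),
    sequence = c("MLPGLALLL", "MLP", strrep("A", 39)),
    label = c(1L, 1L, 0L)
  )
  expect_message(ds <- fragment_peptides(peps), "2 peptide")
  expect_equal(unique(ds$source_id), "ok")
  expect_equal(fragment_counts(ds)$n_excluded_peptides, 2L)
})

test_that("fragmenting is idempotent on its own output", {
  set.seed(3)
  peps <- generate_labelled_peptides(generator_config(50, 50, seed = 3))
  ds <- fragment_peptides(peps)
  again <- fragment_peptides(tibble::tibble(id = ds$window,
                                            sequence = ds$window,
                                            label = ds$label))
  expect_setequal(again$window, ds$window)
  expect_equal(nrow(again), nrow(ds))
  expect_equal(dplyr::arrange(again[, c("window", "label")], window),
               dplyr::arrange(ds[, c("window", "label")], window))
})

test_that("proteome negatives enumerate, deduplicate and exclude positives", {
  one <- tibble::tibble(id = "p", sequence = "MLPGLALLL")
  ds <- build_proteome_negatives(one)
  expect_equal(nrow(ds), 1L)
  expect_equal(ds$label, 0L)

  ds2 <- build_proteome_negatives(one, positive_windows = "MLPGLALLL")
  expect_equal(nrow(ds2), 0L)

  # a protein containing a positive window verbatim drops just that window
  prot <- tibble::tibble(id = "q", sequence = "AMLPGLALLLK")
  ds3 <- build_proteome_negatives(prot, positive_windows = "MLPGLALLL")
  expect_equal(nrow(ds3), 2L)
  expect_false("MLPGLALLL" %in% ds3$window)

  expect_error(build_proteome_negatives(tibble::tibble(id = character(0),
                                                       sequence = character(0))),
               "empty proteome")
})

test_that("mock proteome fragments match brute-force window sets", {
  cfg <- generator_config(n_proteins = 100L,
                          protein_length_range = c(100L, 100L), seed = 4L)
  proteome <- generate_mock_proteome(cfg)
  ds <- build_proteome_negatives(proteome)
  expect_lte(nrow(ds), 100 * 92)
  brute <- unique(unlist(lapply(proteome$sequence, function(s) {
    vapply(1:92, function(i) substr(s, i, i + 8), character(1))
  })))
  expect_equal(nrow(ds), length(brute))
  expect_setequal(ds$window, brute)
})

test_that("hamming-1 exclusion removes near-positive windows", {
  prot <- tibble::tibble(id = "p", sequence = "MLPGLALLL")
  near <- "MLPGLALLK"  # distance 1 from the protein's only window
  ds <- build_proteome_negatives(prot, positive_windows = near,
                                 exclude_hamming = 1L)
  expect_equal(nrow(ds), 0L)
})

test_that("merged datasets dedup globally with curated precedence", {
  curated <- fragment_peptides(tibble::tibble(
    id = "c", sequence = "MLPGLALLL", label = 1L))
  proteome <- build_proteome_negatives(tibble::tibble(
    id = "p", sequence = "AMLPGLALLL"))  # contains the positive window
  merged <- merge_fragment_datasets(curated, proteome)
  expect_equal(anyDuplicated(merged$window), 0L)
  expect_equal(merged$label[merged$window == "MLPGLALLL"], 1L)
})

test_that("fragment datasets round trip through TSV", {
  ds <- fragment_peptides(tibble::tibble(
    id = c("a", "b"), sequence = c("MLPGLALLLL", "KRKRH"),
    label = c(1L, 0L)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fragments(ds, path)
  back <- read_fragments(path)
  expect_equal(back$window, ds$window)
  expect_equal(back$label, ds$label)
  expect_equal(fragment_counts(back)$n_positive,
               fragment_counts(ds)$n_positive)
})
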