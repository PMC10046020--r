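test_that("confusion counts partition inputs with ties predicted positive", {
  cm <- confusion(c(1, 0), c(0.9, 0.1))
  expect_equal(cm, list(tp = 1L, fp = 0L, tn = 1L, fn = 0L))

  # score exactly at the threshold predicts positive
  cm_tie <- confusion(c(1, 0), c(0.5, 0.5))
  expect_equal(cm_tie$tp, 1L)
  expect_equal(cm_tie$fp, 1L)

  set.seed(60)
  labels <- rbinom(1000, 1, 0.4)
  scores <- runif(1000)
  cm_big <- confusion(labels, scores, threshold = 0.3)
  brute <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  for (i in 1:1000) {
    pred <- scores[i] >= 0.3
    if (pred && labels[i] == 1) brute["tp"] <- brute["tp"] + 1L
    if (pred && labels[i] == 0) brute["fp"] <- brute["fp"] + 1L
    if (!pred && labels[i] == 0) brute["tn"] <- brute["tn"] + 1L
    if (!pred && labels[i] == 1) brute["fn"] <- brute["fn"] + 1L
  }
  expect_equal(unlist(cm_big), brute)
  expect_equal(sum(unlist(cm_big)), 1000L)

  expect_error(confusion(c(1, 0), 0.5), "equal length")
})

test_that("AUC equals exhaustive positive/negative pair counting", {
  expect_equal(auc_score(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)

  set.seed(61)
  labels <- rbinom(200, 1, 0.5)
  scores <- round(runif(200), 2)  # rounding forces ties
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  expect_equal(auc_score(labels, scores), wins / (length(pos) * length(neg)))

  expect_error(auc_score(c(1, 1), c(0.4, 0.6)), "both classes")
})

test_that("AUC behaves like a rank statistic", {
  # labels independent of scores concentrate near 1/2
  set.seed(62)
  labels <- rbinom(10000, 1, 0.5)
  scores <- runif(10000)
  expect_equal(auc_score(labels, scores), 0.5, tolerance = 0.02 / 0.5)

  # antisymmetry under score negation for tie-free scores
  set.seed(63)
  labels2 <- rbinom(300, 1, 0.5)
  scores2 <- runif(300)
  expect_equal(auc_score(labels2, scores2) + auc_score(labels2, -scores2), 1)
})

test_that("MCC follows the standard formula with the zero convention", {
  expect_equal(mcc_score(10, 0, 10, 0), 1)
  expect_equal(mcc_score(0, 10, 0, 10), -1) # perfectly inverted classifier
  expect_equal(mcc_score(10, 10, 0, 0), 0)  # all predicted positive -> 0

  # oracle: Pearson correlation of the underlying binary vectors
  set.seed(64)
  for (rep in 1:500) {
    cm <- as.list(stats::setNames(sample(0:10, 4, replace = TRUE),
                                  c("tp", "fp", "tn", "fn")))
    labels <- rep(c(1, 1, 0, 0), times = c(cm$tp, cm$fn, cm$fp, cm$tn))
    preds <- rep(c(1, 0, 1, 0), times = c(cm$tp, cm$fn, cm$fp, cm$tn))
    got <- mcc_score(cm$tp, cm$fp, cm$tn, cm$fn)
    if (stats::sd(labels) > 0 && stats::sd(preds) > 0) {
      expect_equal(got, stats::cor(labels, preds), tolerance = 1e-12)
    } else {
      expect_equal(got, 0)
    }
  }
})

test_that("metric formulas reproduce hand-computed values on a count grid", {
  grid <- expand.grid(tp = c(0, 1, 2, 10), fp = c(0, 1, 2, 10),
                      tn = c(0, 1, 2, 10), fn = c(0, 1, 2, 10))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    n <- g$tp + g$fp + g$tn + g$fn
    if (n == 0) next
    labels <- rep(c(1, 1, 0, 0), times = c(g$tp, g$fn, g$fp, g$tn))
    scores <- rep(c(0.9, 0.1, 0.9, 0.1), times = c(g$tp, g$fn, g$fp, g$tn))
    if (length(unique(labels)) < 2) next
    m <- evaluate_predictions(labels, scores)
    expect_equal(m$acc, (g$tp + g$tn) / n)
    expect_equal(m$sen,
                 if (g$tp + g$fn == 0) NA_real_ else g$tp / (g$tp + g$fn))
    expect_equal(m$spe,
                 if (g$tn + g$fp == 0) NA_real_ else g$tn / (g$tn + g$fp))
    expect_equal(m$pre,
                 if (g$tp + g$fp == 0) NA_real_ else g$tp / (g$tp + g$fp))
    expect_equal(m$mcc, mcc_score(g$tp, g$fp, g$tn, g$fn))
    expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(g$tp, g$fp, g$tn, g$fn))
  }
})

test_that("full reports are internally consistent and permutation invariant", {
  labels <- c(1, 1, 1, 0, 0, 0)
  perfect <- evaluate_predictions(labels, c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1))
  for (metric in c("auc", "acc", "sen", "spe", "pre", "mcc")) {
    expect_equal(perfect[[metric]], 1)
  }
  inverted <- evaluate_predictions(labels, c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9))
  expect_equal(inverted$auc, 0)
  expect_equal(inverted$mcc, -1)

  set.seed(65)
  labels2 <- rbinom(100, 1, 0.5)
  scores2 <- runif(100)
  perm <- sample(100)
  m1 <- evaluate_predictions(labels2, scores2)
  m2 <- evaluate_predictions(labels2[perm], scores2[perm])
  expect_equal(glance(m1), glance(m2))

  row <- glance(m1)
  expect_equal(row$acc, (row$tp + row$tn) / row$n)
  expect_equal(row$sen, row$tp / (row$tp + row$fn))
  expect_equal(row$spe, row$tn / (row$tn + row$fp))
  expect_equal(row$pre, row$tp / (row$tp + row$fp))
})

test_that("metrics agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(66)
  labels <- rbinom(150, 1, 0.5)
  scores <- runif(150)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_score(labels, scores), ref, tolerance = 1e-12)
})

test_that("peptide-level evaluation scores through the window mean rule", {
  ens <- untrained_ensemble()
  all_peps <- small_peptides()
  peps <- all_peps[c(1:20, 101:120), ]  # both classes represented
  m <- evaluate_peptides(peps, ens)
  scored <- attr(m, "scores")
  expect_equal(scored$score,
               vapply(peps$sequence, function(s) peptide_score(ens, s),
                      numeric(1), USE.NAMES = FALSE))
  expect_equal(m$n, 40L)
  expect_equal(m$auc, auc_score(scored$label, scored$score))
})
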