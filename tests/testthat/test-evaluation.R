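# CASP-style evaluation: confusion counts, rates, ROC/AUC, bootstrap
# standard errors and dataset composition.

test_that("confusion counts follow the threshold rule with X as ordered", {
  perfect <- confusion(c(0.9, 0.1, 0.8, 0.2), c("D", "O", "D", "O"))
  expect_equal(perfect, c(tp = 2, fp = 0, tn = 2, fn = 0))
  inverted <- confusion(c(0.1, 0.9, 0.2, 0.8), c("D", "O", "D", "O"))
  expect_equal(inverted, c(tp = 0, fp = 2, tn = 0, fn = 2))
  scores <- c(rep(0.9, 2), rep(0.1, 7), 0.2)
  labels <- c("D", "D", rep("O", 7), "D")
  expect_equal(confusion(scores, labels)[["fn"]], 1)
  # a label string works too, and the count identity holds
  cc <- confusion(c(0.6, 0.4, 0.5), "DOX")
  expect_equal(sum(cc), 3)
  expect_equal(cc[["tp"]], 1)
  expect_equal(cc[["fp"]], 1)  # X at threshold counts as a false positive
  expect_error(confusion(c(0.5), "DO"), "length")
})

test_that("rates reproduce published-table arithmetic", {
  # a confusion table built to give sens 0.5970 and spec 0.8989 exactly
  counts <- c(tp = 5970, fn = 4030, tn = 8989, fp = 1011)
  r <- rates(counts)
  expect_equal(r[["sens"]], 0.5970)
  expect_equal(r[["spec"]], 0.8989)
  expect_equal(round(100 * r[["acc_balanced"]], 2), 74.80)
  expect_equal(round(100 * r[["sw"]], 2), 49.59)
  # identities hold for arbitrary counts
  set.seed(2)
  for (i in 1:10) {
    cc <- c(tp = rpois(1, 40) + 1, fp = rpois(1, 20), tn = rpois(1, 60) + 1,
            fn = rpois(1, 10))
    r <- rates(cc)
    expect_equal(r[["acc_balanced"]], (r[["sens"]] + r[["spec"]]) / 2)
    expect_equal(r[["sw"]], 2 * r[["acc_balanced"]] - 1)
    expect_true(r[["sw"]] >= -1 && r[["sw"]] <= 1)
  }
  # the naive all-ordered classifier sits at balanced accuracy 0.5
  naive <- rates(confusion(rep(0, 100), c(rep("D", 7), rep("O", 93))))
  expect_equal(naive[["acc_balanced"]], 0.5)
  expect_equal(naive[["f_measure"]], 0)  # undefined precision reported as 0
  # perfect prediction saturates every rate
  perf <- rates(c(tp = 10, fp = 0, tn = 90, fn = 0))
  expect_equal(unname(perf), c(1, 1, 1, 1, 1))
  expect_error(rates(c(tp = 0, fp = 0, tn = 5, fn = 0)), "sensitivity")
})

test_that("trapezoidal AUC equals exhaustive pair counting", {
  hand <- roc_auc(c(0.9, 0.8, 0.3, 0.1), c("D", "O", "D", "O"))
  expect_equal(hand$auc, 0.75)
  expect_equal(roc_auc(c(1, 0, 1, 0), c("D", "O", "D", "O"))$auc, 1.0)
  expect_equal(roc_auc(rep(0.4, 6), c("D", "O", "D", "O", "O", "D"))$auc, 0.5)
  set.seed(13)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    labels <- ifelse(runif(n) < 0.3, "D", "O")
    scores <- round(runif(n), 2)  # heavy ties
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc,
                 auc_by_pair_counting(scores, labels), tolerance = 1e-12)
  }
  expect_error(roc_auc(c(0.1, 0.9), c("O", "O")), "at least one")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  scores <- runif(300)
  labels <- ifelse(runif(300) < plogis(3 * (scores - 0.5)), "D", "O")
  ref <- suppressMessages(
    as.numeric(pROC::auc(pROC::roc(labels == "D", scores, quiet = TRUE))))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-10)
})

test_that("threshold sweep of the confusion table is monotone", {
  set.seed(19)
  scores <- runif(150)
  labels <- ifelse(runif(150) < 0.2, "D", "O")
  prev <- confusion(scores, labels, 0)
  for (thr in seq(0.1, 1, by = 0.1)) {
    cur <- confusion(scores, labels, thr)
    expect_lte(cur[["tp"]], prev[["tp"]])
    expect_lte(cur[["fp"]], prev[["fp"]])
    prev <- cur
  }
})

test_that("X residues with low scores affect only the negative counts", {
  scores <- c(0.9, 0.2, 0.7, 0.1)
  labels <- c("D", "O", "D", "O")
  base <- confusion(scores, labels)
  withx <- confusion(c(scores, 0.05, 0.01), c(labels, "X", "X"))
  expect_equal(withx[["tp"]], base[["tp"]])
  expect_equal(withx[["fn"]], base[["fn"]])
  expect_equal(withx[["tn"]], base[["tn"]] + 2)
  expect_equal(withx[["fp"]], base[["fp"]])
})

test_that("bootstrap SE is zero for constant metrics and shrinks with size", {
  labels_small <- c(rep("D", 30), rep("O", 170))
  scores_small <- ifelse(labels_small == "D", runif(200, 0.3, 1),
                         runif(200, 0, 0.7))
  const_metric <- function(s, l) 1
  set.seed(23)
  expect_equal(as.numeric(bootstrap_se(scores_small, labels_small,
                                       const_metric, reps = 100)), 0)
  auc_metric <- function(s, l) roc_auc(s, l)$auc
  set.seed(23)
  se_small <- bootstrap_se(scores_small, labels_small, auc_metric,
                           reps = 200)
  labels_big <- rep(labels_small, 10)
  scores_big <- rep(scores_small, 10)
  set.seed(23)
  se_big <- bootstrap_se(scores_big, labels_big, auc_metric, reps = 200)
  expect_lt(as.numeric(se_big), as.numeric(se_small) / 1.5)
  # determinism
  set.seed(7); a <- bootstrap_se(scores_small, labels_small, auc_metric,
                                 reps = 50)
  set.seed(7); b <- bootstrap_se(scores_small, labels_small, auc_metric,
                                 reps = 50)
  expect_identical(a, b)
})

test_that("undefined resamples are redrawn and reported", {
  # only one positive: 80% subsamples often miss it and must be redrawn
  labels <- c("D", rep("O", 9))
  scores <- c(0.9, runif(9, 0, 0.5))
  auc_metric <- function(s, l) roc_auc(s, l)$auc
  set.seed(3)
  expect_message(bootstrap_se(scores, labels, auc_metric, reps = 30),
                 "redrawn")
})

test_that("dataset composition reproduces printed-count percentages", {
  comp <- dataset_composition(n_disordered = 13909, n_ordered = 201703)
  expect_equal(round(comp[["pct_disordered"]], 2), 6.45)
  comp9 <- dataset_composition(n_disordered = 2427, n_ordered = 23656)
  expect_equal(round(comp9[["pct_disordered"]], 2), 9.30)
  comp10 <- dataset_composition(n_disordered = 1597, n_ordered = 22673)
  expect_equal(round(comp10[["pct_disordered"]], 2), 6.58)
  recs <- list(protein_record("a", "MKVLA", "DDOXO"),
               protein_record("b", "WRN", "OOD"))
  comp_r <- dataset_composition(recs)
  expect_equal(comp_r[["n_disordered"]], 3)
  expect_equal(comp_r[["n_ordered"]], 5)  # X counts as not disordered
  empty <- dataset_composition(n_disordered = 0, n_ordered = 0)
  expect_true(is.na(empty[["pct_disordered"]]))
})

test_that("evaluation reports are internally consistent and serialisable", {
  set.seed(29)
  labels <- paste(ifelse(runif(120) < 0.2, "D", "O"), collapse = "")
  lab_chars <- strsplit(labels, "")[[1]]
  scores <- ifelse(lab_chars == "D", runif(120, 0.4, 1), runif(120, 0, 0.6))
  tracks <- list(score_track("p1", scores))
  rep_df <- evaluation_report(tracks, list(p1 = labels), reps = 30)
  cc <- confusion(scores, lab_chars)
  r <- rates(cc)
  expect_equal(rep_df$ACC, 100 * r[["acc_balanced"]])
  expect_equal(rep_df$Sw, 100 * r[["sw"]])
  expect_equal(rep_df$AUC, roc_auc(scores, lab_chars)$auc)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_evaluation_report(rep_df, path)
  back <- read.delim(path)
  expect_equal(ncol(back), 13)
  expect_equal(back$SENS, 100 * r[["sens"]], tolerance = 1e-3)
})
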