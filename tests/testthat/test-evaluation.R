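# Brute-force oracles for the metric formulas.
auc_oracle <- function(scores, labels) {
  sp <- scores[labels == "positive"]; sn <- scores[labels == "negative"]
  total <- 0
  for (a in sp) for (b in sn) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(sp) * length(sn))
}
mcc_oracle <- function(tp, fp, tn, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}

test_that("metrics evaluate the defining formulas exactly", {
  perfect <- classification_metrics(tp = 5, fp = 0, tn = 5, fn = 0)
  expect_equal(perfect, list(sn = 1, sp = 1, acc = 1, mcc = 1))

  m <- classification_metrics(tp = 130, fp = 21, tn = 134, fn = 25)
  expect_equal(m$acc, 264 / 310)
  expect_equal(m$sn, 130 / 155)
  expect_equal(m$sp, 134 / 155)
  expect_equal(m$mcc, 16895 / sqrt(151 * 155 * 155 * 159))

  # everything called positive: MCC denominator vanishes -> 0 by convention
  all_pos <- classification_metrics(tp = 10, fp = 10, tn = 0, fn = 0)
  expect_equal(all_pos$mcc, 0)
  expect_error(classification_metrics(0, 0, 0, 0), class = "casid_input_error")
})

test_that("metrics and AUC match brute-force oracles on random instances", {
  withr::with_seed(101, {
    for (i in 1:100) {
      n <- sample(4:50, 1)
      counts <- as.vector(stats::rmultinom(1, n, runif(4)))
      if (sum(counts) == 0) next
      m <- classification_metrics(counts[1], counts[2], counts[3], counts[4])
      expect_equal(m$mcc, mcc_oracle(counts[1], counts[2], counts[3], counts[4]),
                   tolerance = 1e-12)

      labels <- c(rep("positive", sample(2:25, 1)), rep("negative", sample(2:25, 1)))
      scores <- round(runif(length(labels)), sample(c(1, 3), 1))  # force ties sometimes
      expect_equal(roc_auc(scores, labels)$auc, auc_oracle(scores, labels),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with an established implementation", {
  withr::with_seed(55, {
    labels <- rep(c("positive", "negative"), each = 30)
    scores <- rnorm(60, mean = ifelse(labels == "positive", 0.8, 0.2), sd = 0.4)
  })
  ours <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("negative", "positive"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("ROC curves are valid paths and AUC is rank-invariant", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c("positive", "positive", "negative", "negative"))$auc, 1)
  expect_equal(roc_auc(rep(0.4, 6), rep(c("positive", "negative"), 3))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1),
                       c("positive", "positive", "negative", "negative"))$auc, 0.75)

  withr::with_seed(77, {
    scores <- runif(40)
    labels <- sample(rep(c("positive", "negative"), 20))
  })
  ra <- roc_auc(scores, labels)
  expect_equal(ra$roc$fpr[1], 0); expect_equal(ra$roc$tpr[1], 0)
  expect_equal(ra$roc$fpr[nrow(ra$roc)], 1)
  expect_equal(ra$roc$tpr[nrow(ra$roc)], 1)
  expect_true(all(diff(ra$roc$fpr) >= 0) && all(diff(ra$roc$tpr) >= 0))
  # strictly increasing transforms leave the AUC unchanged
  expect_equal(roc_auc(exp(3 * scores), labels)$auc, ra$auc)
  expect_error(roc_auc(c(1, 2), c("positive", "positive")),
               class = "casid_protocol_error")
})

test_that("chi-square on call rates matches the direct O/E computation", {
  res <- chi_square_rates(46, 64, 6, 64)
  # oracle: sum (O - E)^2 / E with expected counts from the margins
  O <- rbind(c(46, 18), c(6, 58))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$statistic, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_lt(res$p_value, 0.05)

  even <- chi_square_rates(10, 20, 10, 20)
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)

  swapped <- chi_square_rates(6, 64, 46, 64)
  expect_equal(swapped$statistic, res$statistic)

  yates <- chi_square_rates(46, 64, 6, 64, correct = TRUE)
  expect_lt(yates$statistic, res$statistic)

  expect_error(chi_square_rates(0, 10, 0, 10), class = "casid_protocol_error")
  expect_error(chi_square_rates(5, 0, 1, 10), class = "casid_input_error")
})

test_that("nested k-fold is leakage-checked, reproducible and internally consistent", {
  ds <- toy_dataset(seed = 61, n = 15)
  cfg <- list(k = 3, ranking_method = "f_score", seed = 9,
              grid = grid_spec(log2c = c(3, 11), log2gamma = c(3, 9), folds = 3),
              per_k_grid = FALSE, k_grid = c(10, 50, 400), grid_subset = 50,
              folds_inner = 3)
  r1 <- do.call(nested_kfold, c(list(ds), cfg))
  r2 <- do.call(nested_kfold, c(list(ds), cfg))
  expect_identical(r1, r2)   # bit-reproducible end to end

  expect_length(r1$per_fold, 3)
  with(r1$counts, expect_equal(tp + fp + tn + fn, nrow(ds)))
  m <- classification_metrics(r1$counts$tp, r1$counts$fp, r1$counts$tn, r1$counts$fn)
  expect_equal(r1$sn, m$sn, tolerance = 1e-12)
  expect_equal(r1$sp, m$sp, tolerance = 1e-12)
  expect_equal(r1$acc, m$acc, tolerance = 1e-12)

  # equal-sized folds: pooled accuracy is the mean of fold accuracies
  accs <- vapply(r1$per_fold, `[[`, 0, "acc")
  sizes <- vapply(r1$per_fold, `[[`, 0, "n_test")
  if (length(unique(sizes)) == 1) expect_equal(r1$acc, mean(accs))
  expect_equal(r1$acc_mean_folds, mean(accs))

  # strong planted signal is recovered by the nested protocol
  expect_gte(r1$acc, 0.9)

  expect_error(nested_kfold(ds, k = 16), class = "casid_protocol_error")
})

test_that("leave-one-out reduces to singleton test folds and nails separable data", {
  feat_seqs <- c("ACACACACACAC", "ACACACACACCA", "CACACACACACA",
                 "DFDFDFDFDFDF", "DFDFDFDFDFFD", "FDFDFDFDFDFD")
  ds <- casid:::cas_dataset(sprintf("s%d", 1:6), feat_seqs,
                            rep(c("positive", "negative"), each = 3), "sep")
  rep <- loo_cv(ds, ranking_method = "f_score", seed = 3,
                grid = grid_spec(log2c = 3, log2gamma = c(3, 9), folds = 2),
                k_grid = c(10, 400), folds_inner = 2, per_k_grid = FALSE)
  expect_length(rep$per_fold, 6)
  expect_true(all(vapply(rep$per_fold, `[[`, 0, "n_test") == 1))
  expect_equal(rep$acc, 1)
})

test_that("evaluation reports serialize to JSON and ROC TSV", {
  ds <- toy_dataset(seed = 61, n = 15)
  rep <- nested_kfold(ds, k = 3, ranking_method = "f_score", seed = 9,
                      grid = grid_spec(log2c = 3, log2gamma = 3, folds = 3),
                      per_k_grid = FALSE, k_grid = 50, folds_inner = 3)
  js <- withr::local_tempfile(fileext = ".json")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_eval_json(rep, js)
  write_roc_tsv(rep, tsv)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$acc, rep$acc)
  expect_equal(back$counts$tp, rep$counts$tp)
  roc <- utils::read.delim(tsv)
  expect_equal(nrow(roc), nrow(rep$roc))
})
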