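#' Classification metrics from confusion counts
#'
#' Sensitivity Sn = TP/(TP+FN), specificity Sp = TN/(TN+FP), accuracy
#' Acc = (TP+TN)/(TP+FN+FP+TN) and the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). When any
#' factor of the MCC denominator is zero the coefficient is undefined and is
#' reported as 0 (the standard convention for degenerate confusion tables).
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return List with `sn`, `sp`, `acc`, `mcc`.
#' @examples
#' classification_metrics(tp = 130, fp = 21, tn = 134, fn = 25)
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  total <- tp + fp + tn + fn
  if (total == 0) stop_input("empty evaluation: all confusion counts are zero")
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(sn = tp / (tp + fn),
       sp = tn / (tn + fp),
       acc = (tp + tn) / total,
       mcc = if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom))
}

#' ROC curve and AUC from scores
#'
#' The AUC is the probability that a randomly chosen positive sample scores
#' higher than a randomly chosen negative sample, with ties counted one
#' half: AUC = (#\{score+ > score-\} + 0.5 #\{ties\}) / (n+ n-). The ROC
#' curve is built by sweeping a threshold over the distinct scores; it
#' starts at (0, 0), ends at (1, 1) and is non-decreasing in both
#' coordinates.
#'
#' @param scores Numeric vector of positive-class scores or probabilities.
#' @param labels Parallel vector/factor of `positive`/`negative` truth.
#' @return List with `roc` (data frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- factor(as.character(labels), levels = c("positive", "negative"))
  if (anyNA(labels) || anyNA(scores))
    stop_input("scores/labels contain missing values")
  np <- sum(labels == "positive"); nn <- sum(labels == "negative")
  if (np == 0 || nn == 0)
    stop_protocol("ROC needs at least one positive and one negative label")
  # Rank-sum form of the pair-counting definition (midranks handle ties).
  r <- rank(scores)
  auc <- (sum(r[labels == "positive"]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(scores, decreasing = TRUE)
  tps <- cumsum(labels[ord] == "positive")
  fps <- cumsum(labels[ord] == "negative")
  last <- cumsum(rle(scores[ord])$lengths)  # one ROC point per distinct score
  roc <- data.frame(fpr = c(0, fps[last] / nn), tpr = c(0, tps[last] / np))
  list(roc = roc, auc = auc)
}

# Assemble an eval_report from pooled held-out decisions.
new_eval_report <- function(truth, prob, call, per_fold = NULL, seed = NA,
                            acc_mean_folds = NULL) {
  truth <- factor(as.character(truth), levels = c("positive", "negative"))
  counts <- list(tp = sum(call == "positive" & truth == "positive"),
                 fp = sum(call == "positive" & truth == "negative"),
                 tn = sum(call == "negative" & truth == "negative"),
                 fn = sum(call == "negative" & truth == "positive"))
  m <- classification_metrics(counts$tp, counts$fp, counts$tn, counts$fn)
  ra <- roc_auc(prob, truth)
  structure(list(counts = counts, sn = m$sn, sp = m$sp, acc = m$acc,
                 mcc = m$mcc, roc = ra$roc, auc = ra$auc,
                 acc_mean_folds = if (is.null(acc_mean_folds)) m$acc
                                  else acc_mean_folds,
                 per_fold = per_fold, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report: Acc %.4f (mean over folds %.4f), ",
                     "Sn %.4f, Sp %.4f, MCC %.4f, AUC %.4f>\n"),
              x$acc, x$acc_mean_folds, x$sn, x$sp, x$mcc, x$auc))
  invisible(x)
}

#' Nested k-fold cross-validation of the full pipeline
#'
#' The leakage-free protocol: the dataset is split into k stratified outer
#' folds; for each fold, feature ranking, incremental feature selection and
#' the (C, gamma) grid search are recomputed on the k-1 training folds only,
#' a model is fit and the held-out fold is scored. The report gives the mean
#' of per-fold accuracies (`acc_mean_folds`) plus Sn/Sp/Acc/MCC and ROC/AUC
#' computed on the pooled held-out decisions.
#'
#' @param ds A labeled `cas_dataset`.
#' @param k Number of outer folds (default 10). `k = nrow(ds)` gives the
#'   leave-one-out protocol.
#' @param ranking_method `"f_score"`, `"impurity"`, or `"none"` (no
#'   selection: all 400 features with a grid search only).
#' @param seed Integer seed governing all fold assignments.
#' @param grid [grid_spec()] for the inner grid searches.
#' @param per_k_grid Passed to the inner incremental search; see
#'   [coarse_incremental_search()].
#' @param k_grid Candidate subset sizes for the inner search (default
#'   10, 20, ..., 400).
#' @param n_trees Forest size when `ranking_method = "impurity"`.
#' @param folds_inner Inner CV folds (default 5).
#' @param grid_subset Fast-mode grid restriction; see
#'   [coarse_incremental_search()].
#' @return An `eval_report` with one `per_fold` entry per outer fold
#'   (`acc`, `n_test`, `k_selected`, `c`, `gamma`).
#' @details Held-out samples are called by the SVM's class prediction; the
#'   ROC curve and AUC are computed from the held-out decision values (the
#'   AUC is exactly the probability that a positive sample's decision value
#'   exceeds a negative sample's).
#' @export
nested_kfold <- function(ds, k = 10,
                         ranking_method = c("f_score", "impurity", "none"),
                         seed = 1, grid = grid_spec(), per_k_grid = TRUE,
                         k_grid = seq(10, 400, by = 10), n_trees = 500,
                         folds_inner = 5, grid_subset = NULL) {
  ranking_method <- match.arg(ranking_method)
  features <- encode_dataset(ds)
  y <- check_labeled(features, if (k == nrow(ds)) 3 else k)
  fold_id <- make_folds(y, k, seed)
  n <- nrow(features$x)
  dv <- rep(NA_real_, n)
  call <- rep(NA_character_, n)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    te <- which(fold_id == f)
    tr <- which(fold_id != f)
    ftr <- features_subset(features, tr)
    s <- sub_seed(seed, f)
    sel <- fold_selection(ftr, ranking_method, k_grid, folds_inner, s, grid,
                          per_k_grid, n_trees, grid_subset)
    fit <- fit_svm(ftr$x[, sel$selected, drop = FALSE], ftr$labels,
                   sel$c, sel$gamma)
    p <- predict(fit, features$x[te, sel$selected, drop = FALSE],
                 decision.values = TRUE)
    d <- attr(p, "decision.values")
    # orient decision values so larger = more positive-class
    if (colnames(d)[1] == "negative/positive") d <- -d
    dv[te] <- d[, 1]
    call[te] <- as.character(p)
    per_fold[[f]] <- list(fold = f, n_test = length(te),
                          acc = mean(call[te] == as.character(y[te])),
                          k_selected = length(sel$selected),
                          c = sel$c, gamma = sel$gamma)
  }
  new_eval_report(y, dv, call, per_fold = per_fold, seed = seed,
                  acc_mean_folds = mean(vapply(per_fold, `[[`, 0, "acc")))
}

# Per-outer-fold model selection for the three ranking configurations.
fold_selection <- function(ftr, ranking_method, k_grid, folds_inner, seed,
                           grid, per_k_grid, n_trees, grid_subset = NULL) {
  if (ranking_method == "none") {
    gs <- grid_search(ftr, grid = grid, seed = seed)
    return(list(selected = seq_len(ncol(ftr$x)), c = gs$c, gamma = gs$gamma,
                inner_cv_accuracy = gs$cv_accuracy))
  }
  ranking <- switch(ranking_method,
    f_score = f_score_ranking(ftr),
    impurity = impurity_ranking(ftr, n_trees = n_trees, seed = seed))
  incremental_search(ftr, ranking, k_grid, folds_inner, seed, grid,
                     per_k_grid, grid_subset)
}

#' Leave-one-out nested cross-validation
#'
#' The n-fold limit of [nested_kfold()]: every sample is held out once and
#' the full selection pipeline is re-run on the remaining n-1. Because the
#' protocol repeats the grid search n times, the reduced step-4 grid is the
#' default here.
#'
#' @inheritParams nested_kfold
#' @export
loo_cv <- function(ds, ranking_method = c("f_score", "impurity", "none"),
                   seed = 1, grid = reduced_grid(), per_k_grid = FALSE,
                   k_grid = seq(10, 400, by = 10), folds_inner = 5,
                   grid_subset = NULL) {
  nested_kfold(ds, k = nrow(ds), ranking_method = match.arg(ranking_method),
               seed = seed, grid = grid, per_k_grid = per_k_grid,
               k_grid = k_grid, folds_inner = folds_inner,
               grid_subset = grid_subset)
}

#' Chi-square comparison of two positive-call rates
#'
#' Pearson chi-square test (1 df, no continuity correction by default) on
#' the 2x2 table of positive/negative calls in two sets, e.g. the rate of
#' Cas calls on an independent "positive" set versus a negative set.
#'
#' @param pos_calls,pos_total Positive calls and set size for the first set.
#' @param neg_calls,neg_total Same for the second set.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return List with `statistic`, `p_value`, `table`.
#' @export
chi_square_rates <- function(pos_calls, pos_total, neg_calls, neg_total,
                             correct = FALSE) {
  if (pos_total <= 0 || neg_total <= 0 ||
      pos_calls > pos_total || neg_calls > neg_total)
    stop_input("calls must satisfy 0 <= calls <= total with total > 0")
  tbl <- rbind(c(pos_calls, pos_total - pos_calls),
               c(neg_calls, neg_total - neg_calls))
  if (any(colSums(tbl) == 0))
    stop_protocol("degenerate 2x2 table: a column marginal is zero")
  ct <- stats::chisq.test(tbl, correct = correct)
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       table = tbl)
}

#' Serialize an evaluation report
#'
#' `write_eval_json()` stores the full report; `write_roc_tsv()` exports
#' the ROC points for plotting.
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @export
write_eval_json <- function(report, path) {
  out <- report[c("counts", "sn", "sp", "acc", "mcc", "acc_mean_folds",
                  "auc", "seed")]
  out$per_fold <- report$per_fold
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_eval_json
#' @export
write_roc_tsv <- function(report, path) {
  utils::write.table(report$roc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
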