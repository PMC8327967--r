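#' Hyperparameter grid for the RBF-kernel SVM
#'
#' Default ranges follow the common libsvm grid-search convention:
#' log2(C) from -5 to 15 in steps of 2 and log2(gamma) from -15 to 3 in
#' steps of 2, scored by stratified k-fold cross-validation accuracy.
#'
#' @param log2c,log2gamma Numeric sequences of candidate log2 values.
#' @param folds Number of stratified CV folds used to score each point.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(log2c = seq(-5, 15, by = 2),
                      log2gamma = seq(-15, 3, by = 2),
                      folds = 5) {
  if (length(log2c) == 0 || length(log2gamma) == 0)
    stop_input("grid ranges must be non-empty")
  structure(list(log2c = log2c, log2gamma = log2gamma, folds = folds),
            class = "grid_spec")
}

#' Reduced grid (log2 step 4) for expensive protocols
#'
#' A coarser 6 x 5 grid used by default for leave-one-out protocols and
#' other settings where the full grid is prohibitive.
#' @inheritParams grid_spec
#' @export
reduced_grid <- function(folds = 5) {
  grid_spec(log2c = seq(-5, 15, by = 4), log2gamma = seq(-15, 3, by = 4),
            folds = folds)
}

#' Minimal screening grid for bounded-compute runs
#'
#' A 2 x 2 subgrid of the default ranges (log2 C in \{3, 11\}, log2 gamma in
#' \{-3, 3\}) spanning moderate and large values of both hyperparameters.
#' Used by the package's own test and acceptance runs, where the full grid
#' would dominate the compute budget; results with it are hyperparameter
#' screens, not exhaustive optimizations.
#' @inheritParams grid_spec
#' @export
screening_grid <- function(folds = 5) {
  grid_spec(log2c = c(3, 11), log2gamma = c(-3, 3), folds = folds)
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into k folds. k equal to the sample count gives
# leave-one-out (singleton folds).
make_folds <- function(labels, k, seed) {
  n <- length(labels)
  if (k == n) return(seq_len(n))
  tab <- table(labels)
  if (any(tab < k))
    stop_protocol(sprintf("each class needs >= %d members for %d-fold CV", k, k))
  folds <- integer(n)
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Fit one RBF SVM; DPC values already share the [0,1] scale, so no feature
# scaling is applied anywhere in the package.
fit_svm <- function(x, y, cost, gamma, probability = FALSE) {
  if (nlevels(droplevels(y)) < 2)
    stop_protocol("cannot train an SVM on a single-class dataset")
  e1071::svm(x = x, y = y, scale = FALSE, kernel = "radial",
             cost = cost, gamma = gamma, probability = probability)
}

# k-fold CV accuracy of an RBF SVM at fixed (cost, gamma) over given folds.
cv_accuracy <- function(x, y, fold_id, cost, gamma) {
  correct <- 0L
  for (f in unique(fold_id)) {
    te <- fold_id == f
    fit <- fit_svm(x[!te, , drop = FALSE], droplevels(y[!te]), cost, gamma)
    pred <- predict(fit, x[te, , drop = FALSE])
    correct <- correct + sum(as.character(pred) == as.character(y[te]))
  }
  correct / length(y)
}

# Exhaustive grid scan over precomputed folds. Scan order is descending
# log2c, then descending log2gamma; a strictly better accuracy replaces the
# incumbent, so ties resolve to the larger log2c, then larger log2gamma.
grid_search_folds <- function(x, y, fold_id, grid) {
  best <- list(c = NA_real_, gamma = NA_real_, cv_accuracy = -1)
  for (lc in sort(grid$log2c, decreasing = TRUE)) {
    for (lg in sort(grid$log2gamma, decreasing = TRUE)) {
      acc <- cv_accuracy(x, y, fold_id, 2^lc, 2^lg)
      if (acc > best$cv_accuracy)
        best <- list(c = 2^lc, gamma = 2^lg, cv_accuracy = acc)
    }
  }
  best
}

#' Grid search for SVM hyperparameters
#'
#' Scores every (C, gamma) point of the grid by stratified k-fold
#' cross-validation accuracy on the selected feature columns and returns
#' the best point. The scan order is fixed (descending log2 C, then
#' descending log2 gamma) and ties keep the first point encountered, so
#' results are deterministic given the seed.
#'
#' @param features A labeled `dpc_features` object.
#' @param feature_idx Integer indices of the feature columns to use
#'   (default: all).
#' @param grid A [grid_spec()].
#' @param seed Integer seed governing the fold assignment.
#' @return List with elements `c`, `gamma`, `cv_accuracy`.
#' @export
grid_search <- function(features, feature_idx = seq_len(ncol(features$x)),
                        grid = grid_spec(), seed = 1) {
  y <- check_labeled(features, grid$folds)
  fold_id <- make_folds(y, grid$folds, seed)
  grid_search_folds(features$x[, feature_idx, drop = FALSE], y, fold_id, grid)
}

check_labeled <- function(features, min_per_class = 2) {
  y <- features$labels
  if (is.null(y)) stop_input("features carry no labels")
  if (any(table(y) < min_per_class))
    stop_protocol(sprintf("each class needs >= %d samples", min_per_class))
  y
}

#' Train the final RBF-SVM model bundle
#'
#' Fits an RBF-kernel soft-margin SVM on the feature columns chosen by an
#' incremental search, with the (C, gamma) found there, and Platt-style
#' probability calibration enabled. The bundle records the frozen dipeptide
#' ordering, the selected feature names, the decision threshold and
#' provenance, and is self-contained for prediction.
#'
#' @param features Labeled `dpc_features` of the training set.
#' @param selection A `selection_result` from [coarse_incremental_search()]
#'   or [fine_incremental_search()], or a list with `selected`, `c`,
#'   `gamma`.
#' @param threshold Positive-call probability threshold in (0, 1);
#'   default 0.5. A record is called positive when its positive-class
#'   probability is greater than or equal to the threshold.
#' @param seed Seed recorded in provenance and used for the probability
#'   calibration's internal cross-validation.
#' @param name Training-set name recorded in provenance.
#' @return An object of class `cas_model`.
#' @export
svm_train <- function(features, selection, threshold = 0.5, seed = 1,
                      name = "training") {
  y <- check_labeled(features)
  if (length(selection$selected) == 0) stop_input("empty feature selection")
  if (!(threshold > 0 && threshold < 1))
    stop_input("threshold must lie strictly between 0 and 1")
  sel <- selection$selected
  machine <- with_seed(seed, fit_svm(features$x[, sel, drop = FALSE], y,
                                     selection$c, selection$gamma,
                                     probability = TRUE))
  structure(list(
    feature_indices = sel,
    feature_names = dipeptide_names()[sel],
    c = selection$c, gamma = selection$gamma,
    machine = machine, threshold = threshold,
    dipeptide_order = dipeptide_names(),
    provenance = list(dataset = name, n = nrow(features$x), seed = seed,
                      inner_cv_accuracy = selection$inner_cv_accuracy,
                      r_version = as.character(getRversion()),
                      e1071_version = as.character(utils::packageVersion("e1071")))
  ), class = "cas_model")
}

#' @export
print.cas_model <- function(x, ...) {
  cat(sprintf(paste0("<cas_model: %d dipeptide features, C = %g, gamma = %g, ",
                     "threshold = %g>\n"),
              length(x$feature_indices), x$c, x$gamma, x$threshold))
  invisible(x)
}

#' Score protein sequences with a trained model
#'
#' Computes the positive-class (Cas) probability of each record and calls it
#' positive when the probability reaches the bundle threshold. Records that
#' cannot be encoded (too short, ambiguous residues) are returned as
#' unscorable rows with the reason in `note`, never silently dropped.
#'
#' @param object A `cas_model`.
#' @param newdata A `protein_set`, `cas_dataset`, or data frame with `id`
#'   and `sequence` columns.
#' @param ... Unused.
#' @return Data frame with columns `id`, `probability`, `call`
#'   (`"positive"`/`"negative"`/`NA`), `note`.
#' @export
predict.cas_model <- function(object, newdata, ...) {
  if (is.character(newdata))
    newdata <- data.frame(id = if (is.null(names(newdata)))
      sprintf("query_%d", seq_along(newdata)) else names(newdata),
      sequence = unname(newdata), stringsAsFactors = FALSE)
  if (nrow(newdata) == 0) stop_input("no records to score")
  reason <- vapply(newdata$sequence, sequence_problem, character(1))
  ok <- which(reason == "")
  prob <- rep(NA_real_, nrow(newdata))
  if (length(ok) > 0) {
    x <- t(vapply(newdata$sequence[ok], compute_dpc, numeric(400)))
    x <- x[, object$feature_indices, drop = FALSE]
    p <- predict(object$machine, x, probability = TRUE)
    prob[ok] <- attr(p, "probabilities")[, "positive"]
  }
  call <- ifelse(is.na(prob), NA_character_,
                 ifelse(prob >= object$threshold, "positive", "negative"))
  data.frame(id = newdata$id, probability = prob, call = call,
             note = ifelse(reason == "", "", paste0("unscorable: ", reason)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Save / load a model bundle
#'
#' The machine state is serialized to `path` and a human-readable JSON
#' metadata sidecar (`<path>.json`) records the selected dipeptides,
#' hyperparameters, threshold and provenance.
#'
#' @param model A `cas_model`.
#' @param path File path for the bundle.
#' @return `path` (`save_model`) or the restored `cas_model` (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cas_model"))
  saveRDS(model, path)
  meta <- model[c("feature_indices", "feature_names", "c", "gamma",
                  "threshold", "provenance")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("no model bundle at '%s'", path))
  model <- readRDS(path)
  if (!inherits(model, "cas_model"))
    stop_validation(sprintf("'%s' is not a cas_model bundle", path))
  model
}
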