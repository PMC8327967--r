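# Independent oracle: the F-score formula evaluated directly per column.
fscore_oracle <- function(x, y) {
  pos <- y == "positive"
  apply(x, 2, function(col) {
    num <- (mean(col[pos]) - mean(col))^2 + (mean(col[!pos]) - mean(col))^2
    den <- var(col[pos]) + var(col[!pos])
    if (den == 0) { if (num > 0) Inf else 0 } else num / den
  })
}

test_that("F-score matches the hand formula, including degenerate columns", {
  feat <- make_features(list(c(0.9, 1.1, -0.1, 0.1)),
                        c("positive", "positive", "negative", "negative"))
  r <- f_score_ranking(feat)
  expect_equal(r$scores[1], 12.5)          # 0.5 / 0.04
  expect_equal(r$order[1], 1)
  # constant-everywhere columns score 0, ties broken by ascending index
  expect_true(all(r$scores[-1] == 0))
  expect_equal(r$order[-1], 2:400)

  # constant within class, shifted between classes -> Inf, ranked first
  feat2 <- make_features(list(c(0.9, 1.1, -0.1, 0.1), c(1, 1, 0, 0)),
                         c("positive", "positive", "negative", "negative"))
  r2 <- f_score_ranking(feat2)
  expect_identical(r2$scores[2], Inf)
  expect_equal(r2$order[1:2], c(2, 1))
})

test_that("F-score agrees with the oracle on random matrices and is label-symmetric", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(6:20, 1)
      y <- factor(sample(rep(c("positive", "negative"), c(ceiling(n / 2), floor(n / 2)))),
                  levels = c("positive", "negative"))
      x <- matrix(runif(n * 400), n, 400)
      feat <- structure(list(x = x, labels = y, ids = as.character(1:n),
                             dipeptides = dipeptide_names()),
                        class = "dpc_features")
      r <- f_score_ranking(feat)
      expect_equal(r$scores, unname(fscore_oracle(x, y)), tolerance = 1e-12)

      swapped <- feat
      swapped$labels <- factor(ifelse(y == "positive", "negative", "positive"),
                               levels = c("positive", "negative"))
      expect_equal(f_score_ranking(swapped)$scores, r$scores, tolerance = 1e-12)
    }
  })
})

test_that("F-score is invariant to affine rescaling of a feature column", {
  feat <- toy_features(seed = 9, n = 10)
  base <- f_score_ranking(feat)$scores
  shifted <- feat; shifted$x[, 17] <- shifted$x[, 17] + 3.2
  scaled <- feat; scaled$x[, 17] <- scaled$x[, 17] * 41
  expect_equal(f_score_ranking(shifted)$scores, base, tolerance = 1e-9)
  expect_equal(f_score_ranking(scaled)$scores, base, tolerance = 1e-9)
})

test_that("F-score requires two samples per class", {
  feat <- make_features(list(c(1, 0, 0)),
                        c("positive", "negative", "negative"))
  expect_error(f_score_ranking(feat), class = "casid_protocol_error")
})

test_that("impurity ranking finds a decisive feature and is seed-deterministic", {
  withr::with_seed(5, {
    y <- rep(c("positive", "negative"), each = 15)
    decisive <- ifelse(y == "positive", 1, 0) + rnorm(30, 0, 0.01)
  })
  feat <- make_features(list(decisive), y)
  feat$x[, 2:400] <- matrix(withr::with_seed(6, runif(30 * 399)), 30, 399)
  r1 <- impurity_ranking(feat, n_trees = 100, seed = 123)
  expect_equal(r1$order[1], 1)
  r2 <- impurity_ranking(feat, n_trees = 100, seed = 123)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$order, r2$order)
})

test_that("selected subset is always a prefix of the ranking", {
  feat <- toy_features(seed = 13, n = 15)
  ranking <- f_score_ranking(feat)
  sel <- coarse_incremental_search(feat, ranking, seed = 1,
                                   grid = screening_grid(),
                                   per_k_grid = FALSE, grid_subset = 50)
  expect_identical(sel$selected, ranking$order[seq_len(sel$k)])
  expect_true(sel$inner_cv_accuracy >= 0 && sel$inner_cv_accuracy <= 1)
})

test_that("informative prefix scores at least as well as the full feature set", {
  # top-ranked features carry all the signal; adding 390 noise columns
  # should not materially help
  ds <- generate_fixture(fixture_spec(n_per_class = 100,
                                      length_range = c(120, 180),
                                      bias_pairs = default_bias_pairs()[1:10],
                                      delta = 5, seed = 77))
  feat <- encode_dataset(ds)
  ranking <- f_score_ranking(feat)
  one_point <- grid_spec(log2c = 3, log2gamma = 3)
  acc_at <- function(k) casid:::incremental_search(
    feat, ranking, k_grid = k, seed = 4, grid = one_point)$inner_cv_accuracy
  expect_gte(acc_at(10), acc_at(400) - 0.02)
})

test_that("ties in subset-size accuracy resolve to the smallest k", {
  feat <- toy_features(seed = 21, n = 12, delta = 8)
  ranking <- f_score_ranking(feat)
  one_point <- grid_spec(log2c = 3, log2gamma = 3)
  sel <- casid:::incremental_search(feat, ranking, k_grid = c(50, 100),
                                    seed = 2, grid = one_point)
  sel_sub <- casid:::incremental_search(feat, ranking, k_grid = 50,
                                        seed = 2, grid = one_point)
  if (sel_sub$inner_cv_accuracy == sel$inner_cv_accuracy)
    expect_equal(sel$k, 50)
  # single feasible candidate is returned as-is
  only400 <- casid:::incremental_search(feat, ranking, k_grid = 400,
                                        seed = 2, grid = one_point)
  expect_equal(only400$k, 400)
})

test_that("a larger candidate set never yields a worse optimum", {
  feat <- toy_features(seed = 8, n = 12)
  ranking <- f_score_ranking(feat)
  one_point <- grid_spec(log2c = 3, log2gamma = 3)
  small <- casid:::incremental_search(feat, ranking, k_grid = c(10, 100),
                                      seed = 3, grid = one_point)
  large <- casid:::incremental_search(feat, ranking,
                                      k_grid = c(10, 50, 100, 200),
                                      seed = 3, grid = one_point)
  expect_gte(large$inner_cv_accuracy, small$inner_cv_accuracy)
})

test_that("fine search degenerates to k = 1 on data separable by the top feature", {
  feat <- make_features(list(c(rep(1, 6), rep(0, 6))),
                        rep(c("positive", "negative"), each = 6))
  feat$x[, 2:400] <- matrix(withr::with_seed(14, runif(12 * 399)), 12, 399)
  ranking <- f_score_ranking(feat)
  sel <- fine_incremental_search(feat, ranking, folds = 3, seed = 5,
                                 grid = grid_spec(log2c = c(3, 11),
                                                  log2gamma = c(3, 9),
                                                  folds = 3),
                                 per_k_grid = FALSE, grid_subset = 5)
  expect_equal(sel$k, 1)
  expect_equal(sel$inner_cv_accuracy, 1)
})

test_that("selection results serialize with dipeptide names", {
  feat <- toy_features(seed = 4, n = 10)
  sel <- coarse_incremental_search(feat, f_score_ranking(feat), seed = 1,
                                   grid = screening_grid(),
                                   per_k_grid = FALSE, grid_subset = 50)
  js <- withr::local_tempfile(fileext = ".json")
  write_selection_json(sel, js)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$selected_features, dipeptide_names()[sel$selected])
  expect_equal(back$c, sel$c)
  expect_equal(back$gamma, sel$gamma)
})
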