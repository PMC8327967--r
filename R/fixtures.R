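#' Default dipeptide bias set for the synthetic generator
#'
#' Fifteen fixed dipeptides whose transition mass is inflated in the
#' positive class. The set is arbitrary but frozen, so generated benchmarks
#' are comparable across runs and machines.
#'
#' @return Character vector of 15 dipeptides.
#' @export
default_bias_pairs <- function() {
  c("AL", "LK", "KD", "DE", "EG", "GR", "RI", "IV", "VN",
    "NS", "ST", "TL", "LE", "ER", "RA")
}

#' Specification for a synthetic two-class sequence benchmark
#'
#' Defines a benchmark in which the two classes differ only in dipeptide
#' frequencies — exactly the signal a dipeptide-composition classifier can
#' see. Negatives are drawn from a uniform first-order Markov chain over the
#' 20 residues; positives from a chain whose transition mass into each bias
#' pair (a, b) is multiplied by (1 + delta) and renormalized.
#'
#' The defaults (155 sequences per class, lengths 100-500, 15 bias pairs at
#' delta = 0.65) emulate a Cas-sized training set whose class separation is
#' moderate rather than trivial: with expected per-cell dipeptide counts of
#' roughly (L-1)/400 per sequence, delta = 0.65 over 15 pairs puts the
#' aggregate class separability in the range where a well-tuned classifier
#' is clearly better than chance but far from perfect, comparable in
#' difficulty to distinguishing real Cas from non-Cas proteins.
#'
#' @param n_per_class Sequences per class.
#' @param length_range Integer min/max sequence length (min >= 2); one
#'   shared length distribution is used for both classes (lengths are drawn
#'   once per index and reused, so the two classes are length-matched
#'   pairwise).
#' @param bias_pairs Either a character vector of dipeptides (all receiving
#'   strength `delta`) or a named numeric vector mapping dipeptides to
#'   individual strengths.
#' @param delta Common bias strength (ignored when `bias_pairs` is named
#'   numeric).
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_per_class = 155, length_range = c(100, 500),
                         bias_pairs = default_bias_pairs(), delta = 0.65,
                         seed = 1) {
  if (length(length_range) != 2 || length_range[1] < 2 ||
      length_range[2] < length_range[1])
    stop_input("length_range must be (min >= 2, max >= min)")
  bias <- if (is.numeric(bias_pairs)) bias_pairs
          else stats::setNames(rep(delta, length(bias_pairs)), bias_pairs)
  if (length(bias) > 0) {
    if (is.null(names(bias)) || !all(names(bias) %in% dipeptide_names()))
      stop_input("bias pairs must be valid dipeptides over the 20-letter alphabet")
    if (any(!is.finite(bias)) || any(bias < 0))
      stop_input("bias strengths must be finite and non-negative")
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 length_range = as.integer(length_range),
                 bias = bias, seed = as.integer(seed)),
            class = "fixture_spec")
}

# Positive-class 20x20 transition matrix for a spec (rows sum to 1).
bias_transition <- function(bias) {
  tm <- matrix(1 / 20, 20, 20, dimnames = list(AA20, AA20))
  for (p in names(bias)) {
    a <- substr(p, 1, 1); b <- substr(p, 2, 2)
    tm[a, b] <- tm[a, b] * (1 + bias[[p]])
  }
  tm / rowSums(tm)
}

# Sample one sequence of length L from a first-order chain (uniform start).
sample_chain <- function(L, cum_rows) {
  s <- integer(L)
  s[1] <- sample.int(20, 1)
  if (L > 1) {
    u <- runif(L - 1)
    for (i in 2:L) s[i] <- findInterval(u[i - 1], cum_rows[s[i - 1], ]) + 1L
  }
  paste(AA20[s], collapse = "")
}

#' Generate a synthetic labeled benchmark dataset
#'
#' @param spec A [fixture_spec()].
#' @param name Dataset name; also used as the id prefix so multiple
#'   generated sets can coexist without id collisions.
#' @return A `cas_dataset` with `n_per_class` positives followed by
#'   `n_per_class` negatives. Every generated sequence satisfies the
#'   20-letter, length >= 2 record invariants by construction.
#' @examples
#' ds <- generate_fixture(fixture_spec(n_per_class = 20, seed = 7))
#' table(ds$label)
#' @export
generate_fixture <- function(spec, name = "fixture") {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_per_class
  pos_cum <- t(apply(bias_transition(spec$bias), 1, cumsum))[, 1:19, drop = FALSE]
  neg_cum <- t(apply(matrix(1 / 20, 20, 20), 1, cumsum))[, 1:19, drop = FALSE]
  with_seed(spec$seed, {
    lens <- sample(spec$length_range[1]:spec$length_range[2], n, replace = TRUE)
    pos <- vapply(lens, sample_chain, character(1), cum_rows = pos_cum)
    neg <- vapply(lens, sample_chain, character(1), cum_rows = neg_cum)
    cas_dataset(c(sprintf("%s_pos_%03d", name, seq_len(n)),
                  sprintf("%s_neg_%03d", name, seq_len(n))),
                c(pos, neg),
                rep(c("positive", "negative"), each = n),
                name = name)
  })
}

#' Synthetic stand-ins for the study datasets
#'
#' Builds, from the generator alone, the four datasets the evaluation
#' protocols expect, at the canonical sizes of a curated Cas benchmark:
#' \describe{
#'   \item{train}{155 + 155 training sequences,}
#'   \item{independent}{64 + 64 independent test sequences drawn from the
#'     same two distributions,}
#'   \item{eval_train / eval_test}{a 148 + 148 / 7 + 7 hold-out split of the
#'     training set (7 positives and 7 negatives removed at random), used to
#'     probe whether a model can recognise positives it never saw).}
#' }
#' All sequences are synthetic; none are real Cas proteins.
#'
#' @param seed Integer seed.
#' @param spec Base [fixture_spec()]; `n_per_class` and `seed` are
#'   overridden per dataset.
#' @return Named list of `cas_dataset`s: `train`, `independent`,
#'   `eval_train`, `eval_test`.
#' @export
synthetic_study <- function(seed = 1, spec = fixture_spec()) {
  tr_spec <- spec; tr_spec$n_per_class <- 155L; tr_spec$seed <- sub_seed(seed, 1)
  in_spec <- spec; in_spec$n_per_class <- 64L;  in_spec$seed <- sub_seed(seed, 2)
  train <- generate_fixture(tr_spec, name = "train")
  independent <- generate_fixture(in_spec, name = "indep")
  split <- with_seed(sub_seed(seed, 3), {
    pos <- which(train$label == "positive")
    neg <- which(train$label == "negative")
    sort(c(sample(pos, 7), sample(neg, 7)))
  })
  list(train = train,
       independent = independent,
       eval_train = dataset_subset(train, setdiff(seq_len(nrow(train)), split),
                                   name = "eval_train"),
       eval_test = dataset_subset(train, split, name = "eval_test"))
}

#' Validate and package externally supplied study datasets
#'
#' Takes FASTA files for the curated study datasets, checks each against the
#' record counts a Cas benchmark of this design must have (155/155 training,
#' 64/64 independent, 148/148 evaluation-training, 7/7 evaluation-testing
#' per class) and writes canonical FASTA fixtures.
#'
#' @param paths Named list of FASTA paths; recognised names are
#'   `train_pos`, `train_neg`, `independent_pos`, `independent_neg`,
#'   `eval_train_pos`, `eval_train_neg`, `eval_test_pos`, `eval_test_neg`.
#'   Any subset may be given.
#' @param out_dir Directory for the canonical fixtures.
#' @return Named list of `cas_dataset`s (one per provided pos/neg pair),
#'   invisibly.
#' @export
package_supplements <- function(paths, out_dir) {
  expected <- c(train_pos = 155, train_neg = 155,
                independent_pos = 64, independent_neg = 64,
                eval_train_pos = 148, eval_train_neg = 148,
                eval_test_pos = 7, eval_test_neg = 7)
  unknown <- setdiff(names(paths), names(expected))
  if (length(unknown) > 0)
    stop_input(sprintf("unrecognised dataset name(s): %s",
                       paste(unknown, collapse = ", ")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (nm in names(paths)) {
    recs <- read_fasta(paths[[nm]], strict = TRUE)
    if (nrow(recs) != expected[[nm]])
      stop_validation(sprintf("'%s': expected %d records, found %d",
                              nm, expected[[nm]], nrow(recs)))
    write_fasta(recs, file.path(out_dir, paste0(nm, ".fasta")))
  }
  sets <- unique(sub("_(pos|neg)$", "", names(paths)))
  for (s in sets) {
    p <- paste0(s, "_pos"); n <- paste0(s, "_neg")
    if (all(c(p, n) %in% names(paths)))
      out[[s]] <- load_labeled(file.path(out_dir, paste0(p, ".fasta")),
                               file.path(out_dir, paste0(n, ".fasta")),
                               name = s)
  }
  invisible(out)
}
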