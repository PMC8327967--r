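# Small in-code fixtures shared across test files.

# Benchmark-comparison blocks report every deviation from the published
# figures individually; never cut the run short because several of them
# fail together.
options(testthat.progress.max_fails = Inf)

# Strong-signal toy benchmark: two classes cleanly separated in dipeptide
# space, small enough that SVM fits are instantaneous.
toy_dataset <- function(seed = 42, n = 20, delta = 5, len = c(60, 120)) {
  generate_fixture(fixture_spec(n_per_class = n, length_range = len,
                                delta = delta, seed = seed),
                   name = sprintf("toy%d", seed))
}

toy_features <- function(...) encode_dataset(toy_dataset(...))

# Hand-built feature container: a matrix padded to 400 columns.
make_features <- function(cols, labels, fill = 0.5) {
  n <- length(labels)
  x <- matrix(fill, nrow = n, ncol = 400,
              dimnames = list(sprintf("s%02d", seq_len(n)), dipeptide_names()))
  for (j in seq_along(cols)) x[, j] <- cols[[j]]
  structure(list(x = x,
                 labels = factor(labels, levels = c("positive", "negative")),
                 ids = rownames(x), dipeptides = dipeptide_names()),
            class = "dpc_features")
}

# Write a FASTA file from id/sequence vectors, with optional dialect quirks.
write_test_fasta <- function(path, ids, seqs, width = NULL, eol = "\n") {
  lines <- character(0)
  for (i in seq_along(ids)) {
    body <- if (is.null(width)) seqs[i] else
      vapply(seq(1, nchar(seqs[i]), width), function(s)
        substr(seqs[i], s, min(s + width - 1, nchar(seqs[i]))), "")
    lines <- c(lines, paste0(">", ids[i]), body)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = eol)
  path
}

# The bounded search configuration used for protocol-scale tests: screening
# grid, thinned subset-size ladder, shared grid search on the top-100
# ranked features.
bounded <- list(grid = screening_grid(),
                k_grid = c(10, 25, 50, 100, 200, 400),
                grid_subset = 100)
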