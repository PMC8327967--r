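#' The canonical dipeptide index
#'
#' The 400 ordered amino-acid pairs in row-major alphabetical order
#' (`AA`, `AC`, ..., `AY`, `CA`, ..., `YY`): pair (a, b) sits at position
#' `20 * rank(a) + rank(b) + 1` with residues ranked alphabetically in
#' `ACDEFGHIKLMNPQRSTVWY`. This ordering is frozen and serialized with
#' every model so that feature indices remain portable.
#'
#' @return Character vector of length 400.
#' @export
dipeptide_names <- function() {
  as.vector(t(outer(AA20, AA20, paste0)))
}

#' Dipeptide composition of one protein sequence
#'
#' Encodes a sequence as the 400-vector of dipeptide frequencies: entry i is
#' the number of overlapping occurrences of the i-th dipeptide divided by
#' the total number of dipeptide windows, L - 1 for a sequence of length L.
#' The vector is non-negative and sums to one.
#'
#' @param sequence A single amino-acid sequence (character scalar over the
#'   20-letter alphabet), or a one-row `protein_set`.
#' @return Named numeric vector of length 400 (names from
#'   [dipeptide_names()]).
#' @examples
#' compute_dpc("ACAC")[c("AC", "CA")]  # 2/3 and 1/3
#' @export
compute_dpc <- function(sequence) {
  if (is.data.frame(sequence)) {
    stopifnot(nrow(sequence) == 1)
    sequence <- sequence$sequence
  }
  stopifnot(is.character(sequence), length(sequence) == 1)
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  if (L < 2) stop_input("sequence too short: need length >= 2 to form a dipeptide")
  r <- match(chars, AA20)
  if (anyNA(r))
    stop_validation(sprintf("non-standard residue(s): %s",
                            paste(unique(chars[is.na(r)]), collapse = ", ")))
  idx <- 20L * (r[-L] - 1L) + r[-1L]
  counts <- tabulate(idx, nbins = 400L)
  stats::setNames(counts / (L - 1), dipeptide_names())
}

#' Encode a dataset as a dipeptide-composition feature matrix
#'
#' @param ds A `cas_dataset` (labeled) or `protein_set` (unlabeled).
#' @return An object of class `dpc_features`: list with `x` (n x 400 matrix,
#'   rows named by record id, columns by dipeptide), `labels` (factor or
#'   `NULL`) and `ids`.
#' @export
encode_dataset <- function(ds) {
  n <- nrow(ds)
  x <- matrix(0, nrow = n, ncol = 400,
              dimnames = list(ds$id, dipeptide_names()))
  for (i in seq_len(n)) {
    x[i, ] <- tryCatch(compute_dpc(ds$sequence[i]), casid_error = function(e)
      stop_casid(sprintf("record '%s': %s", ds$id[i], conditionMessage(e)),
                 class(e)[1]))
  }
  structure(list(x = x, labels = ds$label, ids = ds$id,
                 dipeptides = dipeptide_names()),
            class = "dpc_features")
}

#' @export
print.dpc_features <- function(x, ...) {
  cat(sprintf("<dpc_features: %d x %d%s>\n", nrow(x$x), ncol(x$x),
              if (is.null(x$labels)) "" else sprintf(
                ", labeled (%d positive / %d negative)",
                sum(x$labels == "positive"), sum(x$labels == "negative"))))
  invisible(x)
}

#' Export a feature matrix as TSV for inspection
#'
#' @param features A `dpc_features` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dpc_tsv <- function(features, path) {
  df <- data.frame(id = features$ids,
                   label = if (is.null(features$labels)) NA
                           else as.character(features$labels),
                   features$x, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Subset a dpc_features by row index.
features_subset <- function(features, idx) {
  structure(list(x = features$x[idx, , drop = FALSE],
                 labels = if (!is.null(features$labels)) features$labels[idx],
                 ids = features$ids[idx], dipeptides = features$dipeptides),
            class = "dpc_features")
}
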