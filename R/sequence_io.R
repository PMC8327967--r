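#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly multi-line, possibly CRLF-terminated) FASTA file of
#' amino-acid sequences. Sequences are uppercased and a single trailing stop
#' character `*` is stripped before validation. A valid record has a length
#' of at least 2 (so at least one dipeptide exists) and contains only the
#' 20 standard residues `ACDEFGHIKLMNPQRSTVWY`; ambiguity codes such as
#' `X`, `B` or `Z` are rejected, mirroring the dataset filters used to
#' curate Cas training sets.
#'
#' @param path Path to a FASTA file.
#' @param strict If `TRUE` (default) any invalid record aborts the read with
#'   a validation error naming the record and the offending residue. If
#'   `FALSE`, invalid records are dropped; the returned object carries a
#'   `skipped` attribute (a data frame of id and reason) describing them, so
#'   a batch prediction can report them as unscorable instead of failing.
#' @return A data frame with columns `id` and `sequence`, in file order,
#'   of class `protein_set`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "ACDEF", ">p2", "MKVL"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop_input(sprintf("cannot read FASTA file '%s'", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_input(sprintf(
                    "failed to parse '%s' as FASTA: %s", path, conditionMessage(e))))
  if (length(set) == 0) stop_input(sprintf("no FASTA records in '%s'", path))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(gsub("[\r \t]", "", as.character(set)))
  seqs <- sub("\\*$", "", seqs)
  names(seqs) <- NULL

  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop_validation(sprintf("duplicate sequence id(s): %s",
                            paste(unique(dup), collapse = ", ")))

  reason <- vapply(seqs, sequence_problem, character(1))
  bad <- which(reason != "")
  if (length(bad) > 0 && strict)
    stop_validation(sprintf("invalid record '%s': %s", ids[bad[1]], reason[bad[1]]))
  skipped <- data.frame(id = ids[bad], reason = reason[bad],
                        stringsAsFactors = FALSE, row.names = NULL)
  keep <- setdiff(seq_along(ids), bad)
  if (length(keep) == 0) stop_input(sprintf("no valid records in '%s'", path))

  out <- data.frame(id = ids[keep], sequence = seqs[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("protein_set", "data.frame")
  attr(out, "skipped") <- skipped
  out
}

# "" if the sequence is a valid ProteinRecord body, otherwise a reason.
sequence_problem <- function(s) {
  if (nchar(s) < 2) return("sequence shorter than 2 residues")
  bad <- setdiff(unique(strsplit(s, "")[[1]]), AA20)
  if (length(bad) > 0)
    return(sprintf("non-standard residue(s): %s", paste(bad, collapse = ", ")))
  ""
}

#' Write protein sequences to a FASTA file
#'
#' @param records A `protein_set`/data frame with `id` and `sequence`
#'   columns, or a `cas_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::AAStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Load a labeled positive/negative dataset from two FASTA files
#'
#' Reads both files in strict mode and concatenates them, positives first,
#' yielding the labeled dataset layout used throughout: a balanced design
#' would have, e.g., 155 Cas proteins followed by 155 non-Cas proteins.
#'
#' @param pos_path FASTA of positive (Cas) sequences.
#' @param neg_path FASTA of negative (non-Cas) sequences.
#' @param name Dataset name recorded in provenance.
#' @return A `cas_dataset`: data frame with columns `id`, `sequence`,
#'   `label` (factor with levels `positive`, `negative`).
#' @export
load_labeled <- function(pos_path, neg_path, name = "dataset") {
  pos <- read_fasta(pos_path, strict = TRUE)
  neg <- read_fasta(neg_path, strict = TRUE)
  shared <- intersect(pos$id, neg$id)
  if (length(shared) > 0)
    stop_validation(sprintf("id(s) present in both files: %s",
                            paste(utils::head(shared, 5), collapse = ", ")))
  cas_dataset(c(pos$id, neg$id), c(pos$sequence, neg$sequence),
              rep(c("positive", "negative"), c(nrow(pos), nrow(neg))),
              name = name)
}

# Construct/validate the labeled-dataset container.
cas_dataset <- function(id, sequence, label, name = "dataset") {
  stopifnot(length(id) == length(sequence), length(id) == length(label))
  if (anyDuplicated(id))
    stop_validation("record ids must be unique within a dataset")
  out <- data.frame(id = id, sequence = sequence,
                    label = factor(label, levels = c("positive", "negative")),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (anyNA(out$label)) stop_validation("labels must be 'positive' or 'negative'")
  attr(out, "name") <- name
  class(out) <- c("cas_dataset", "data.frame")
  out
}

#' @export
print.cas_dataset <- function(x, ...) {
  cat(sprintf("<cas_dataset '%s': %d sequences (%d positive, %d negative)>\n",
              attr(x, "name"), nrow(x), sum(x$label == "positive"),
              sum(x$label == "negative")))
  invisible(x)
}

# Subset a cas_dataset by row index, keeping class and name.
dataset_subset <- function(ds, idx, name = attr(ds, "name")) {
  cas_dataset(ds$id[idx], ds$sequence[idx], as.character(ds$label[idx]), name = name)
}
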