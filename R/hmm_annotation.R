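#' Profile-HMM annotation of predicted Cas proteins
#'
#' The annotation stage mirrors the classical two-step design: sequences
#' called Cas by the SVM are searched against a collection of Cas-family
#' profile HMMs (built from seed alignments, e.g. TIGRFAMs/Pfam Cas
#' families) with `hmmscan`; a family hit corroborates the call and names
#' the family. Profile building and searching are delegated to the HMMER3
#' binaries (`hmmbuild`, `hmmpress`, `hmmscan`); this module is a wrapper
#' contract, not a reimplementation of profile-HMM algorithms.
#'
#' @name hmm-annotation
NULL

hmmer_binary <- function(tool) {
  path <- Sys.which(tool)
  if (!nzchar(path))
    stop_environment(sprintf(
      "'%s' not found on PATH; install HMMER3 (http://hmmer.org) to use the annotation stage",
      tool))
  path
}

#' Write a multiple sequence alignment in Stockholm format
#'
#' @param alignment Named character vector of aligned sequences (equal
#'   lengths; `-` or `.` for gaps).
#' @param id Family identifier written as `#=GF ID`.
#' @param path Output path.
#' @export
write_stockholm <- function(alignment, id, path) {
  if (length(alignment) == 0) stop_input("empty alignment")
  if (length(unique(nchar(alignment))) != 1)
    stop_validation("aligned sequences must have equal lengths")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# STOCKHOLM 1.0", sprintf("#=GF ID %s", id)), con)
  writeLines(sprintf("%-30s %s", names(alignment), alignment), con)
  writeLines("//", con)
  invisible(path)
}

#' Generate a synthetic protein-family seed alignment
#'
#' Builds a toy family for testing the annotation stage: a random ancestral
#' sequence is point-mutated independently in each member (no indels, so
#' the members are trivially aligned).
#'
#' @param name Family name.
#' @param n_seq Number of members.
#' @param length Alignment length.
#' @param mut_rate Per-site substitution probability.
#' @param seed Integer seed.
#' @return Named character vector of aligned sequences, with the family
#'   name in attribute `id`.
#' @export
synthetic_family_alignment <- function(name, n_seq = 8, length = 120,
                                       mut_rate = 0.1, seed = 1) {
  with_seed(seed, {
    root <- sample(AA20, length, replace = TRUE)
    seqs <- vapply(seq_len(n_seq), function(i) {
      s <- root
      mut <- runif(length) < mut_rate
      s[mut] <- sample(AA20, sum(mut), replace = TRUE)
      paste(s, collapse = "")
    }, character(1))
    structure(stats::setNames(seqs, sprintf("%s_m%02d", name, seq_len(n_seq))),
              id = name)
  })
}

#' Build a pressed profile-HMM collection from seed alignments
#'
#' Runs `hmmbuild` (default parameters) on each Stockholm seed alignment,
#' concatenates the profiles into one database and formats it with
#' `hmmpress` for `hmmscan`. Optionally writes a per-family gathering (GA)
#' bit-score threshold into each profile, so the collection can be searched
#' in gathering-threshold mode like curated Pfam/TIGRFAMs profiles.
#'
#' @param seed_alignments Character vector of Stockholm file paths.
#' @param out_dir Directory for the database files.
#' @param gathering Optional numeric: a single bit-score threshold applied
#'   to every family, or a vector named by family. `NULL` (default) leaves
#'   profiles without GA lines.
#' @return A `profile_collection`: list with `db` (path to the pressed HMM
#'   file), `families`, `pressed`, `gathering`.
#' @export
build_collection <- function(seed_alignments, out_dir = tempfile("hmmdb"),
                             gathering = NULL) {
  if (length(seed_alignments) == 0) stop_input("no seed alignments given")
  hmmbuild <- hmmer_binary("hmmbuild")
  hmmpress <- hmmer_binary("hmmpress")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  profiles <- character(0)
  families <- character(0)
  for (aln in seed_alignments) {
    if (!file.exists(aln)) stop_input(sprintf("missing alignment file '%s'", aln))
    hmm <- file.path(out_dir, paste0(basename(aln), ".hmm"))
    log <- suppressWarnings(system2(hmmbuild,
                                    c("--amino", shQuote(hmm), shQuote(aln)),
                                    stdout = TRUE, stderr = TRUE))
    if (!is.null(attr(log, "status")))
      stop_validation(sprintf("hmmbuild failed on '%s':\n%s", aln,
                              paste(utils::tail(log, 5), collapse = "\n")))
    fam <- sub("^NAME\\s+", "", grep("^NAME", readLines(hmm), value = TRUE)[1])
    families <- c(families, fam)
    profiles <- c(profiles, hmm)
  }
  if (anyDuplicated(families))
    stop_validation(sprintf("duplicate family name(s): %s",
                            paste(unique(families[duplicated(families)]),
                                  collapse = ", ")))
  db <- file.path(out_dir, "cas_profiles.hmm")
  text <- unlist(lapply(profiles, readLines))
  if (!is.null(gathering)) {
    ga <- if (is.null(names(gathering)))
      stats::setNames(rep(gathering, length(families)), families) else gathering
    text <- inject_gathering(text, ga)
  }
  writeLines(text, db)
  for (ext in c(".h3f", ".h3i", ".h3m", ".h3p"))
    unlink(paste0(db, ext))
  log <- suppressWarnings(system2(hmmpress, shQuote(db),
                                  stdout = TRUE, stderr = TRUE))
  if (!is.null(attr(log, "status")))
    stop_validation(paste("hmmpress failed:", paste(log, collapse = "\n")))
  structure(list(db = db, families = families, pressed = TRUE,
                 gathering = gathering),
            class = "profile_collection")
}

# Insert a "GA <t> <t>;" header line into each profile of an HMM text file
# (before the STATS lines), keyed by the profile's NAME.
inject_gathering <- function(lines, ga) {
  out <- character(0)
  current <- NA_character_
  for (ln in lines) {
    if (startsWith(ln, "NAME "))
      current <- sub("^NAME\\s+", "", ln)
    if (startsWith(ln, "STATS") && !is.na(current) && current %in% names(ga)) {
      out <- c(out, sprintf("GA    %.2f %.2f;", ga[[current]], ga[[current]]))
      current <- NA_character_  # only once per profile
    }
    out <- c(out, ln)
  }
  out
}

#' @export
print.profile_collection <- function(x, ...) {
  cat(sprintf("<profile_collection: %d families%s at %s>\n",
              length(x$families),
              if (isTRUE(x$pressed)) " (pressed)" else "", x$db))
  invisible(x)
}

#' Annotate sequences against a profile-HMM collection
#'
#' Searches each record against the collection with `hmmscan` and returns
#' the ranked hits. With `use_gathering = TRUE` the scan runs in
#' gathering-threshold mode (`--cut_ga`): only hits reaching each family's
#' curated GA bit score are reported, the reliable-membership convention of
#' Pfam/TIGRFAMs. Queries with no hit are kept in the table with family
#' `"no family match"` — a positive SVM call without a family hit is a
#' putative Cas protein without family assignment, not a rejected call.
#'
#' @param collection A pressed `profile_collection`.
#' @param records A `protein_set`/`cas_dataset`/data frame with `id` and
#'   `sequence`.
#' @param use_gathering Use gathering thresholds instead of an E-value
#'   cutoff.
#' @param max_evalue Report threshold when `use_gathering = FALSE`.
#' @return Data frame with columns `query_id`, `family_name`, `e_value`,
#'   `bit_score`, `passed_gathering`; hits sorted by ascending E-value
#'   within each query.
#' @export
hmm_annotate <- function(collection, records, use_gathering = FALSE,
                         max_evalue = 10) {
  stopifnot(inherits(collection, "profile_collection"))
  if (!isTRUE(collection$pressed)) stop_input("collection is not pressed")
  if (nrow(records) == 0) stop_input("no records to annotate")
  hmmscan <- hmmer_binary("hmmscan")
  qfa <- tempfile(fileext = ".fasta")
  on.exit(unlink(qfa))
  write_fasta(records, qfa)
  tbl <- tempfile(fileext = ".tblout")
  on.exit(unlink(tbl), add = TRUE)
  args <- c("--tblout", shQuote(tbl),
            if (use_gathering) "--cut_ga" else c("-E", format(max_evalue)),
            shQuote(collection$db), shQuote(qfa))
  log <- suppressWarnings(system2(hmmscan, args, stdout = TRUE, stderr = TRUE))
  if (!is.null(attr(log, "status")))
    stop_environment(paste("hmmscan failed:",
                           paste(utils::tail(log, 5), collapse = "\n")))
  hits <- parse_tblout(tbl)
  if (use_gathering && nrow(hits) > 0) {
    hits$passed_gathering <- TRUE
  } else if (nrow(hits) > 0 && !is.null(collection$gathering)) {
    ga <- if (is.null(names(collection$gathering)))
      stats::setNames(rep(collection$gathering, length(collection$families)),
                      collection$families) else collection$gathering
    hits$passed_gathering <- hits$bit_score >= ga[hits$family_name]
  }
  missing <- setdiff(records$id, hits$query_id)
  if (length(missing) > 0)
    hits <- rbind(hits, data.frame(query_id = missing,
                                   family_name = "no family match",
                                   e_value = NA_real_, bit_score = NA_real_,
                                   passed_gathering = NA,
                                   stringsAsFactors = FALSE))
  hits <- hits[order(match(hits$query_id, records$id), hits$e_value), ]
  rownames(hits) <- NULL
  hits
}

# Parse hmmscan --tblout: whitespace-delimited; field 1 target (family),
# 3 query, 5 full-sequence E-value, 6 bit score.
parse_tblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(query_id = character(0), family_name = character(0),
                      e_value = numeric(0), bit_score = numeric(0),
                      passed_gathering = logical(0), stringsAsFactors = FALSE))
  parts <- strsplit(trimws(lines), "\\s+")
  data.frame(query_id = vapply(parts, `[[`, "", 3),
             family_name = vapply(parts, `[[`, "", 1),
             e_value = as.numeric(vapply(parts, `[[`, "", 5)),
             bit_score = as.numeric(vapply(parts, `[[`, "", 6)),
             passed_gathering = NA, stringsAsFactors = FALSE)
}

#' Combine SVM predictions with family annotation
#'
#' Produces the standard two-stage result table: every record's SVM
#' probability and call, plus for records called positive the best HMM
#' family hit (or "no family match"). Annotation never changes a call; it
#' only adds a corroborating family label.
#'
#' @param predictions Output of [predict.cas_model()].
#' @param annotation Output of [hmm_annotate()] for the positive records
#'   (may cover any subset; others get `NA`).
#' @return The `predictions` data frame with an extra `annotation` column.
#' @export
annotate_predictions <- function(predictions, annotation) {
  best <- annotation[!duplicated(annotation$query_id), ]
  fam <- stats::setNames(best$family_name, best$query_id)
  predictions$annotation <- ifelse(
    !is.na(predictions$call) & predictions$call == "positive",
    ifelse(predictions$id %in% names(fam), fam[predictions$id],
           "no family match"),
    NA_character_)
  predictions
}
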