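#' @title Quantification-table input/output and count-matrix assembly
#' @name quant_io
#' @description
#' The entry point of the pipeline is a per-run protein quantification table
#' as exported from a ProteinProphet-style search summary: one row per
#' (run, protein) identification carrying the identification probability,
#' the number of distinct supporting peptide sequences, and the spectral
#' count. These functions read and write that dialect, apply the
#' identification-probability filter, and assemble the zero-filled
#' protein-by-run spectral count matrix over the union protein set.
NULL

QUANT_COLUMNS <- c("run_id", "group", "protein_id", "probability",
                   "peptide_count", "spectral_count")
GROUP_LEVELS <- c("model", "control")

#' Read a per-run protein quantification table
#'
#' Parses a tab-separated quantification table with required columns
#' `run_id`, `group`, `protein_id`, `probability`, `peptide_count`,
#' `spectral_count`, and an optional `peptides` column holding
#' semicolon-joined distinct peptide sequences. Run metadata (group label,
#' replicate index) is derived from the embedded `group` column unless a
#' runs sidecar is supplied via `runs_path`.
#'
#' Each row is validated: `probability` must lie in \[0, 1\] and both counts
#' must be strictly positive integers. Violations raise an error citing the
#' offending file line.
#'
#' @param path Path to the quantification TSV (UTF-8, header required).
#' @param runs_path Optional path to a runs sidecar TSV with columns
#'   `run_id`, `group`, `replicate_index`.
#' @return A list with elements `records` (data.frame of identification
#'   records, one per (run, protein)) and `runs` (data.frame with columns
#'   `run_id`, `group`, `replicate_index`).
#' @seealso [write_quant_table()], [assemble_count_matrix()]
#' @export
read_quant_table <- function(path, runs_path = NULL) {
  if (!file.exists(path)) {
    stop("quantification table not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  missing_cols <- setdiff(QUANT_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("quantification table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- validate_quant_records(raw, path)
  runs <- if (!is.null(runs_path)) {
    read_runs_table(runs_path)
  } else {
    derive_runs(records)
  }
  check_records_against_runs(records, runs)
  list(records = records, runs = runs)
}

# Row-level validation; `line` is the 1-based file line (header = line 1).
validate_quant_records <- function(raw, path) {
  n <- nrow(raw)
  if (n == 0) {
    records <- data.frame(run_id = character(), group = character(),
                          protein_id = character(), probability = numeric(),
                          peptide_count = integer(), spectral_count = integer(),
                          stringsAsFactors = FALSE)
    if ("peptides" %in% names(raw)) records$peptides <- character()
    return(records)
  }
  line <- seq_len(n) + 1L
  fail <- function(what, bad) {
    stop("invalid ", what, " in ", path, " at line ",
         paste(line[bad], collapse = ", "), call. = FALSE)
  }
  prob <- suppressWarnings(as.numeric(raw$probability))
  bad <- is.na(prob) | prob < 0 | prob > 1
  if (any(bad)) fail("probability (must be a number in [0,1])", bad)
  parse_count <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- is.na(v) | v != floor(v) | v < 1
    if (any(bad)) fail(paste0(what, " (must be a positive integer)"), bad)
    as.integer(v)
  }
  pep <- parse_count(raw$peptide_count, "peptide_count")
  spec <- parse_count(raw$spectral_count, "spectral_count")
  bad <- !(raw$group %in% GROUP_LEVELS)
  if (any(bad)) fail(paste0("group (must be one of: ",
                            paste(GROUP_LEVELS, collapse = ", "), ")"), bad)
  key <- paste(raw$run_id, raw$protein_id, sep = "\r")
  if (anyDuplicated(key)) fail("duplicate (run_id, protein_id) pair",
                               duplicated(key))
  records <- data.frame(run_id = raw$run_id, group = raw$group,
                        protein_id = raw$protein_id, probability = prob,
                        peptide_count = pep, spectral_count = spec,
                        stringsAsFactors = FALSE)
  if ("peptides" %in% names(raw)) records$peptides <- raw$peptides
  records
}

# Run metadata from the embedded group column: replicate index follows
# first appearance order within each group.
derive_runs <- function(records) {
  if (nrow(records) == 0) {
    return(data.frame(run_id = character(), group = character(),
                      replicate_index = integer(),
                      stringsAsFactors = FALSE))
  }
  idx <- !duplicated(records$run_id)
  runs <- data.frame(run_id = records$run_id[idx], group = records$group[idx],
                     stringsAsFactors = FALSE)
  runs$replicate_index <- stats::ave(seq_len(nrow(runs)), runs$group,
                                     FUN = seq_along)
  validate_runs(runs)
}

#' Read a runs sidecar table
#'
#' @param path Path to a TSV with columns `run_id`, `group`,
#'   `replicate_index`.
#' @return A validated runs data.frame.
#' @export
read_runs_table <- function(path) {
  if (!file.exists(path)) {
    stop("runs table not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  needed <- c("run_id", "group", "replicate_index")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("runs table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  runs <- data.frame(run_id = raw$run_id, group = raw$group,
                     replicate_index = suppressWarnings(
                       as.integer(raw$replicate_index)),
                     stringsAsFactors = FALSE)
  validate_runs(runs)
}

validate_runs <- function(runs) {
  if (anyDuplicated(runs$run_id)) {
    stop("run_id values must be unique: ",
         paste(unique(runs$run_id[duplicated(runs$run_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(runs$group %in% GROUP_LEVELS)) {
    stop("run group labels must be one of: ",
         paste(GROUP_LEVELS, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(runs$replicate_index)) || any(runs$replicate_index < 1)) {
    stop("replicate_index must be an integer >= 1", call. = FALSE)
  }
  n_per_group <- table(factor(runs$group, levels = GROUP_LEVELS))
  if (any(n_per_group < 2)) {
    stop("each group needs at least 2 runs; got ",
         paste(sprintf("%s=%d", names(n_per_group), n_per_group),
               collapse = ", "), call. = FALSE)
  }
  runs[order(match(runs$group, GROUP_LEVELS), runs$replicate_index), ,
       drop = FALSE]
}

check_records_against_runs <- function(records, runs) {
  unknown <- setdiff(unique(records$run_id), runs$run_id)
  if (length(unknown) > 0) {
    stop("record(s) reference run_id not present in run metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a per-run protein quantification table
#'
#' Emits the same TSV dialect [read_quant_table()] parses, with
#' deterministic row order (run_id, then protein_id).
#'
#' @param records Identification-record data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(records, path) {
  cols <- QUANT_COLUMNS
  if ("peptides" %in% names(records)) cols <- c(cols, "peptides")
  out <- records[order(records$run_id, records$protein_id), cols,
                 drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a runs sidecar table
#'
#' @param runs Runs data.frame (`run_id`, `group`, `replicate_index`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_runs_table <- function(runs, path) {
  out <- runs[order(runs$run_id), c("run_id", "group", "replicate_index"),
              drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter identification records by ProteinProphet probability
#'
#' Retains exactly the records whose identification probability is
#' *strictly* greater than `threshold` (a record at exactly the threshold
#' is removed). Input order is preserved. The conventional cut-off of 0.9
#' corresponds to a protein-level false discovery rate of roughly 1% in
#' TPP output.
#'
#' @param records Identification-record data.frame.
#' @param threshold Probability cut-off in \[0, 1\]; default 0.9.
#' @return The retained records.
#' @export
filter_by_probability <- function(records, threshold = 0.9) {
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold >= 0, threshold <= 1)
  records[records$probability > threshold, , drop = FALSE]
}

#' Assemble a zero-filled spectral count matrix
#'
#' Builds the protein-by-run integer count matrix over the union of all
#' proteins identified in any run. A cell is zero exactly when the protein
#' was not identified in that run. Proteins are ordered lexicographically
#' by accession for deterministic output; runs are ordered model group
#' first, then by replicate index.
#'
#' Per-protein distinct-peptide support is aggregated across all runs in
#' which the protein was identified: when the optional `peptides` column
#' (semicolon-joined sequences) is present, support is the size of the
#' union of distinct sequences; otherwise it falls back to the maximum
#' per-run `peptide_count`.
#'
#' @param records Probability-filtered identification records.
#' @param runs Runs data.frame.
#' @return An object of class `spectral_counts`: a list with `counts`
#'   (integer matrix, proteins x runs, dimnames set), `runs` (data.frame)
#'   and `peptide_support` (named integer vector).
#' @seealso [compute_scw()], [run_summary()]
#' @export
assemble_count_matrix <- function(records, runs) {
  runs <- validate_runs(runs)
  check_records_against_runs(records, runs)
  proteins <- sort(unique(records$protein_id))
  counts <- matrix(0L, nrow = length(proteins), ncol = nrow(runs),
                   dimnames = list(proteins, runs$run_id))
  if (nrow(records) > 0) {
    counts[cbind(match(records$protein_id, proteins),
                 match(records$run_id, runs$run_id))] <-
      records$spectral_count
  }
  if (any(colSums(counts) == 0) && length(proteins) > 0) {
    empty <- runs$run_id[colSums(counts) == 0]
    stop("run(s) with zero total spectral count: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  peptide_support <- aggregate_peptide_support(records, proteins)
  structure(list(counts = counts, runs = runs,
                 peptide_support = peptide_support),
            class = "spectral_counts")
}

# Distinct peptide sequences across the union of runs where the protein was
# identified; max per-run count is the documented fallback when sequences
# are not listed.
aggregate_peptide_support <- function(records, proteins) {
  if (length(proteins) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  if ("peptides" %in% names(records) &&
      !all(is.na(records$peptides) | records$peptides == "")) {
    seqs <- strsplit(records$peptides, ";", fixed = TRUE)
    support <- vapply(split(seqs, factor(records$protein_id,
                                         levels = proteins)),
                      function(x) length(unique(unlist(x))), integer(1))
  } else {
    support <- vapply(split(records$peptide_count,
                            factor(records$protein_id, levels = proteins)),
                      function(x) as.integer(max(x)), integer(1))
  }
  support
}

#' @export
print.spectral_counts <- function(x, ...) {
  cat(sprintf("spectral_counts: %d proteins x %d runs (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s n=%d", GROUP_LEVELS,
                            tabulate(match(x$runs$group, GROUP_LEVELS),
                                     length(GROUP_LEVELS))),
                    collapse = ", ")))
  cat(sprintf("total spectra per run: %s\n",
              paste(colSums(x$counts), collapse = " ")))
  invisible(x)
}

#' Per-run and per-group identification summary
#'
#' For each run: the number of proteins identified (nonzero cells) and the
#' total spectral count (column sum); per-group means of both are appended
#' as a second table. This mirrors the run-level summary a search-summary
#' report would print.
#'
#' @param x A `spectral_counts` object.
#' @return A list with data.frames `per_run` (`run_id`, `group`,
#'   `replicate_index`, `n_proteins`, `total_spectra`) and `per_group`
#'   (`group`, `mean_proteins`, `mean_spectra`).
#' @export
run_summary <- function(x) {
  stopifnot(inherits(x, "spectral_counts"))
  per_run <- data.frame(x$runs,
                        n_proteins = colSums(x$counts > 0),
                        total_spectra = colSums(x$counts),
                        row.names = NULL, stringsAsFactors = FALSE)
  grp <- factor(per_run$group, levels = GROUP_LEVELS)
  per_group <- data.frame(group = GROUP_LEVELS,
                          mean_proteins = as.numeric(
                            tapply(per_run$n_proteins, grp, mean)),
                          mean_spectra = as.numeric(
                            tapply(per_run$total_spectra, grp, mean)),
                          row.names = NULL, stringsAsFactors = FALSE)
  list(per_run = per_run, per_group = per_group)
}
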