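#' Secretome classification from dual signal-peptide predictions
#'
#' A protein is classified as secreted when *both* an artificial
#' neural-network predictor and a hidden-Markov-model predictor (the two
#' algorithms of SignalP-style tools) call an N-terminal signal peptide.
#' Proteins with no annotation row are treated as non-secretory, with a
#' warning listing the unannotated accessions.
#'
#' @param protein_ids Character vector of accessions to classify.
#' @param annotations Data.frame with columns `protein_id`, `nn_positive`,
#'   `hmm_positive` (logical or 0/1), one row per accession.
#' @return Logical vector (`TRUE` = secreted), same length and order as
#'   `protein_ids`.
#' @export
classify_secreted <- function(protein_ids, annotations) {
  annotations <- normalize_annotations(annotations)
  idx <- match(protein_ids, annotations$protein_id)
  if (anyNA(idx)) {
    warning("no secretion annotation for: ",
            paste(protein_ids[is.na(idx)], collapse = ", "),
            "; treating as non-secretory", call. = FALSE)
  }
  secreted <- annotations$nn_positive[idx] & annotations$hmm_positive[idx]
  secreted[is.na(secreted)] <- FALSE
  secreted
}

normalize_annotations <- function(annotations) {
  stopifnot(all(c("protein_id", "nn_positive", "hmm_positive") %in%
                  names(annotations)))
  if (anyDuplicated(annotations$protein_id)) {
    stop("duplicate annotation for: ",
         paste(unique(annotations$protein_id[
           duplicated(annotations$protein_id)]), collapse = ", "),
         call. = FALSE)
  }
  annotations$nn_positive <- as.logical(as.integer(annotations$nn_positive))
  annotations$hmm_positive <- as.logical(as.integer(annotations$hmm_positive))
  annotations
}

#' Read a secretion-annotation table
#'
#' @param path TSV with columns `protein_id`, `nn_positive`, `hmm_positive`
#'   (0/1 flags).
#' @return Annotation data.frame with logical flag columns.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) {
    stop("annotation table not found: ", path, call. = FALSE)
  }
  normalize_annotations(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Cross-tabulate selected proteins by secretion class and direction
#'
#' Partitions a set of selected differential calls into secreted versus
#' non-secretory proteins and cross-tabulates against the direction of
#' change, yielding the summary a secretome study reports: the share of
#' differential proteins that are secreted, the share of secreted proteins
#' that decreased, and the share of non-secretory proteins that increased.
#' Percentages are computed from the integer cells and rounded half-up to
#' one decimal place.
#'
#' @param calls Data.frame of *selected* calls with columns `protein_id`
#'   and `direction`; every direction must be `"increased"` or
#'   `"decreased"`.
#' @param annotations Secretion-annotation data.frame
#'   (see [classify_secreted()]).
#' @return An object of class `partition_summary`: a list with `n_total`,
#'   `n_secreted`, `n_nonsecreted`, `counts_2x2` (integer matrix,
#'   rows secreted/non_secreted x columns increased/decreased),
#'   `pct_secreted`, `pct_nonsecreted`, `pct_secreted_decreased`,
#'   `pct_nonsecreted_increased`.
#' @export
partition_summary <- function(calls, annotations) {
  if (nrow(calls) == 0) {
    stop("no calls to partition", call. = FALSE)
  }
  if (!all(calls$direction %in% c("increased", "decreased"))) {
    stop("all calls must have direction 'increased' or 'decreased'; got: ",
         paste(unique(setdiff(calls$direction,
                              c("increased", "decreased"))), collapse = ", "),
         call. = FALSE)
  }
  secreted <- classify_secreted(calls$protein_id, annotations)
  tab <- table(factor(ifelse(secreted, "secreted", "non_secreted"),
                      levels = c("secreted", "non_secreted")),
               factor(calls$direction,
                      levels = c("increased", "decreased")))
  counts_2x2 <- matrix(as.integer(tab), nrow = 2,
                       dimnames = dimnames(tab))
  n_total <- nrow(calls)
  n_secreted <- sum(counts_2x2["secreted", ])
  n_nonsecreted <- sum(counts_2x2["non_secreted", ])
  pct <- function(num, den) {
    if (den == 0) return(NA_real_)
    round_half_up(100 * num / den, 1)
  }
  structure(list(
    n_total = n_total,
    n_secreted = n_secreted,
    n_nonsecreted = n_nonsecreted,
    counts_2x2 = counts_2x2,
    pct_secreted = pct(n_secreted, n_total),
    pct_nonsecreted = pct(n_nonsecreted, n_total),
    pct_secreted_decreased = pct(counts_2x2["secreted", "decreased"],
                                 n_secreted),
    pct_nonsecreted_increased = pct(counts_2x2["non_secreted", "increased"],
                                    n_nonsecreted)
  ), class = "partition_summary")
}

# Half-up decimal rounding (base round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

#' @export
print.partition_summary <- function(x, ...) {
  cat(sprintf("partition_summary: %d differential proteins\n", x$n_total))
  cat(sprintf("  secreted:      %d (%.1f%%), of which %.1f%% decreased\n",
              x$n_secreted, x$pct_secreted, x$pct_secreted_decreased))
  cat(sprintf("  non-secretory: %d (%.1f%%), of which %.1f%% increased\n",
              x$n_nonsecreted, x$pct_nonsecreted,
              x$pct_nonsecreted_increased))
  print(x$counts_2x2)
  invisible(x)
}

#' Write a partition summary as JSON
#'
#' All `partition_summary` fields plus an optional parameter block, in a
#' machine-readable layout.
#'
#' @param x A `partition_summary`.
#' @param path Output path.
#' @param parameters Optional named list echoed under `"parameters"`.
#' @return `path`, invisibly.
#' @export
write_partition_summary <- function(x, path, parameters = NULL) {
  stopifnot(inherits(x, "partition_summary"))
  payload <- list(
    n_total = x$n_total,
    n_secreted = x$n_secreted,
    n_nonsecreted = x$n_nonsecreted,
    counts_2x2 = list(
      secreted_increased = x$counts_2x2["secreted", "increased"],
      secreted_decreased = x$counts_2x2["secreted", "decreased"],
      non_secreted_increased = x$counts_2x2["non_secreted", "increased"],
      non_secreted_decreased = x$counts_2x2["non_secreted", "decreased"]
    ),
    pct_secreted = x$pct_secreted,
    pct_nonsecreted = x$pct_nonsecreted,
    pct_secreted_decreased = x$pct_secreted_decreased,
    pct_nonsecreted_increased = x$pct_nonsecreted_increased
  )
  if (!is.null(parameters)) payload$parameters <- parameters
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
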