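#' Compute spectral count weights (SCW)
#'
#' The spectral count weight of a protein in one MS analysis is its
#' spectral count divided by the total spectral count of that analysis: a
#' per-run relative abundance on the simplex. A protein not identified in a
#' run (count 0) has SCW 0 in that run, so every protein carries a full
#' vector of SCW values across all runs and group comparison is possible
#' over the union protein set. Normalizing within run absorbs run-to-run
#' differences in total identified spectra.
#'
#' @param x A `spectral_counts` object from [assemble_count_matrix()].
#' @return An object of class `scw_matrix`: a list with `scw` (numeric
#'   matrix, proteins x runs, each column summing to 1) and `runs`.
#' @examples
#' runs <- data.frame(run_id = c("m1", "m2", "c1", "c2"),
#'                    group = c("model", "model", "control", "control"),
#'                    replicate_index = c(1, 2, 1, 2))
#' recs <- data.frame(run_id = rep(runs$run_id, each = 2),
#'                    group = rep(runs$group, each = 2),
#'                    protein_id = rep(c("P1", "P2"), 4),
#'                    probability = 0.99, peptide_count = 2L,
#'                    spectral_count = c(2L, 8L, 3L, 7L, 5L, 5L, 4L, 6L))
#' scw <- compute_scw(assemble_count_matrix(recs, runs))
#' colSums(scw$scw)  # all exactly 1
#' @export
compute_scw <- function(x) {
  stopifnot(inherits(x, "spectral_counts"))
  totals <- colSums(x$counts)
  if (any(totals == 0)) {
    stop("run(s) with zero total spectral count: ",
         paste(colnames(x$counts)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  scw <- sweep(x$counts, 2, totals, "/")
  structure(list(scw = scw, runs = x$runs), class = "scw_matrix")
}

#' @export
print.scw_matrix <- function(x, ...) {
  cat(sprintf("scw_matrix: %d proteins x %d runs; column sums %s\n",
              nrow(x$scw), ncol(x$scw),
              paste(format(colSums(x$scw)), collapse = " ")))
  invisible(x)
}

#' Split a protein's SCW values by group
#'
#' Returns the two per-group replicate vectors of SCW values for one
#' protein, in replicate order — the pair of vectors the per-protein
#' t-test consumes. With the standard 5 + 5 technical-replicate design
#' this yields ten values per protein.
#'
#' @param x An `scw_matrix`.
#' @param protein_id Protein accession present in the matrix.
#' @return A list with numeric vectors `model` and `control`.
#' @export
group_scw_vectors <- function(x, protein_id) {
  stopifnot(inherits(x, "scw_matrix"))
  if (!protein_id %in% rownames(x$scw)) {
    stop("unknown protein: ", protein_id, call. = FALSE)
  }
  row <- x$scw[protein_id, ]
  list(model = unname(row[x$runs$group == "model"]),
       control = unname(row[x$runs$group == "control"]))
}

#' Export an SCW matrix as TSV
#'
#' One row per protein (`protein_id` plus one column per run), values in
#' scientific notation with 6 significant digits. Full precision is kept
#' internally; this formatting applies to the report file only.
#'
#' @param x An `scw_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scw_table <- function(x, path) {
  stopifnot(inherits(x, "scw_matrix"))
  formatted <- apply(x$scw, 2, function(v) {
    sprintf("%.5e", v)
  })
  if (nrow(x$scw) == 1) formatted <- matrix(formatted, nrow = 1)
  out <- data.frame(protein_id = rownames(x$scw), formatted,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("protein_id", colnames(x$scw))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
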