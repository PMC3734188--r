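# Builders for in-code fixtures shared across test files.

make_runs <- function(n_model = 5, n_control = 5) {
  data.frame(
    run_id = c(sprintf("m%d", seq_len(n_model)),
               sprintf("c%d", seq_len(n_control))),
    group = rep(c("model", "control"), c(n_model, n_control)),
    replicate_index = c(seq_len(n_model), seq_len(n_control)),
    stringsAsFactors = FALSE)
}

# Identification records from a protein x run count matrix (0 = absent).
records_from_counts <- function(counts, runs, peptide_counts = NULL,
                                probability = 0.99) {
  if (is.null(peptide_counts)) {
    peptide_counts <- stats::setNames(rep(3L, nrow(counts)),
                                      rownames(counts))
  }
  idx <- which(counts > 0, arr.ind = TRUE)
  data.frame(
    run_id = colnames(counts)[idx[, "col"]],
    group = runs$group[match(colnames(counts)[idx[, "col"]], runs$run_id)],
    protein_id = rownames(counts)[idx[, "row"]],
    probability = probability,
    peptide_count = unname(peptide_counts[rownames(counts)[idx[, "row"]]]),
    spectral_count = as.integer(counts[idx]),
    stringsAsFactors = FALSE)
}

random_count_matrix <- function(n_proteins, n_runs_per_group,
                                max_count = 50) {
  runs <- make_runs(n_runs_per_group, n_runs_per_group)
  repeat {
    counts <- matrix(
      sample(0:max_count, n_proteins * nrow(runs), replace = TRUE),
      nrow = n_proteins,
      dimnames = list(sprintf("P%03d", seq_len(n_proteins)), runs$run_id))
    if (all(colSums(counts) > 0) && all(rowSums(counts) > 0)) break
  }
  list(counts = counts, runs = runs)
}

# Hand-built 12-protein 5v5 toy exercising every selection criterion:
# three clean spike-ins, one single-peptide spike-in, one spike-in absent
# from one elevated run, one exact fold-2.5 protein, five flat nulls, and
# a filler protein padding every run to 1000 total spectra so SCW values
# are exact fractions of 1000.
toy_cascade_dataset <- function() {
  runs <- make_runs(5, 5)
  proteins <- c("SPIKE1", "SPIKE2", "SPIKE3", "SINGLEPEP", "MISSED",
                "FOLD25", sprintf("NULL%d", 1:5), "FILLER")
  counts <- matrix(0L, nrow = length(proteins), ncol = 10,
                   dimnames = list(proteins, runs$run_id))
  counts["SPIKE1", ] <- c(rep(100L, 5), rep(10L, 5))
  counts["SPIKE2", ] <- c(90L, 95L, 100L, 105L, 110L, 9L, 10L, 11L, 10L, 10L)
  counts["SPIKE3", ] <- c(rep(10L, 5), rep(60L, 5))   # decreased
  counts["SINGLEPEP", ] <- c(rep(100L, 5), rep(10L, 5))
  counts["MISSED", ] <- c(80L, 90L, 0L, 85L, 95L, rep(10L, 5))
  counts["FOLD25", ] <- c(rep(50L, 5), rep(20L, 5))
  counts[sprintf("NULL%d", 1:5), ] <- 30L
  counts["FILLER", ] <- 1000L - colSums(counts)
  peptide_counts <- stats::setNames(rep(3L, length(proteins)), proteins)
  peptide_counts["SINGLEPEP"] <- 1L
  records <- records_from_counts(counts, runs, peptide_counts)
  list(records = records, runs = runs, counts = counts,
       expected_selected = c("SPIKE1", "SPIKE2", "SPIKE3"))
}
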