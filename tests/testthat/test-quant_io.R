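test_that("well-formed tables round-trip field-exactly through write/read", {
  runs <- make_runs(2, 2)
  records <- data.frame(
    run_id = c("m1", "m1", "c1"), group = c("model", "model", "control"),
    protein_id = c("P001", "P002", "P001"),
    probability = c(0.99, 0.95, 0.97),
    peptide_count = c(3L, 1L, 2L), spectral_count = c(12L, 4L, 9L),
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  runs_path <- withr::local_tempfile(fileext = ".tsv")
  write_quant_table(records, path)
  write_runs_table(runs, runs_path)
  back <- read_quant_table(path, runs_path = runs_path)
  reordered <- records[order(records$run_id, records$protein_id), ]
  rownames(reordered) <- NULL
  expect_equal(back$records, reordered)
  expect_equal(nrow(back$records), 3)
  expect_setequal(back$runs$run_id, runs$run_id)
})

test_that("row-level validation cites the offending file line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  lines <- c("run_id\tgroup\tprotein_id\tprobability\tpeptide_count\tspectral_count",
             "m1\tmodel\tP001\t0.99\t2\t10",
             "m2\tmodel\tP001\t0.98\t2\t11",
             "c1\tcontrol\tP001\t1.2\t2\t9",
             "c2\tcontrol\tP001\t0.97\t2\t8")
  writeLines(lines, path)
  expect_error(read_quant_table(path), "line 4")

  lines[4] <- "c1\tcontrol\tP001\t0.96\t0\t9"
  writeLines(lines, path)
  expect_error(read_quant_table(path), "peptide_count.*line 4")

  lines[4] <- "c1\tcontrol\tP001\t0.96\t2\t3.5"
  writeLines(lines, path)
  expect_error(read_quant_table(path), "spectral_count.*line 4")
})

test_that("missing required columns and empty tables are handled", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("run_id\tgroup\tprotein_id\tprobability\tpeptide_count", path)
  expect_error(read_quant_table(path), "spectral_count")

  writeLines(paste(c("run_id", "group", "protein_id", "probability",
                     "peptide_count", "spectral_count"), collapse = "\t"),
             path)
  parsed <- read_quant_table(path)
  expect_equal(nrow(parsed$records), 0)
  expect_equal(nrow(parsed$runs), 0)
})

test_that("probability filter is strictly greater-than and order-preserving", {
  records <- data.frame(
    run_id = "m1", group = "model",
    protein_id = c("A", "B", "C", "D"),
    probability = c(0.95, 0.90, 0.9000001, 0.2),
    peptide_count = 2L, spectral_count = 5L, stringsAsFactors = FALSE)
  kept <- filter_by_probability(records, 0.9)
  expect_equal(kept$protein_id, c("A", "C"))  # exactly 0.90 removed
  expect_equal(nrow(filter_by_probability(records[0, , drop = FALSE])), 0)
  expect_equal(filter_by_probability(records, 0)$protein_id,
               records$protein_id)
  expect_equal(nrow(filter_by_probability(records, 1)), 0)
})

test_that("count-matrix assembly zero-fills the union protein set", {
  runs <- make_runs(3, 2)
  # protein A in model runs 1-3 only; B in control only
  records <- data.frame(
    run_id = c("m1", "m2", "m3", "c1", "c2"),
    group = c(rep("model", 3), rep("control", 2)),
    protein_id = c("A", "A", "A", "B", "B"),
    probability = 0.99, peptide_count = 2L,
    spectral_count = c(5L, 6L, 7L, 3L, 4L), stringsAsFactors = FALSE)
  m <- assemble_count_matrix(records, runs)
  expect_equal(dim(m$counts), c(2, 5))
  expect_equal(unname(m$counts["A", c("c1", "c2")]), c(0L, 0L))
  expect_equal(unname(m$counts["B", c("m1", "m2", "m3")]), c(0L, 0L, 0L))
  expect_error(
    assemble_count_matrix(transform(records, run_id = sub("m3", "zz", run_id)),
                          runs),
    "zz")
})

test_that("column sums equal per-run summed spectral counts (oracle)", {
  set.seed(42)
  for (rep in 1:5) {
    rc <- random_count_matrix(10, 3)
    records <- records_from_counts(rc$counts, rc$runs)
    m <- assemble_count_matrix(records, rc$runs)
    # independent oracle: sum the raw records per run
    oracle <- tapply(records$spectral_count,
                     factor(records$run_id, levels = rc$runs$run_id), sum)
    expect_equal(unname(colSums(m$counts)[rc$runs$run_id]),
                 unname(as.numeric(oracle)))
  }
})

test_that("assembly is invariant to input record order", {
  rc <- random_count_matrix(8, 3)
  records <- records_from_counts(rc$counts, rc$runs)
  set.seed(1)
  shuffled <- records[sample.int(nrow(records)), ]
  expect_equal(assemble_count_matrix(shuffled, rc$runs),
               assemble_count_matrix(records, rc$runs))
})

test_that("peptide support aggregates distinct sequences across runs", {
  runs <- make_runs(2, 2)
  records <- data.frame(
    run_id = c("m1", "m2", "c1", "c2"),
    group = c("model", "model", "control", "control"),
    protein_id = c("A", "A", "A", "B"), probability = 0.99,
    peptide_count = c(2L, 2L, 1L, 1L), spectral_count = c(5L, 5L, 2L, 3L),
    peptides = c("PEPK;TIDER", "PEPK;GLYK", "PEPK", "OTHK"),
    stringsAsFactors = FALSE)
  m <- assemble_count_matrix(records, runs)
  # union of distinct sequences: PEPK, TIDER, GLYK
  expect_equal(unname(m$peptide_support["A"]), 3L)
  expect_equal(unname(m$peptide_support["B"]), 1L)
  # fallback without sequences: max per-run count
  m2 <- assemble_count_matrix(records[, -7], runs)
  expect_equal(unname(m2$peptide_support["A"]), 2L)
})

test_that("run summary counts identified proteins and spectra per run", {
  runs <- make_runs(2, 2)
  counts <- matrix(c(0L, 2L, 5L, 0L, 3L, 1L, 4L, 4L, 0L, 0L, 6L, 2L),
                   nrow = 3,
                   dimnames = list(c("A", "B", "C"), runs$run_id))
  m <- assemble_count_matrix(records_from_counts(counts, runs), runs)
  s <- run_summary(m)
  expect_equal(s$per_run$n_proteins[s$per_run$run_id == "m1"], 2)
  expect_equal(s$per_run$total_spectra[s$per_run$run_id == "m1"], 7)
  expect_equal(s$per_group$mean_spectra[s$per_group$group == "model"],
               mean(colSums(counts)[1:2]))
})
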