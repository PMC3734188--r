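test_that("pooled t statistic matches the hand-computed value exactly", {
  res <- two_sample_t(c(0.10, 0.12, 0.11, 0.13, 0.09),
                      c(0.20, 0.22, 0.21, 0.23, 0.19))
  # pooled sd 0.0158..., se 0.01, mean difference -0.1 -> t = -10
  # (to machine precision: the decimal inputs are not binary-exact)
  expect_equal(res$statistic, -10, tolerance = 1e-12)
  expect_equal(res$df, 8)
  expect_lt(res$p_value, 0.01)
  # symmetry: swapping groups flips the sign, p unchanged
  swapped <- two_sample_t(c(0.20, 0.22, 0.21, 0.23, 0.19),
                          c(0.10, 0.12, 0.11, 0.13, 0.09))
  expect_equal(swapped$statistic, 10, tolerance = 1e-12)
  expect_identical(swapped$p_value, res$p_value)
})

test_that("p-values agree with stats::t.test as independent oracle", {
  set.seed(101)
  for (rep in 1:200) {
    a <- stats::rnorm(5, mean = stats::runif(1, 0, 0.1), sd = 0.02)
    b <- stats::rnorm(5, mean = stats::runif(1, 0, 0.1), sd = 0.02)
    res <- two_sample_t(a, b)
    oracle <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(res$p_value, oracle$p.value, tolerance = 1e-12)
    expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-12)
  }
})

test_that("degenerate zero-variance vectors get continuity-limit p-values", {
  expect_identical(two_sample_t(rep(0.1, 5), rep(0.1, 5))$p_value, 1)
  expect_identical(two_sample_t(rep(0.1, 5), rep(0.3, 5))$p_value, 0)
  expect_identical(two_sample_t(rep(0, 5), rep(0, 5))$p_value, 1)
  expect_error(two_sample_t(0.5, c(0.1, 0.2)), "at least 2 replicates")
})

test_that("fold change is the elevated-over-other ratio with direction", {
  fc <- fold_change_and_direction(c(0.0035, 0.002, 0.01, 0, 0.001),
                                  c(0.0010, 0,     0.01, 0, 0.004))
  expect_equal(fc$fold_change, c(3.5, Inf, 1, 1, 4))
  expect_equal(fc$direction,
               c("increased", "increased", "none", "none", "decreased"))
})

test_that("cascade flags and selection behave per criterion on the toy", {
  toy <- toy_cascade_dataset()
  m <- assemble_count_matrix(toy$records, toy$runs)
  calls <- run_differential_analysis(compute_scw(m), m)
  calls <- calls[match(rownames(toy$counts), calls$protein_id), ]

  expect_setequal(calls$protein_id[calls$selected], toy$expected_selected)

  single <- calls[calls$protein_id == "SINGLEPEP", ]
  expect_false(single$selected)
  expect_false(single$passes_peptide)
  expect_true(single$passes_p && single$passes_presence && single$passes_fc)

  missed <- calls[calls$protein_id == "MISSED", ]
  expect_false(missed$selected)
  expect_false(missed$passes_presence)

  fold25 <- calls[calls$protein_id == "FOLD25", ]
  expect_identical(fold25$fold_change, 2.5)
  expect_false(fold25$passes_fc)   # strict inequality at the boundary
  expect_false(fold25$selected)
  expect_true(fold25$passes_p && fold25$passes_peptide &&
                fold25$passes_presence)

  spike3 <- calls[calls$protein_id == "SPIKE3", ]
  expect_equal(spike3$direction, "decreased")
})

test_that("boundary semantics: p and fold cut-offs are strict", {
  toy <- toy_cascade_dataset()
  m <- assemble_count_matrix(toy$records, toy$runs)
  scw <- compute_scw(m)
  calls <- run_differential_analysis(scw, m)
  # a protein whose p-value exactly equals the cut-off must fail passes_p
  forced <- calls
  forced$p_value[forced$protein_id == "SPIKE1"] <- 0.01
  forced <- apply_selection_criteria(forced, m)
  expect_false(forced$selected[forced$protein_id == "SPIKE1"])
})

test_that("selection agrees with a brute-force oracle on random matrices", {
  set.seed(202)
  for (rep in 1:5) {
    rc <- random_count_matrix(10, 5, max_count = 30)
    m <- assemble_count_matrix(records_from_counts(rc$counts, rc$runs),
                               rc$runs)
    scw <- compute_scw(m)
    calls <- run_differential_analysis(scw, m)
    # oracle: explicit per-protein loop with closed-form pooled t
    for (p in rownames(rc$counts)) {
      a <- scw$scw[p, rc$runs$group == "model"]
      b <- scw$scw[p, rc$runs$group == "control"]
      sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 8
      p_oracle <- if (sp2 == 0) {
        if (mean(a) == mean(b)) 1 else 0
      } else {
        2 * stats::pt(-abs((mean(a) - mean(b)) / sqrt(sp2 * 2 / 5)), 8)
      }
      fold_oracle <- if (max(mean(a), mean(b)) == 0) 1 else
        max(mean(a), mean(b)) / min(mean(a), mean(b))
      row <- calls[calls$protein_id == p, ]
      expect_equal(row$p_value, p_oracle, tolerance = 1e-12)
      expect_equal(row$fold_change, fold_oracle, tolerance = 1e-12)
      sel_oracle <- p_oracle < 0.01 &&
        m$peptide_support[[p]] >= 2 &&
        fold_oracle > 2.5 &&
        (if (mean(a) > mean(b)) all(m$counts[p, rc$runs$group == "model"] > 0)
         else if (mean(a) < mean(b)) all(m$counts[p, rc$runs$group == "control"] > 0)
         else FALSE)
      expect_identical(row$selected, sel_oracle)
    }
  }
})

test_that("swapping group labels maps increased to decreased, p unchanged", {
  toy <- toy_cascade_dataset()
  runs_swapped <- toy$runs
  runs_swapped$group <- ifelse(runs_swapped$group == "model", "control",
                               "model")
  records_swapped <- toy$records
  records_swapped$group <- ifelse(records_swapped$group == "model",
                                  "control", "model")
  m1 <- assemble_count_matrix(toy$records, toy$runs)
  m2 <- assemble_count_matrix(records_swapped, runs_swapped)
  c1 <- run_differential_analysis(compute_scw(m1), m1)
  c2 <- run_differential_analysis(compute_scw(m2), m2)
  c2 <- c2[match(c1$protein_id, c2$protein_id), ]
  expect_equal(c2$p_value, c1$p_value)
  expect_equal(c2$fold_change, c1$fold_change)
  map <- c(increased = "decreased", decreased = "increased", none = "none")
  expect_equal(c2$direction, unname(map[c1$direction]))
})

test_that("selection shrinks monotonically as thresholds tighten", {
  toy <- toy_cascade_dataset()
  m <- assemble_count_matrix(toy$records, toy$runs)
  scw <- compute_scw(m)
  base <- run_differential_analysis(scw, m)
  sel_base <- base$protein_id[base$selected]
  for (args in list(list(fc_cutoff = 5), list(p_cutoff = 1e-6),
                    list(min_peptides = 4))) {
    tightened <- do.call(run_differential_analysis,
                         c(list(scw = scw, counts = m), args))
    expect_true(all(tightened$protein_id[tightened$selected] %in% sel_base))
  }
})

test_that("differential table round-trips with Inf folds preserved", {
  toy <- toy_cascade_dataset()
  m <- assemble_count_matrix(toy$records, toy$runs)
  calls <- run_differential_analysis(compute_scw(m), m)
  calls$fold_change[1] <- Inf   # force an absent-vs-present literal
  path <- withr::local_tempfile(fileext = ".tsv")
  write_differential_table(calls, path)
  back <- read_differential_table(path)
  expect_equal(back$fold_change[1], Inf)  # sorted first by fold
  expect_setequal(back$protein_id, calls$protein_id)
})
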