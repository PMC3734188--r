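#' Pooled two-sample Student's t-test
#'
#' Two-sided equal-variance (pooled) Student's t-test on two replicate
#' vectors, with `df = n1 + n2 - 2`. Implemented from the closed form so
#' that the degenerate cases spectral counting produces are well defined:
#' when both groups have zero variance the p-value is taken as the
#' continuity limit — 1 if the means are equal, 0 if they differ.
#'
#' @param model Numeric vector of model-group values (length >= 2).
#' @param control Numeric vector of control-group values (length >= 2).
#' @return A list with `statistic` (pooled t; `Inf`/`-Inf`/`0` in the
#'   degenerate zero-variance cases), `df`, and `p_value`.
#' @examples
#' two_sample_t(c(0.10, 0.12, 0.11, 0.13, 0.09),
#'              c(0.20, 0.22, 0.21, 0.23, 0.19))$statistic  # exactly -10
#' @export
two_sample_t <- function(model, control) {
  n1 <- length(model)
  n2 <- length(control)
  if (n1 < 2 || n2 < 2) {
    stop("each group needs at least 2 replicates (got ", n1, " and ", n2,
         ")", call. = FALSE)
  }
  df <- n1 + n2 - 2
  delta <- mean(model) - mean(control)
  pooled_var <- (sum((model - mean(model))^2) +
                 sum((control - mean(control))^2)) / df
  if (pooled_var == 0) {
    if (delta == 0) {
      return(list(statistic = 0, df = df, p_value = 1))
    }
    return(list(statistic = sign(delta) * Inf, df = df, p_value = 0))
  }
  se <- sqrt(pooled_var * (1 / n1 + 1 / n2))
  t_stat <- delta / se
  list(statistic = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df))
}

#' Fold change and direction from group means
#'
#' The fold change is the elevated group's mean over the other group's:
#' `max(m_model, m_control) / min(...)`, so it is always >= 1 and the
#' `direction` records which group is elevated. When exactly one mean is
#' zero the fold change is `Inf` (a presence/absence contrast); when both
#' are zero it is 1 with direction `none`.
#'
#' @param mean_model,mean_control Non-negative group means (vectorized).
#' @return A data.frame with columns `fold_change` and `direction`
#'   (`"increased"` = elevated in model, `"decreased"` = elevated in
#'   control, `"none"` = equal means).
#' @export
fold_change_and_direction <- function(mean_model, mean_control) {
  stopifnot(length(mean_model) == length(mean_control),
            all(mean_model >= 0), all(mean_control >= 0))
  hi <- pmax(mean_model, mean_control)
  lo <- pmin(mean_model, mean_control)
  fold <- ifelse(hi == 0, 1, hi / lo)  # 0/0 -> 1; x/0 -> Inf
  direction <- ifelse(mean_model > mean_control, "increased",
                      ifelse(mean_model < mean_control, "decreased", "none"))
  data.frame(fold_change = fold, direction = direction,
             stringsAsFactors = FALSE)
}

#' Apply the three-criteria selection cascade
#'
#' Fills the per-criterion pass flags on a table of differential calls and
#' sets `selected` to their conjunction (with the p-value cut-off):
#'
#' * `passes_p` — raw t-test p-value strictly below `p_cutoff`;
#' * `passes_peptide` — at least `min_peptides` distinct peptide sequences
#'   support the protein across all runs (single-peptide identifications
#'   are excluded regardless of spectral count);
#' * `passes_presence` — the protein has a nonzero spectral count in
#'   *every* run of the group in which it is elevated (direction-dependent;
#'   `FALSE` when direction is `none`);
#' * `passes_fc` — fold change strictly greater than `fc_cutoff`
#'   (`Inf` passes; the presence criterion still gates absent-vs-present
#'   contrasts).
#'
#' All flags are always reported so failed proteins can be audited.
#'
#' @param calls Data.frame of calls with columns `protein_id`, `p_value`,
#'   `fold_change`, `direction`, `peptide_support`.
#' @param counts The `spectral_counts` object used for presence checks.
#' @param p_cutoff Significance cut-off (strict); default 0.01.
#' @param fc_cutoff Fold-change cut-off (strict); default 2.5.
#' @param min_peptides Minimum distinct peptide support; default 2.
#' @return `calls` with logical columns `passes_p`, `passes_peptide`,
#'   `passes_presence`, `passes_fc`, `selected` filled.
#' @export
apply_selection_criteria <- function(calls, counts, p_cutoff = 0.01,
                                     fc_cutoff = 2.5, min_peptides = 2) {
  stopifnot(inherits(counts, "spectral_counts"),
            all(calls$protein_id %in% rownames(counts$counts)))
  idx <- match(calls$protein_id, rownames(counts$counts))
  present_model <- rowSums(
    counts$counts[idx, counts$runs$group == "model", drop = FALSE] > 0) ==
    sum(counts$runs$group == "model")
  present_control <- rowSums(
    counts$counts[idx, counts$runs$group == "control", drop = FALSE] > 0) ==
    sum(counts$runs$group == "control")
  calls$passes_p <- calls$p_value < p_cutoff
  calls$passes_peptide <- calls$peptide_support >= min_peptides
  calls$passes_presence <- ifelse(
    calls$direction == "increased", present_model,
    ifelse(calls$direction == "decreased", present_control, FALSE))
  calls$passes_fc <- calls$fold_change > fc_cutoff
  calls$selected <- calls$passes_p & calls$passes_peptide &
    calls$passes_presence & calls$passes_fc
  calls
}

#' Per-protein differential analysis over SCW values
#'
#' For every protein in the union set: split its SCW values by group,
#' compute group means, the pooled two-sided t-test p-value, the fold
#' change and its direction, then apply the three-criteria selection
#' cascade. No multiple-testing correction is applied (the cascade works
#' on raw p-values); the expected number of false positives at the raw
#' cut-off is `n_tested * p_cutoff` and is reported by the pipeline log.
#'
#' @param scw An `scw_matrix` from [compute_scw()].
#' @param counts The matching `spectral_counts` object (same proteins and
#'   runs; supplies raw counts for presence checks and peptide support).
#' @param p_cutoff,fc_cutoff,min_peptides Cascade thresholds; see
#'   [apply_selection_criteria()].
#' @return A data.frame with one row per protein: `protein_id`,
#'   `mean_model`, `mean_control`, `p_value`, `fold_change`, `direction`,
#'   `peptide_support`, the four pass flags, and `selected`.
#' @export
run_differential_analysis <- function(scw, counts, p_cutoff = 0.01,
                                      fc_cutoff = 2.5, min_peptides = 2) {
  stopifnot(inherits(scw, "scw_matrix"), inherits(counts, "spectral_counts"),
            identical(rownames(scw$scw), rownames(counts$counts)),
            identical(scw$runs$run_id, counts$runs$run_id))
  model_cols <- scw$runs$group == "model"
  control_cols <- scw$runs$group == "control"
  mean_model <- rowMeans(scw$scw[, model_cols, drop = FALSE])
  mean_control <- rowMeans(scw$scw[, control_cols, drop = FALSE])
  p_value <- vapply(seq_len(nrow(scw$scw)), function(i) {
    two_sample_t(scw$scw[i, model_cols], scw$scw[i, control_cols])$p_value
  }, numeric(1))
  fc <- fold_change_and_direction(mean_model, mean_control)
  calls <- data.frame(protein_id = rownames(scw$scw),
                      mean_model = unname(mean_model),
                      mean_control = unname(mean_control),
                      p_value = p_value,
                      fold_change = fc$fold_change,
                      direction = fc$direction,
                      peptide_support = unname(
                        counts$peptide_support[rownames(scw$scw)]),
                      row.names = NULL, stringsAsFactors = FALSE)
  apply_selection_criteria(calls, counts, p_cutoff = p_cutoff,
                           fc_cutoff = fc_cutoff,
                           min_peptides = min_peptides)
}

#' Write a differential-call table as TSV
#'
#' Rows sorted by descending fold change, ties broken by accession;
#' infinite fold changes are written as the literal `Inf`.
#'
#' @param calls Differential-call data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_differential_table <- function(calls, path) {
  out <- calls[order(-calls$fold_change, calls$protein_id), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a differential-call table written by [write_differential_table()]
#'
#' @param path Path to the TSV.
#' @return The differential-call data.frame (`Inf` literals restored).
#' @export
read_differential_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
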