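---
title: "Spectral-count-weight differential expression: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-count-weight differential expression: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scwdiff)
```

## The problem

Organ perfusion experiments — here, isolated rat livers whose perfusate is
collected after passing through the organ's vasculature — yield protein
mixtures containing both genuinely secreted proteins and intracellular
proteins leaked from tissue. Shotgun LC-MS/MS of such samples produces, per
run, a list of identified proteins with ProteinProphet identification
probabilities, distinct-peptide support, and spectral counts (the number of
MS/MS spectra assigned to each protein's peptides). Spectral counts are a
label-free abundance proxy, but the total number of spectra differs between
runs, and low-abundance proteins drop in and out of the identified list.
`scwdiff` implements the complete analysis from these per-run tables to a
list of differentially abundant proteins partitioned into secreted and
non-secretory classes.

## The SCW statistic

The spectral count weight of protein $p$ in run $r$ is

$$\mathrm{SCW}_{pr} = \frac{c_{pr}}{\sum_{q} c_{qr}},$$

its spectral count divided by the run's total spectral count. Each run's
SCW column is a point on the probability simplex, which absorbs run-to-run
differences in sequencing depth (runs in this design differ by up to ~20%
in total spectra). A protein not identified in a run is assigned
$\mathrm{SCW} = 0$ there — zero-imputation over the union protein set —
so every protein has a complete vector of values across all runs and the
two groups can be compared even for proteins absent from some analyses.

Only identifications with probability strictly above the cut-off (default
0.9, the conventional ~1% protein-level FDR operating point for TPP
output) enter the matrix, and the run totals in the denominator are
computed over those retained identifications, so the normalizer is
consistent with the protein list being analyzed. Filtering is applied per
(run, protein) record: a protein may survive in some runs and not others,
which matches per-analysis ProteinProphet output.

## Testing and the selection cascade

With $n_1 = n_2 = 5$ technical replicates per group, each protein's model
and control SCW vectors are compared with a two-sided pooled-variance
Student's t-test ($df = n_1 + n_2 - 2 = 8$). Pooled (equal-variance)
rather than Welch was chosen because "Student's t-test" names that test in
the classical sense, and technical replicates of the same pooled sample
give no reason to expect unequal group variances. Two degenerate cases
arise with count data and are defined by continuity limits: when both
groups have zero variance, $p = 1$ if the means are equal and $p = 0$ if
they differ. `stats::t.test(var.equal = TRUE)` (which refuses
zero-variance input) serves as the independent oracle for the
non-degenerate cases in the test suite.

The fold change is the elevated group's mean SCW over the other group's,
so it is always $\geq 1$ with a separate direction label; mean SCW rather
than summed raw spectra is used because SCW is the relative-abundance
estimate. When exactly one mean is zero the fold is $+\infty$ — an
absent-versus-present contrast, which the presence criterion below still
gates; when both are zero the protein is a non-call (fold 1, direction
`none`).

A protein is *selected* when all of the following hold:

1. raw $p < 0.01$ (strict; no multiple-testing correction — the expected
   number of false positives at $n$ tested proteins, $0.01\,n$, is echoed
   in the pipeline log so a null-compatible outcome is flagged);
2. at least 2 distinct peptide sequences support it (single-peptide
   identifications are excluded regardless of spectral count). Support is
   counted over the *union* of all runs in which the protein was
   identified — the most permissive reading consistent with excluding
   single-peptide proteins; when distinct sequences are not listed in the
   input, the maximum per-run peptide count is the documented fallback;
3. it has a nonzero count in *every* run of the group in which it is
   elevated (direction-dependent; a `none` direction fails);
4. fold change strictly greater than 2.5.

All four flags are reported for every protein so failed candidates can be
audited, and the cascade is a conjunction — evaluation order is
immaterial. All thresholds are strict inequalities; a protein at exactly
$p = 0.01$ or fold $= 2.5$ is not selected.

## Secretome partition

A selected protein is classified as secreted when *both* a neural-network
and a hidden-Markov-model signal-peptide predictor (the two SignalP
algorithm families) call it positive; proteins lacking an annotation row
default to non-secretory, with a warning naming them — the partition must
be an exhaustive binary split. The summary is the 2×2 cross-tabulation of
secretion class by direction with three derived percentages: the secreted
share of all differential proteins, the decreased share of secreted
proteins, and the increased share of non-secretory proteins. Percentages
are computed from the integer cells and rounded half-up to one decimal
(base `round()` is round-half-even, so a small helper implements the
conventional reporting rule).

`make_secretome_fixture()` provides the fixed 86-protein worked example
used across the documentation: margins 59 increased / 27 decreased and
27 secreted / 59 non-secretory, with cells (secreted-decreased 19,
secreted-increased 8, non-secreted-increased 51, non-secreted-decreased 8)
derived once from the benchmark's marginal percentages and satisfying both
margins exactly:

```{r fixture}
fx <- make_secretome_fixture()
partition_summary(fx$calls, fx$annotations)
```

## The synthetic-data generator

Raw spectral-count data at this design's scale are rarely redistributable,
so the package carries a generator whose defaults *are* the study
conditions the analysis assumes: two groups × 5 technical replicates,
800 proteins in the underlying mixture, per-run depth uniform on
16,000–19,500 total spectra, log-normal baseline abundances
(`abundance_sigma = 1.5` natural-log units, giving the heavy-tailed
abundance distribution typical of shotgun proteomes and ~700 identified
proteins per run after dropout), 10% spike-ins with folds $2^{1.4}$–$2^3$
(2.6–8), 59/86 of them increased, negative-binomial counts with
dispersion 0.1, and detection defined as count ≥ 1.

Parameters, with units and rationale:

| parameter | default | meaning |
|---|---|---|
| `n_proteins` | 800 | proteome size before dropout |
| `runs_per_group` | 5 | technical replicates per pooled sample |
| `depth_range` | 16,000–19,500 | per-run total-spectrum target (spectra) |
| `abundance_sigma` | 1.5 | log-normal sd of baseline relative abundance |
| `frac_differential` | 0.10 | fraction of proteins with a true fold |
| `log2_fc_range` | 1.4–3.0 | spike-in fold bounds (log2) |
| `direction_prob_increased` | 59/86 | share of spike-ins elevated in model |
| `dispersion` | 0.1 | NB overdispersion; 0 = Poisson |
| `peptide_rate` | 3 | distinct peptides per log10 expected count |
| `seed` | — | pins every draw; identical seed = identical data |

Two modeling choices deserve emphasis. First, only *technical* variability
is modeled, because the emulated design pools the biological replicates
into one sample per group before MS — hence the small dispersion default;
the generator says nothing about biological between-animal variance, and
passing recovery tests on it does not demonstrate power against biological
noise. Second, the model-group expected abundances are renormalized to the
simplex after spike-ins are applied. This mirrors the compositional nature
of spectral counting (more spectra for induced proteins means fewer for
everything else) and has a measurable consequence: with renormalization
factor $Z = \sum_q b_q f_q^{\pm 1}$, an increased spike-in of true fold
$f$ is observable by any relative-abundance measure only as $f/Z$, and a
decreased one as $fZ$. The generator's property tests therefore check
empirical SCW ratios against these compositional targets, and recovery
metrics that compare estimated to true folds inherit a bias of order $Z$
(typically 1.1–1.25 at the defaults).

Draws are consumed in a fixed documented order (baseline abundances,
spike-in selection, directions, folds, depths, then counts run by run,
then per-record probabilities and peptide counts) under R's Mersenne
twister, so a seed pins the entire dataset. Identification probabilities
are drawn on (0.9, 1], which exercises the probability filter without
letting it remove records at the default threshold — detection dropout
(count = 0) is deliberately the *only* identification-failure mechanism,
the simplest process generating the zero-imputation pattern the analysis
is built around. The generator does not simulate peptide sequences,
retention times, shared-peptide ambiguity, or protein length effects.

## Numerical and design choices

* Canonical protein order is lexicographic by accession; run order is
  model group first, then replicate index. All writers emit deterministic
  row order, so identical inputs give byte-identical outputs (the
  pipeline log deliberately carries no timestamps for the same reason).
* SCW values are kept at full double precision internally; the TSV export
  rounds to 6 significant digits, and reported percentages to 1 decimal.
* The probability filter, p-value and fold cut-offs are strict
  inequalities; the peptide criterion is $\geq$.
* Empty inputs degrade gracefully (a header-only table parses to zero
  records); a run with zero total spectra is an error naming the run, as
  is a record referencing unknown run metadata — both with the offending
  identifiers in the message.
* `evaluate_recovery()` reports sensitivity and empirical FDR as `NA`
  (absent in JSON) when their denominators are empty rather than forcing
  0/0 to a number.

The test suite runs the full design at its native scale (800 proteins,
5v5) for the null-calibration and recovery checks — a few seconds per
simulated dataset — and uses small hand-built matrices (a 12-protein toy
covering every criterion boundary, and random ≤ 8×4 matrices against
brute-force oracles) for exactness checks.

## Limitations

* The t-test treats SCW values as continuous; for proteins near the
  detection limit the statistic is driven by zeros and the test is only
  approximately calibrated (the null-calibration test verifies the
  aggregate false-positive rate at the default scale, not per-protein
  validity).
* No multiple-testing correction is applied, by design: the cascade's
  credibility comes from the conjunction of criteria, and the expected
  false-positive count is reported instead.
* Secretion classification consumes precomputed predictor flags; the
  package does not run signal-peptide prediction, and non-classical
  secretion is outside the binary split.
* Fold-change estimates from mean SCW are compositionally biased whenever
  total abundance shifts between conditions (see the generator section);
  this is a property of spectral-count proportions, not of the
  implementation.
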