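#' Relative mRNA concentration from a Cq value
#'
#' Converts quantification-cycle values to relative mRNA concentrations
#' (arbitrary units) through the primer-efficiency model
#' `concentration = (1 / E)^Cq`, where E is the primer amplification
#' efficiency (2 = perfect doubling per cycle). The result is strictly
#' decreasing in Cq and, for Cq > 0, in E.
#'
#' @param efficiency Primer efficiency, in (1, 2].
#' @param cq Quantification cycle.
#' @return Relative concentration, arbitrary units.
#' @examples
#' relative_concentration(2, 10)   # 2^-10
#' @export
relative_concentration <- function(efficiency, cq) {
  assert_that(all(is.finite(efficiency)) && all(efficiency > 1) &&
                all(efficiency <= 2),
              "primer efficiency must lie in (1, 2]")
  assert_that(all(is.finite(cq)), "Cq must be finite")
  (1 / efficiency)^cq
}

#' Collapse technical qPCR replicates by averaging Cq
#'
#' Technical replicates of the same biological sample and primer are
#' averaged on the Cq scale before any concentration is computed (the
#' conventional order; averaging after exponentiation would weight
#' replicates unequally). Idempotent.
#'
#' @param cq_tbl Tibble with at least sample_id, gene_id, cq, efficiency
#'   columns; other columns are treated as identifying and preserved.
#' @return Tibble with one row per (sample, gene).
#' @export
collapse_technical_replicates <- function(cq_tbl) {
  assert_cols(cq_tbl, c("sample_id", "gene_id", "cq"), "cq_tbl")
  keys <- setdiff(names(cq_tbl), "cq")
  cq_tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(cq = mean(.data$cq), .groups = "drop")
}

#' Normalize target concentrations to reference genes
#'
#' Converts each Cq to a relative concentration and divides, within each
#' sample, every gene's concentration by the arithmetic mean concentration
#' of the designated (stably expressed) reference genes.
#'
#' @param cq_tbl Tibble of Cq records (sample_id, treatment, timepoint_h,
#'   replicate, gene_id, cq, efficiency), one row per (sample, gene).
#' @param reference_genes Character vector of reference gene IDs (>= 1;
#'   two is conventional).
#' @return Input tibble with added columns `concentration` and
#'   `ref_normalized`.
#' @export
normalize_to_references <- function(cq_tbl, reference_genes) {
  assert_cols(cq_tbl, c("sample_id", "gene_id", "cq", "efficiency"), "cq_tbl")
  assert_that(length(reference_genes) >= 1, "need at least one reference gene")
  tbl <- cq_tbl |>
    dplyr::mutate(concentration = relative_concentration(.data$efficiency,
                                                         .data$cq))
  ref <- tbl |>
    dplyr::filter(.data$gene_id %in% reference_genes) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_ref = dplyr::n(),
                     ref_mean = mean(.data$concentration), .groups = "drop")
  bad <- setdiff(unique(tbl$sample_id),
                 ref$sample_id[ref$n_ref == length(reference_genes)])
  assert_that(length(bad) == 0,
              paste("missing reference-gene Cq in sample(s):",
                    paste(bad, collapse = ", ")))
  tbl |>
    dplyr::left_join(ref[, c("sample_id", "ref_mean")], by = "sample_id") |>
    dplyr::mutate(ref_normalized = .data$concentration / .data$ref_mean) |>
    dplyr::select(-"ref_mean")
}

#' Normalize to mock-treated samples and express as log2 fold change
#'
#' Within each (gene, timepoint), treated values are divided by the mean
#' reference-normalized value of the mock replicates harvested at the same
#' timepoint, then log2-transformed. Mock replicates themselves are centered
#' on the log2 scale so their mean log2 fold change is exactly 0.
#'
#' @param rel Tibble from [normalize_to_references()].
#' @param mock Treatment label of the mock control (default "mock").
#' @return Input with added column `log2fc`.
#' @export
normalize_to_mock <- function(rel, mock = "mock") {
  assert_cols(rel, c("treatment", "timepoint_h", "gene_id", "ref_normalized"),
              "rel")
  assert_that(mock %in% rel$treatment,
              sprintf("no samples with mock treatment '%s'", mock))
  mocks <- rel |>
    dplyr::filter(.data$treatment == mock) |>
    dplyr::group_by(.data$gene_id, .data$timepoint_h) |>
    dplyr::summarise(mock_mean = mean(.data$ref_normalized),
                     mock_log_mean = mean(log2(.data$ref_normalized)),
                     .groups = "drop")
  assert_that(all(mocks$mock_mean > 0), "mock mean is zero for some gene")
  rel |>
    dplyr::left_join(mocks, by = c("gene_id", "timepoint_h")) |>
    dplyr::mutate(log2fc = ifelse(
      .data$treatment == mock,
      log2(.data$ref_normalized) - .data$mock_log_mean,
      log2(.data$ref_normalized / .data$mock_mean))) |>
    dplyr::select(-"mock_mean", -"mock_log_mean")
}

# Welch t-test that tolerates zero-variance groups.
safe_welch_p <- function(a, b) {
  out <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
  if (is.na(out)) {
    out <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
  }
  out
}

#' Per-marker significance of treatment vs mock expression
#'
#' Two-sample Welch t-tests on log2 reference-normalized values, treated vs
#' mock within each (gene, treatment, timepoint), with Bonferroni correction
#' across a configurable test family (default: all timepoints of one
#' gene-by-treatment series). Groups with fewer than two replicates are
#' flagged untestable rather than dropped.
#'
#' @param rel Tibble from [normalize_to_references()] (mock normalization
#'   not required; tests use ref-normalized values).
#' @param mock Mock treatment label.
#' @param family Character vector of columns defining the Bonferroni family
#'   (default `c("gene_id", "treatment")`, i.e. correction across
#'   timepoints within a series).
#' @param alpha Significance level after correction (default 0.05).
#' @return Tibble (treatment, timepoint_h, gene_id, n_treated, n_mock,
#'   mean_log2_ratio, p_raw, p_adj, significant, testable).
#' @export
marker_significance <- function(rel, mock = "mock",
                                family = c("gene_id", "treatment"),
                                alpha = 0.05) {
  assert_cols(rel, c("treatment", "timepoint_h", "gene_id", "ref_normalized"),
              "rel")
  vals <- rel |> dplyr::mutate(logval = log2(.data$ref_normalized))
  mock_groups <- vals |>
    dplyr::filter(.data$treatment == mock) |>
    dplyr::group_by(.data$gene_id, .data$timepoint_h) |>
    dplyr::summarise(mock_vals = list(.data$logval), .groups = "drop")
  res <- vals |>
    dplyr::filter(.data$treatment != mock) |>
    dplyr::group_by(.data$treatment, .data$timepoint_h, .data$gene_id) |>
    dplyr::summarise(treated_vals = list(.data$logval), .groups = "drop") |>
    dplyr::left_join(mock_groups, by = c("gene_id", "timepoint_h")) |>
    dplyr::mutate(
      n_treated = purrr::map_int(.data$treated_vals, length),
      n_mock = purrr::map_int(.data$mock_vals, \(x) length(x %||% numeric(0))),
      testable = .data$n_treated >= 2 & .data$n_mock >= 2,
      mean_log2_ratio = purrr::map2_dbl(
        .data$treated_vals, .data$mock_vals,
        \(a, b) mean(a) - mean(b %||% NA_real_)),
      p_raw = purrr::pmap_dbl(
        list(.data$treated_vals, .data$mock_vals, .data$testable),
        \(a, b, ok) if (ok) safe_welch_p(a, b) else NA_real_))
  res |>
    dplyr::group_by(dplyr::across(dplyr::all_of(family))) |>
    dplyr::mutate(p_adj = stats::p.adjust(.data$p_raw, method = "bonferroni")) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = !is.na(.data$p_adj) & .data$p_adj < alpha) |>
    dplyr::select(-"treated_vals", -"mock_vals")
}

#' Full qPCR relative-quantification pipeline
#'
#' Technical-replicate collapse, concentration, reference normalization,
#' mock normalization and significance calls in one call.
#'
#' @inheritParams normalize_to_references
#' @inheritParams marker_significance
#' @return List with `expression` (per-replicate log2FC tibble) and
#'   `significance` (per-series test table).
#' @export
qpcr_pipeline <- function(cq_tbl, reference_genes, mock = "mock",
                          family = c("gene_id", "treatment"), alpha = 0.05) {
  rel <- cq_tbl |>
    collapse_technical_replicates() |>
    normalize_to_references(reference_genes) |>
    normalize_to_mock(mock = mock)
  list(expression = rel,
       significance = marker_significance(rel, mock = mock, family = family,
                                          alpha = alpha))
}
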