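#' Counts-per-million matrix
#'
#' @param counts Wide count tibble (gene_id + one column per sample).
#' @param norm_factors Optional tibble (sample_id, norm_factor) from
#'   [tmm_factors()]; when supplied, cpm uses effective library sizes.
#' @return Numeric matrix of cpm values (genes x samples).
#' @export
cpm_matrix <- function(counts, norm_factors = NULL) {
  m <- counts_matrix(counts)
  lib <- colSums(m)
  if (!is.null(norm_factors)) {
    f <- factor_vector(norm_factors, colnames(m))
    lib <- lib * f
  }
  sweep(m, 2, lib, "/") * 1e6
}

factor_vector <- function(norm_factors, sample_ids) {
  assert_cols(norm_factors, c("sample_id", "norm_factor"), "norm_factors")
  f <- stats::setNames(norm_factors$norm_factor, norm_factors$sample_id)
  missing <- setdiff(sample_ids, names(f))
  assert_that(length(missing) == 0,
              paste("no normalization factor for sample(s):",
                    paste(missing, collapse = ", ")))
  unname(f[sample_ids])
}

#' Filter genes by expression level
#'
#' Keeps genes whose counts-per-million (computed on raw library sizes)
#' exceed `cpm_min` in at least `n_min` samples. Gene order is preserved.
#'
#' @param counts Wide count tibble.
#' @param cpm_min Minimum cpm (default 0.5, exclusive).
#' @param n_min Minimum number of samples above `cpm_min` (default 3).
#' @return Filtered count tibble.
#' @export
filter_genes <- function(counts, cpm_min = 0.5, n_min = 3) {
  cpm <- cpm_matrix(counts)
  keep <- rowSums(cpm > cpm_min) >= n_min
  assert_that(any(keep), "no genes pass the expression filter")
  counts[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors between samples: the reference
#' sample is the one whose upper-quartile cpm is closest to the mean upper
#' quartile; per sample, log2 ratios (M) and average log2 abundances (A)
#' against the reference are doubly trimmed (30% on M, 5% on A, both tails)
#' and combined by a precision-weighted mean; factors are rescaled to
#' geometric mean 1. Delegates to the standard edgeR implementation of
#' this procedure.
#'
#' @param counts Wide count tibble (>= 2 samples).
#' @param logratio_trim Two-sided trim fraction on M values (default 0.3).
#' @param abs_trim Two-sided trim fraction on A values (default 0.05).
#' @return Tibble (sample_id, norm_factor), geometric mean 1.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  m <- counts_matrix(counts)
  assert_that(ncol(m) >= 2, "TMM needs at least 2 samples")
  f <- edgeR::calcNormFactors(m, method = "TMM",
                              logratioTrim = logratio_trim,
                              sumTrim = abs_trim)
  tibble(sample_id = colnames(m), norm_factor = as.numeric(f))
}

#' Moderated log2 counts-per-million
#'
#' `log2((y + prior) / effective_library_size * 1e6)`: a prior count
#' (default 2) is added to each gene count so zeros never hit the
#' logarithm. The prior is added to the numerator only; the library size
#' is not adjusted.
#'
#' @param counts Wide count tibble.
#' @param norm_factors Optional TMM factors; effective library size =
#'   raw library size x factor.
#' @param prior Prior count (default 2).
#' @return Wide tibble of moderated log2 cpm (gene_id + samples).
#' @export
moderated_log2cpm <- function(counts, norm_factors = NULL, prior = 2) {
  m <- counts_matrix(counts)
  lib <- colSums(m)
  if (!is.null(norm_factors)) lib <- lib * factor_vector(norm_factors, colnames(m))
  out <- log2(sweep(m + prior, 2, lib, "/") * 1e6)
  matrix_to_counts(out)
}

# Per-gene TREAT-style statistics for one two-group comparison.
# Returns b (log2FC), se, and the pieces needed to price any threshold tau.
treat_statistics <- function(counts, samples, treatment, control,
                             norm_factors = NULL, offset_cpm = 0.5,
                             d0 = 10) {
  assert_cols(samples, c("sample_id", "treatment"), "samples")
  m <- counts_matrix(counts)
  ids_t <- samples$sample_id[samples$treatment == treatment]
  ids_c <- samples$sample_id[samples$treatment == control]
  assert_that(length(ids_t) >= 2 && length(ids_c) >= 2,
              "need at least 2 replicates per group")
  assert_that(all(c(ids_t, ids_c) %in% colnames(m)),
              "sample sheet and count matrix disagree on sample IDs")
  if (is.null(norm_factors)) norm_factors <- tmm_factors(counts)
  eff <- colSums(m) * factor_vector(norm_factors, colnames(m))
  cpm <- sweep(m, 2, eff, "/") * 1e6
  # normalized counts on the scale of the typical library, for the
  # mean-variance model
  lbar <- exp(mean(log(eff[c(ids_t, ids_c)])))
  ncount <- cpm * lbar / 1e6
  nt <- length(ids_t)
  nc <- length(ids_c)
  mt_cpm <- rowMeans(cpm[, ids_t, drop = FALSE])
  mc_cpm <- rowMeans(cpm[, ids_c, drop = FALSE])
  b <- log2((mt_cpm + offset_cpm) / (mc_cpm + offset_cpm))
  # method-of-moments NB dispersion pooled within groups, shrunk to the
  # across-gene median with d0 pseudo-degrees of freedom
  mom <- function(ids) {
    x <- ncount[, ids, drop = FALSE]
    mu <- rowMeans(x)
    v <- apply(x, 1, stats::var)
    (v - mu) / pmax(mu, 1e-8)^2
  }
  phi_hat <- pmax(0, ((nt - 1) * mom(ids_t) + (nc - 1) * mom(ids_c)) /
                    (nt - 1 + nc - 1))
  phi0 <- stats::median(phi_hat[is.finite(phi_hat)])
  df <- nt + nc - 2
  phi <- (d0 * phi0 + df * phi_hat) / (d0 + df)
  off_n <- offset_cpm * lbar / 1e6
  mt_n <- mt_cpm * lbar / 1e6 + off_n
  mc_n <- mc_cpm * lbar / 1e6 + off_n
  se <- (1 / log(2)) * sqrt((1 + phi * mt_n) / (nt * mt_n) +
                              (1 + phi * mc_n) / (nc * mc_n))
  tibble(gene_id = rownames(m), mean_cpm_treatment = mt_cpm,
         mean_cpm_control = mc_cpm, log2fc = unname(b), se = unname(se),
         dispersion = unname(phi))
}

treat_pvalue <- function(b, se, tau) {
  stats::pnorm((abs(b) - tau) / se, lower.tail = FALSE) +
    stats::pnorm((abs(b) + tau) / se, lower.tail = FALSE)
}

#' Fold-change-threshold differential expression test
#'
#' Tests, per gene, the composite null |log2FC| <= tau against a normal
#' reference: the fold-change estimate is the log2 ratio of offset group
#' mean cpm (TMM-normalized), its standard error comes from the
#' negative-binomial mean-variance relation via the delta method, with a
#' method-of-moments dispersion shrunk toward the across-gene median.
#' Genes are called up/down when the BH-adjusted p-value falls below `fdr`
#' and the fold change exceeds the threshold.
#'
#' @param counts Wide count tibble (already expression-filtered).
#' @param samples Sample sheet tibble (sample_id, treatment, ...).
#' @param treatment,control Treatment labels of the two groups.
#' @param tau Log2 fold-change threshold (default log2(1.3)).
#' @param fdr False discovery rate cutoff for calls (default 0.05).
#' @param norm_factors Optional TMM factors (computed from `counts` if NULL).
#' @param offset_cpm Stabilizing offset added to group mean cpm (default 0.5).
#' @param d0 Prior pseudo-degrees for dispersion shrinkage (default 10).
#' @return Tibble of class `deg_result` (gene_id, mean cpm per group,
#'   log2fc, se, dispersion, p_value, q_value, call in up/down/ns), with
#'   attributes `tau`, `fdr`, `treatment`, `control`.
#' @export
treat_test <- function(counts, samples, treatment, control,
                       tau = log2(1.3), fdr = 0.05, norm_factors = NULL,
                       offset_cpm = 0.5, d0 = 10) {
  assert_that(tau >= 0, "tau must be >= 0")
  st <- treat_statistics(counts, samples, treatment, control,
                         norm_factors = norm_factors,
                         offset_cpm = offset_cpm, d0 = d0)
  out <- st |>
    dplyr::mutate(
      p_value = treat_pvalue(.data$log2fc, .data$se, tau),
      q_value = bh_fdr(.data$p_value),
      call = dplyr::case_when(
        .data$q_value < fdr & .data$log2fc > tau ~ "up",
        .data$q_value < fdr & .data$log2fc < -tau ~ "down",
        TRUE ~ "ns"))
  structure(out, class = c("deg_result", class(out)),
            tau = tau, fdr = fdr, treatment = treatment, control = control)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (wraps
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p Vector of p-values in [0, 1].
#' @return Vector of q-values, monotone in the p-value ranks.
#' @export
bh_fdr <- function(p) {
  assert_that(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' DEG counts along a grid of fold-change thresholds
#'
#' For each treatment (vs the shared control), counts the genes called
#' differentially expressed at every threshold of a uniform grid. The
#' fold-change estimates and standard errors are computed once per
#' treatment; only the threshold-dependent p-values are re-priced along
#' the grid.
#'
#' @param counts Filtered wide count tibble.
#' @param samples Sample sheet.
#' @param treatments Treatment labels to scan (default: all non-control).
#' @param control Control label (default "mock").
#' @param tau_grid Uniform threshold grid (default seq(0.1, 1.5, 0.02)).
#' @param fdr FDR cutoff (default 0.05).
#' @param norm_factors Optional TMM factors.
#' @inheritParams treat_test
#' @return Tibble (treatment, tau, n_deg).
#' @export
deg_count_curve <- function(counts, samples, treatments = NULL,
                            control = "mock",
                            tau_grid = seq(0.1, 1.5, by = 0.02),
                            fdr = 0.05, norm_factors = NULL,
                            offset_cpm = 0.5, d0 = 10) {
  treatments <- treatments %||%
    setdiff(unique(samples$treatment), control)
  if (is.null(norm_factors)) norm_factors <- tmm_factors(counts)
  purrr::map_dfr(treatments, function(tr) {
    st <- treat_statistics(counts, samples, tr, control,
                           norm_factors = norm_factors,
                           offset_cpm = offset_cpm, d0 = d0)
    purrr::map_dfr(tau_grid, function(tau) {
      p <- treat_pvalue(st$log2fc, st$se, tau)
      q <- bh_fdr(p)
      tibble(treatment = tr, tau = tau,
             n_deg = sum(q < fdr & abs(st$log2fc) > tau))
    })
  })
}

#' Maximum-curvature (elbow) point of a curve on a uniform grid
#'
#' Returns the interior grid point maximizing the discrete second
#' difference `y[i-1] - 2 y[i] + y[i+1]`; ties break to the smallest x.
#' Used both for the fold-change threshold (DEG count vs threshold) and
#' for choosing k in k-means (within-SS vs k).
#'
#' @param x Uniform grid (>= 3 points).
#' @param y Curve values at the grid points.
#' @return List: `elbow` (the x value), `index`, `second_diff`.
#' @export
find_elbow <- function(x, y) {
  assert_that(length(x) >= 3, "need at least 3 grid points")
  steps <- diff(x)
  assert_that(all(abs(steps - steps[1]) <= 1e-8 * max(abs(steps))),
              "threshold grid must be uniform")
  i <- seq(2, length(x) - 1)
  d2 <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (max(d2) - min(d2) <= .Machine$double.eps * max(1, max(abs(y)))) {
    warning("curve has no curvature; returning smallest interior grid point")
    return(list(elbow = x[2], index = 2L, second_diff = d2))
  }
  best <- i[which.max(d2)]  # which.max takes the first (smallest x) on ties
  list(elbow = x[best], index = best, second_diff = d2)
}

#' Elbow selection of the fold-change threshold
#'
#' Chooses, per treatment, the threshold at the point of maximum curvature
#' (largest discrete second difference) of the DEG count as a function of
#' the log2 fold-change threshold, then takes the median elbow across
#' treatments (lower median for an even number of treatments).
#'
#' @param curves Tibble from [deg_count_curve()] (treatment, tau, n_deg).
#' @return List of class `elbow_curve`: `curves`, `per_treatment`
#'   (tibble: treatment, elbow), `threshold` (the median elbow).
#' @export
elbow_threshold <- function(curves) {
  assert_cols(curves, c("treatment", "tau", "n_deg"), "curves")
  per <- curves |>
    dplyr::group_by(.data$treatment) |>
    dplyr::arrange(.data$tau, .by_group = TRUE) |>
    dplyr::summarise(elbow = find_elbow(.data$tau, .data$n_deg)$elbow,
                     .groups = "drop")
  structure(list(curves = curves, per_treatment = per,
                 threshold = lower_median(per$elbow)),
            class = "elbow_curve")
}

# Median that resolves an even count to the lower middle value.
lower_median <- function(x) {
  s <- sort(x)
  s[ceiling(length(s) / 2)]
}

#' @export
print.elbow_curve <- function(x, ...) {
  cat("Elbow-selected fold-change threshold\n")
  print(as.data.frame(x$per_treatment))
  cat(sprintf("chosen threshold (median elbow): %.4f\n", x$threshold))
  invisible(x)
}

#' @method glance deg_result
#' @export
glance.deg_result <- function(x, ...) {
  tibble(treatment = attr(x, "treatment"), control = attr(x, "control"),
         tau = attr(x, "tau"), fdr = attr(x, "fdr"),
         n_genes = nrow(x),
         n_up = sum(x$call == "up"), n_down = sum(x$call == "down"))
}

#' Genes called differentially expressed
#'
#' @param deg A `deg_result` from [treat_test()].
#' @param direction "any", "up" or "down".
#' @return Character vector of gene IDs.
#' @export
deg_genes <- function(deg, direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  if (direction == "any") deg$gene_id[deg$call != "ns"]
  else deg$gene_id[deg$call == direction]
}
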