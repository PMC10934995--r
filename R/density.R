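#' Bacterial density (CFU per gram) from plate counts
#'
#' Converts colony counts to CFU per gram of plant fresh weight:
#' `raw = colony_count * dilution_factor / (plated_fraction * plant_weight)`.
#' To accommodate plants below the limit of detection, a pseudo-count
#' (default 10^2 CFU g^-1) is added to every sample. The per-sample
#' detection limit is the density corresponding to a single colony at the
#' plated dilution, computed with the same formula.
#'
#' @param cfu_tbl Tibble with columns colony_count, dilution_factor,
#'   plated_fraction, plant_weight (identifying columns are preserved).
#' @param pseudo Pseudo-count added to every sample, CFU g^-1 (default 100).
#' @return Input with added columns raw_cfu_per_g, cfu_per_g (pseudo-counted),
#'   below_detection, detection_limit.
#' @export
cfu_per_gram <- function(cfu_tbl, pseudo = 100) {
  assert_cols(cfu_tbl, c("colony_count", "dilution_factor", "plated_fraction",
                         "plant_weight"), "cfu_tbl")
  assert_that(all(cfu_tbl$plated_fraction > 0), "plated_fraction must be > 0")
  assert_that(all(cfu_tbl$plant_weight > 0), "plant_weight must be > 0")
  assert_that(all(cfu_tbl$dilution_factor >= 1), "dilution_factor must be >= 1")
  assert_that(all(cfu_tbl$colony_count >= 0), "colony_count must be >= 0")
  cfu_tbl |>
    dplyr::mutate(
      raw_cfu_per_g = .data$colony_count * .data$dilution_factor /
        (.data$plated_fraction * .data$plant_weight),
      cfu_per_g = .data$raw_cfu_per_g + pseudo,
      below_detection = .data$colony_count == 0,
      detection_limit = .data$dilution_factor /
        (.data$plated_fraction * .data$plant_weight))
}

#' Range of the detection limit across plants
#'
#' Summarises per-sample detection limits (driven by plant weight and the
#' lowest plated dilution) as a min/max range, the band drawn behind
#' density-versus-time plots.
#'
#' @param density_tbl Output of [cfu_per_gram()].
#' @return One-row tibble (limit_min, limit_max).
#' @export
detection_limit_range <- function(density_tbl) {
  assert_cols(density_tbl, "detection_limit", "density_tbl")
  tibble(limit_min = min(density_tbl$detection_limit),
         limit_max = max(density_tbl$detection_limit))
}

#' Linear dose-response regression against log bacterial density
#'
#' Ordinary least squares of a response (e.g. marker-gene log2 fold change,
#' or plant weight) on log10 bacterial density. Reports slope, intercept,
#' R^2, adjusted R^2 and the F-test p-value.
#'
#' @param data Data frame of paired observations.
#' @param response,density Column names (unquoted) of the response and the
#'   bacterial density.
#' @param log10_density Take log10 of the density column first (default
#'   TRUE; set FALSE if it is already on the log scale).
#' @return Object of class `density_fit` (supports [tidy()], [glance()],
#'   `autoplot()`, `print()`).
#' @export
density_regression <- function(data, response, density, log10_density = TRUE) {
  y <- dplyr::pull(data, {{ response }})
  x <- dplyr::pull(data, {{ density }})
  if (log10_density) x <- log10(x)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  assert_that(length(x) >= 3, "need at least 3 finite observations")
  assert_that(stats::var(x) > 0, "density values have zero variance")
  fit <- stats::lm(y ~ x)
  structure(list(fit = fit, data = tibble(x = x, y = y),
                 log10_density = log10_density),
            class = "density_fit")
}

#' @export
print.density_fit <- function(x, ...) {
  g <- glance(x)
  cat("Dose-response linear fit (n =", g$n, ")\n")
  cat(sprintf("  slope = %.4g, intercept = %.4g\n", g$slope, g$intercept))
  cat(sprintf("  R^2 = %.3f, adj. R^2 = %.3f, F-test p = %.4g\n",
              g$r_squared, g$adj_r_squared, g$p_value))
  invisible(x)
}

#' Dose-response regression on per-group means
#'
#' Convenience wrapper mirroring the common display: responses and densities
#' are first averaged within groups (e.g. strain x timepoint), then the
#' group means are regressed on log10 mean density.
#'
#' @param data Data frame of per-replicate observations.
#' @param response,density Unquoted column names.
#' @param ... Unquoted grouping columns.
#' @inheritParams density_regression
#' @return A `density_fit` on the group means.
#' @export
mean_density_regression <- function(data, response, density, ...,
                                    log10_density = TRUE) {
  means <- data |>
    dplyr::group_by(...) |>
    dplyr::summarise(.response = mean({{ response }}),
                     .density = mean({{ density }}), .groups = "drop")
  density_regression(means, ".response", ".density",
                     log10_density = log10_density)
}

#' One-way ANOVA with Tukey HSD letters on log10 densities
#'
#' Compares bacterial densities between groups on the log10 scale:
#' one-way ANOVA, Tukey honest significant differences, and a compact
#' letter display (groups sharing a letter are not significantly
#' different).
#'
#' @param density_tbl Output of [cfu_per_gram()] (or any tibble with the
#'   value column).
#' @param group Unquoted grouping column (e.g. treatment).
#' @param value Unquoted value column (default `cfu_per_g`).
#' @param log10_value Test on log10 of the value (default TRUE).
#' @param alpha Family-wise level for the letters (default 0.05).
#' @return List of class `cfu_comparison`: `anova` (tibble: df, F, p),
#'   `tukey` (pairwise tibble), `letters` (tibble: group, letter).
#' @export
group_compare_cfu <- function(density_tbl, group, value = cfu_per_g,
                              log10_value = TRUE, alpha = 0.05) {
  g <- factor(dplyr::pull(density_tbl, {{ group }}))
  v <- dplyr::pull(density_tbl, {{ value }})
  if (log10_value) v <- log10(v)
  assert_that(nlevels(g) >= 2, "need at least 2 groups")
  sizes <- table(g)
  assert_that(all(sizes >= 2), paste(
    "group(s) with fewer than 2 observations:",
    paste(names(sizes)[sizes < 2], collapse = ", ")))
  d <- data.frame(v = v, g = g)
  fit <- stats::aov(v ~ g, data = d)
  an <- summary(fit)[[1]]
  anova_tbl <- tibble(term = trimws(rownames(an)), df = an$Df,
                      sum_sq = an$`Sum Sq`, statistic = an$`F value`,
                      p_value = an$`Pr(>F)`)
  tk <- stats::TukeyHSD(fit)$g
  tukey_tbl <- tibble(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"])
  letters_tbl <- tryCatch({
    glht <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
    cl <- multcomp::cld(glht, level = alpha)
    tibble(group = names(cl$mcletters$Letters),
           letter = unname(cl$mcletters$Letters))
  }, error = function(e) {
    # degenerate fits (e.g. zero residual variance): fall back to letters
    # derived directly from the Tukey adjusted p-values
    tibble(group = levels(g), letter = cld_from_pvalues(levels(g), tukey_tbl,
                                                        alpha))
  })
  structure(list(anova = anova_tbl, tukey = tukey_tbl, letters = letters_tbl),
            class = "cfu_comparison")
}

# Greedy compact-letter display from a pairwise p-value table.
cld_from_pvalues <- function(groups, tukey_tbl, alpha) {
  k <- length(groups)
  differ <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(tukey_tbl))) {
    pair <- strsplit(tukey_tbl$contrast[i], "-", fixed = TRUE)[[1]]
    sig <- is.finite(tukey_tbl$p_adj[i]) && tukey_tbl$p_adj[i] < alpha
    differ[pair[1], pair[2]] <- differ[pair[2], pair[1]] <- sig
  }
  sets <- list()
  for (g in groups) {
    placed <- FALSE
    for (i in seq_along(sets)) {
      if (!any(differ[g, sets[[i]]])) {
        sets[[i]] <- c(sets[[i]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- g
  }
  vapply(groups, function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
          collapse = "")
  }, character(1))
}

#' @export
print.cfu_comparison <- function(x, ...) {
  cat("One-way ANOVA on log10 densities:\n")
  print(as.data.frame(x$anova))
  cat("\nTukey HSD letters:\n")
  print(as.data.frame(x$letters))
  invisible(x)
}
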