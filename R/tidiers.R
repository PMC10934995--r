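#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy density_fit
#' @export
tidy.density_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("intercept", "slope"),
         estimate = s[, "Estimate"],
         std_error = s[, "Std. Error"],
         statistic = s[, "t value"],
         p_value = s[, "Pr(>|t|)"])
}

#' @method glance density_fit
#' @export
glance.density_fit <- function(x, ...) {
  # computed directly so a zero-variance response degrades gracefully
  # (R^2 = 0, F-test p = 1) instead of returning numerical noise
  y <- x$data$y
  n <- length(y)
  rss <- sum(stats::residuals(x$fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss <= 0) 0 else 1 - rss / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  f <- if (rss <= 0 || r2 >= 1) Inf else (r2 / (1 - r2)) * (n - 2)
  p <- if (tss <= 0) 1 else
    stats::pf(f, 1, n - 2, lower.tail = FALSE)
  tibble(slope = unname(stats::coef(x$fit)[2]),
         intercept = unname(stats::coef(x$fit)[1]),
         r_squared = r2, adj_r_squared = adj, p_value = p, n = n)
}

#' @method tidy cfu_comparison
#' @export
tidy.cfu_comparison <- function(x, ...) x$tukey

#' @method glance cfu_comparison
#' @export
glance.cfu_comparison <- function(x, ...) {
  tibble(statistic = x$anova$statistic[1], p_value = x$anova$p_value[1],
         df = x$anova$df[1], n_groups = nrow(x$letters))
}

#' @method tidy kmeans_profile
#' @export
tidy.kmeans_profile <- function(x, ...) x$clusters
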