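test_that("expression filter keeps genes above 0.5 cpm in >= 3 samples", {
  m <- matrix(0, 4, 4)
  m[2, 1:3] <- 1        # cpm 1 in 3 samples at lib 1e6 -> kept
  m[3, 1:2] <- 1000     # above threshold in only 2 samples -> removed
  m[4, ] <- 50          # comfortably expressed
  m[1, 4] <- 1e6 - colSums(m)[4]  # pad so every library is 1e6
  m[1, 1:3] <- 1e6 - colSums(m[2:4, 1:3])
  stopifnot(all(colSums(m) == 1e6))
  counts <- make_counts(m)
  kept <- filter_genes(counts)$gene_id
  expect_true("g002" %in% kept)
  expect_false("g003" %in% kept)
  expect_true("g004" %in% kept)
  # all-zero gene is always removed
  expect_false(any(filter_genes(make_counts(rbind(m, 0)))$gene_id == "g005"))
  expect_error(filter_genes(make_counts(matrix(0, 2, 4) + 0.0)), "filter")
})

test_that("TMM factors: identical samples, pure depth scaling, and the oracle", {
  m <- withr::with_seed(1, matrix(rpois(2000, 100), 500, 4))
  same <- make_counts(cbind(m[, 1], m[, 1], m[, 1], m[, 1]))
  expect_equal(tmm_factors(same)$norm_factor, rep(1, 4))

  depth <- make_counts(cbind(m[, 1], m[, 1] * 2L))
  f <- tmm_factors(depth)$norm_factor
  expect_equal(f[2] / f[1], 1, tolerance = 1e-9)

  # asymmetric expression changes: agree with an independent
  # re-implementation of the doubly trimmed weighted mean
  skew <- m
  up <- withr::with_seed(2, sample.int(500, 50))
  skew[up, 2] <- skew[up, 2] * 8L
  got <- tmm_factors(make_counts(skew))$norm_factor
  want <- tmm_oracle(skew)
  expect_true(all(got / want >= 0.97 & got / want <= 1.03))
})

test_that("moderated log2 cpm adds the prior to the numerator only", {
  m <- matrix(c(0, 1e6, 10, 1e6 - 10), 2, 2)   # columns sum to 1e6
  lc <- moderated_log2cpm(make_counts(m), prior = 2)
  expect_equal(lc[[2]][1], log2((0 + 2) / 1e6 * 1e6))  # exactly 1

  pos <- make_counts(matrix(c(10, 20, 40, 30), 2, 2))
  lc0 <- moderated_log2cpm(pos, prior = 0)
  cpm <- cpm_matrix(pos)
  expect_equal(as.matrix(lc0[, -1]), log2(cpm), ignore_attr = TRUE)

  # doubling counts and libraries moves values by at most the prior bound
  y <- matrix(c(5, 10, 20, 40), 2, 2)
  d1 <- as.matrix(moderated_log2cpm(make_counts(y), prior = 2)[, -1])
  d2 <- as.matrix(moderated_log2cpm(make_counts(2 * y), prior = 2)[, -1])
  expect_true(all(abs(d2 - d1) <= log2(1 + 2 / (min(y) + 2))))
})

test_that("BH adjustment is the standard step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- withr::with_seed(3, runif(100))
  q <- bh_fdr(p)
  expect_true(all(q[order(p)] == cummax(q[order(p)])))  # monotone
  expect_true(all(q <= 1))
})

test_that("identical groups yield no calls and p-values of one", {
  m <- withr::with_seed(4, matrix(rpois(600 * 3, 200), 600, 3))
  counts <- make_counts(cbind(m, m))
  names(counts)[-1] <- two_group_samples()$sample_id
  res <- treat_test(counts, two_group_samples(), "trt", "ctrl")
  expect_equal(res$log2fc, rep(0, 600))
  expect_true(all(res$p_value >= 0.5))
  expect_true(all(res$call == "ns"))
})

test_that("the threshold test finds planted effects at controlled error", {
  counts <- nb_two_group(550, 3, baseline = 1000,
                         beta = c(rep(0, 500), rep(3, 25), rep(-3, 25)),
                         phi = 0.05, seed = 101)
  res <- treat_test(counts, two_group_samples(), "trt", "ctrl")
  truth <- c(rep(FALSE, 500), rep(TRUE, 50))
  called <- res$call != "ns"
  expect_gte(mean(called[truth]), 0.8)           # power
  expect_lte(sum(called & !truth) / max(1, sum(called)), 0.1)
  # direction agrees with the planted sign
  expect_true(all(res$call[501:525][called[501:525]] == "up"))
  expect_true(all(res$call[526:550][called[526:550]] == "down"))
})

test_that("an infinite threshold silences every call; tau = 0 is the Wald limit", {
  counts <- nb_two_group(200, 3, 500, rep(c(0, 2), each = 100), 0.05, 7)
  res_inf <- treat_test(counts, two_group_samples(), "trt", "ctrl", tau = 1e6)
  expect_true(all(res_inf$call == "ns"))
  r0 <- treat_test(counts, two_group_samples(), "trt", "ctrl", tau = 0)
  r1 <- treat_test(counts, two_group_samples(), "trt", "ctrl", tau = 0.5)
  expect_true(all(r0$p_value <= r1$p_value + 1e-12))
})

test_that("DEG counts are nonincreasing in the threshold and the FDR cutoff", {
  counts <- nb_two_group(400, 3, 800, rep(c(0, 1, 2, 3), each = 100), 0.05, 11)
  curve <- deg_count_curve(counts, two_group_samples(),
                           treatments = "trt", control = "ctrl",
                           tau_grid = seq(0.1, 1.5, 0.1))
  expect_true(all(diff(curve$n_deg) <= 0))
  n_at_fdr <- vapply(c(0.01, 0.05, 0.1), function(fdr) {
    sum(treat_test(counts, two_group_samples(), "trt", "ctrl",
                   fdr = fdr)$call != "ns")
  }, numeric(1))
  expect_true(all(diff(n_at_fdr) >= 0))
})

test_that("pipeline calls are invariant to gene and sample order", {
  counts <- nb_two_group(300, 3, 600, rep(c(0, 3), each = 150), 0.05, 13)
  samples <- two_group_samples()
  res <- treat_test(filter_genes(counts), samples, "trt", "ctrl")
  perm_g <- withr::with_seed(1, sample.int(nrow(counts)))
  perm_s <- withr::with_seed(2, sample.int(nrow(samples)))
  counts2 <- counts[perm_g, c(1, 1 + perm_s)]
  res2 <- treat_test(filter_genes(counts2), samples[perm_s, ], "trt", "ctrl")
  res2 <- res2[match(res$gene_id, res2$gene_id), ]
  expect_equal(res$call, res2$call)
  expect_equal(res$log2fc, res2$log2fc)
})

test_that("elbow rule finds kinks, medians and degenerate curves as specified", {
  # piecewise-linear curve with a single kink at 0.38
  x <- seq(0.1, 0.7, by = 0.02)
  y <- ifelse(x <= 0.38, 200 - 400 * (x - 0.1), 88 - 20 * (x - 0.38))
  expect_equal(find_elbow(x, y)$elbow, 0.38)

  # linear curve: every second difference 0 -> smallest interior + warning
  expect_warning(e <- find_elbow(x, 100 - 50 * x), "curvature")
  expect_equal(e$elbow, x[2])

  curves <- dplyr::bind_rows(lapply(
    list(c("a", 0.30), c("b", 0.38), c("c", 0.50)),
    function(tc) {
      kink <- as.numeric(tc[2])
      tibble::tibble(treatment = tc[1], tau = x,
                     n_deg = ifelse(x <= kink, 300 - 500 * (x - 0.1),
                                    300 - 500 * (kink - 0.1) - 10 * (x - kink)))
    }))
  eb <- elbow_threshold(curves)
  expect_equal(eb$per_treatment$elbow, c(0.30, 0.38, 0.50))
  expect_equal(eb$threshold, 0.38)  # the same cutoff as log2(1.3) ~ 0.3785

  # even number of treatments: lower median
  eb2 <- elbow_threshold(curves[curves$treatment != "c", ])
  expect_equal(eb2$threshold, 0.30)

  # non-uniform grids are rejected
  bad <- tibble::tibble(treatment = "a", tau = c(0.1, 0.2, 0.4),
                        n_deg = c(3, 2, 1))
  expect_error(elbow_threshold(bad), "uniform")
})
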