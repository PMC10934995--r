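test_that("the 150 bp overlap rule assigns states at the boundary exactly", {
  seg <- tibble::tibble(chrom = "chr1", start = c(0, 1000), end = c(1000, 2000),
                        state = c("2", "3"))
  # 150 bp gene fully inside one state
  inside <- tibble::tibble(gene_id = "gA", chrom = "chr1",
                           start = 100, end = 250)
  got <- assign_states(inside, seg)
  expect_equal(got$state, "2")
  expect_equal(got$overlap_bp, 150)

  # 149 bp in state 2, 151 bp in state 3: only state 3 passes
  straddle <- tibble::tibble(gene_id = "gB", chrom = "chr1",
                             start = 851, end = 1151)
  got2 <- assign_states(straddle, seg)
  expect_equal(got2$state, "3")
})

test_that("overlaps with split segments of the same state are summed", {
  whole <- tibble::tibble(chrom = "chr1", start = 0, end = 1000, state = "1")
  halves <- tibble::tibble(chrom = "chr1", start = c(0, 400),
                           end = c(400, 1000), state = "1")
  genes <- tibble::tibble(gene_id = "g", chrom = "chr1", start = 300,
                          end = 600)
  expect_equal(as.data.frame(assign_states(genes, whole)),
               as.data.frame(assign_states(genes, halves)))
  # 100 bp + 200 bp across the split still clears the 150 bp rule
  expect_equal(assign_states(genes, halves)$overlap_bp, 300)
})

test_that("assignments match the per-base labelling oracle on random genomes", {
  for (seed in c(11, 12, 13)) {
    ann <- random_annotation(seed, genome = 1e5, n_genes = 60)
    got <- assign_states(ann$genes, ann$seg)
    want <- assign_states_oracle(ann$genes, ann$seg)
    expect_equal(as.data.frame(got)[, c("gene_id", "state", "overlap_bp")],
                 as.data.frame(want), ignore_attr = TRUE)
  }
})

test_that("genes on chromosomes missing from the segmentation warn, not fail", {
  seg <- tibble::tibble(chrom = "chr1", start = 0, end = 1000, state = "1")
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = c("chr1", "chr9"),
                          start = c(0, 0), end = c(500, 500))
  expect_warning(got <- assign_states(genes, seg), "chr9")
  expect_equal(got$gene_id, "g1")
  # the unassigned gene still counts in the background denominator
  expect_equal(state_proportions(got)$n, 2)
})

test_that("state proportions count multi-state genes in every state they carry", {
  seg <- tibble::tibble(chrom = "chr1", start = c(0, 500), end = c(500, 1000),
                        state = c("1", "2"))
  genes <- tibble::tibble(gene_id = sprintf("g%d", 1:10), chrom = "chr1",
                          start = c(rep(0, 4), rep(600, 5), 300),
                          end = c(rep(400, 4), rep(950, 5), 800))
  asn <- assign_states(genes, seg)
  ps <- state_proportions(asn, sprintf("g%d", 1:10))
  expect_equal(ps$x[ps$state == "1"], 5L)  # 4 inside + 1 straddler
  expect_equal(ps$x[ps$state == "2"], 6L)  # 5 inside + 1 straddler
  expect_equal(ps$p, ps$x / 10)
  expect_gt(sum(ps$p), 1)  # proportions need not sum to 1

  # set = all genes reproduces the genome background identically
  expect_equal(state_proportions(asn, NULL), state_proportions(asn))
  expect_warning(ps2 <- state_proportions(asn, c("g1", "nope")), "ignored")
  expect_true(all(ps2$n == 1L))
})

test_that("Marascuilo critical ranges match the closed form", {
  res <- marascuilo(c(40, 10), c(100, 100))
  want_r <- sqrt(qchisq(0.95, 1)) * sqrt(0.4 * 0.6 / 100 + 0.1 * 0.9 / 100)
  expect_equal(res$crit_range, want_r, tolerance = 1e-12)
  expect_equal(res$abs_diff, 0.30)
  expect_true(res$significant)  # 0.30 > 0.1126

  # identical groups are never flagged
  eq <- marascuilo(c(25, 25), c(80, 80))
  expect_equal(eq$abs_diff, 0)
  expect_false(eq$significant)

  # three groups: all pairs, chi-squared with k - 1 df
  res3 <- marascuilo(c(10, 20, 30), c(50, 50, 50), labels = c("a", "b", "c"))
  expect_equal(nrow(res3), 3)
  p <- c(0.2, 0.4, 0.6)
  want <- sqrt(qchisq(0.95, 2)) *
    sqrt(p[1] * (1 - p[1]) / 50 + p[3] * (1 - p[3]) / 50)
  expect_equal(res3$crit_range[res3$group1 == "a" & res3$group2 == "c"], want)

  expect_error(marascuilo(c(5, 60), c(10, 50)), "x must")
  expect_error(marascuilo(10, 20), "k >= 2")
})

test_that("Marascuilo keeps its family-wise error under the null", {
  # k = 3 equal proportions; any flagged pair is a family-wise error
  n_sim <- 500
  fwer <- withr::with_seed(8, mean(vapply(seq_len(n_sim), function(i) {
    x <- rbinom(3, 200, 0.3)
    any(marascuilo(x, rep(200, 3))$significant)
  }, logical(1))))
  expect_lte(fwer, 0.05 + 2 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("enrichment against the genome flags nothing for the background itself", {
  ann <- random_annotation(21, genome = 2e5, n_genes = 200)
  asn <- assign_states(ann$genes, ann$seg)
  enr <- enrichment_analysis(asn, ann$genes$gene_id)
  expect_true(all(enr$direction == "none"))
  expect_true(all(enr$abs_diff == 0))
  # joint mode widens critical ranges
  enr_joint <- enrichment_analysis(asn, ann$genes$gene_id[1:50],
                                   mode = "joint")
  enr_pair <- enrichment_analysis(asn, ann$genes$gene_id[1:50])
  expect_true(all(enr_joint$crit_range > enr_pair$crit_range))
})

test_that("planted state bias among responsive genes is recovered as enrichment", {
  cfg <- sim_config(seed = 101, n_genes = 1000, genome_length = 1e7,
                    frac_de = 0.2, state_de_bias = c(3, rep(1, 8)))
  sc <- simulate_counts(cfg)
  enr <- enrichment_analysis(sc$truth$gene_states, sc$truth$de_genes)
  expect_equal(enr$direction[enr$state == "1"], "enriched")
})
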