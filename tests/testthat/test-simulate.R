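test_that("segmentation tiles the genome and tracks target state coverage", {
  cfg <- sim_config(seed = 42, n_states = 2, state_props = c(0.5, 0.5),
                    genome_length = 1e6)
  seg <- simulate_segmentation(cfg)
  expect_equal(seg$start[1], 0)
  expect_equal(seg$end[nrow(seg)], 1e6)
  expect_true(all(seg$start[-1] == seg$end[-nrow(seg)])) # contiguous
  cov1 <- sum((seg$end - seg$start)[seg$state == "1"]) / 1e6
  expect_gte(cov1, 0.48)
  expect_lte(cov1, 0.52)

  # uneven target proportions are also realized within 2%
  cfg9 <- sim_config(seed = 7, n_states = 3, state_props = c(0.6, 0.3, 0.1),
                     genome_length = 1e6)
  seg9 <- simulate_segmentation(cfg9)
  realized <- tapply(seg9$end - seg9$start, seg9$state, sum) / 1e6
  expect_true(all(abs(realized[c("1", "2", "3")] - c(0.6, 0.3, 0.1)) < 0.02))
})

test_that("degenerate one-state config yields a single full-genome label", {
  cfg <- sim_config(seed = 1, n_states = 1, state_props = 1,
                    state_de_bias = 1, genome_length = 5e4)
  seg <- simulate_segmentation(cfg)
  expect_true(all(seg$state == "1"))
  expect_equal(min(seg$start), 0)
  expect_equal(max(seg$end), 5e4)
})

test_that("segmentation is deterministic and errors on impossible genomes", {
  cfg <- sim_config(seed = 5, genome_length = 2e6)
  f1 <- tempfile(fileext = ".bed")
  f2 <- tempfile(fileext = ".bed")
  write_bed(simulate_segmentation(cfg), f1)
  write_bed(simulate_segmentation(cfg), f2)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  tiny <- sim_config(seed = 1, n_states = 9, genome_length = 1000)
  expect_error(simulate_segmentation(tiny), "state")
})

test_that("simulated genes are non-overlapping and share the overlap rule", {
  cfg <- sim_config(seed = 3, n_genes = 300, genome_length = 3e6)
  seg <- simulate_segmentation(cfg)
  ga <- simulate_genes(cfg, seg)
  g <- ga$genes
  expect_equal(nrow(g), 300)
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))  # sorted, no overlap
  # same >= 150 bp rule as assign_states: identical result by construction
  expect_equal(as.data.frame(ga$gene_states),
               as.data.frame(assign_states(g, seg)))
  # genes longer than typical segments span several states
  expect_gt(max(table(ga$gene_states$gene_id)), 1)
})

test_that("a gene straddling two segments records both states (base counting)", {
  seg <- tibble::tibble(chrom = "chr1", start = c(0, 1000), end = c(1000, 2000),
                        state = c("1", "2"))
  genes <- tibble::tibble(gene_id = "gA", chrom = "chr1",
                          start = 800, end = 1200)  # 200 bp in each
  got <- assign_states(genes, seg)
  expect_equal(got$state, c("1", "2"))
  expect_equal(got$overlap_bp, c(200, 200))
  expect_equal(as.data.frame(got), as.data.frame(assign_states_oracle(genes, seg)),
               ignore_attr = TRUE)
})

test_that("null simulation has no fold change; planted effects are monotone in dose", {
  cfg0 <- sim_config(seed = 21, n_genes = 400, genome_length = 4e6,
                     frac_de = 0, n_reps = 10, lib_size_cv = 0,
                     baseline_mean = 500, baseline_sdlog = 0,
                     treatments = tibble::tibble(name = c("mock", "trt"),
                                                 density = c(0, 1e8)))
  sc0 <- simulate_counts(cfg0)
  m <- counts_matrix_for_test(sc0$counts)
  mock <- rowMeans(m[, sc0$samples$treatment == "mock"])
  trt <- rowMeans(m[, sc0$samples$treatment == "trt"])
  expect_lt(median(abs(log2(trt / mock))), 0.2)

  # beta = 2-scale effects grow with density (checked on means over reps)
  cfg1 <- sim_config(seed = 22, n_genes = 200, genome_length = 2e6,
                     frac_de = 0.25, beta_scale = 2, frac_down = 0,
                     n_reps = 50, lib_size_cv = 0, dispersion = 0.05)
  sc1 <- simulate_counts(cfg1)
  m1 <- counts_matrix_for_test(sc1$counts)
  de <- sc1$truth$de_genes
  mean_at <- function(tr) rowMeans(m1[de, sc1$samples$treatment == tr])
  lfc <- function(tr) log2(mean_at(tr) / mean_at("mock"))
  expect_gt(mean(lfc("d1e8") >= lfc("d1e5")), 0.95)
})

test_that("zero dispersion gives Poisson-like counts", {
  cfg <- sim_config(seed = 9, n_genes = 500, genome_length = 5e6,
                    dispersion = 0, frac_de = 0, lib_size_cv = 0,
                    baseline_mean = 100, baseline_sdlog = 0, n_reps = 10,
                    treatments = tibble::tibble(name = "mock", density = 0))
  sc <- simulate_counts(cfg)
  m <- counts_matrix_for_test(sc$counts)
  ratio <- apply(m, 1, var) / rowMeans(m)
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("simulated Cq values follow the efficiency model", {
  # exact inversion at zero noise
  expect_equal(relative_concentration(2, 10), 2^-10)
  cfg <- sim_config(seed = 2, cq_noise_sd = 0)
  qp <- simulate_qpcr(cfg, truth = NULL)
  back <- relative_concentration(qp$cq$efficiency, qp$cq$cq)
  # doubling concentration lowers Cq by exactly one cycle at E = 2
  expect_equal(-log(2 * back[1]) / log(2), -log(back[1]) / log(2) - 1)

  # noise realization matches the configured sd
  cfgN <- sim_config(seed = 4, cq_noise_sd = 0.2, n_reps = 100L,
                     treatments = tibble::tibble(name = c("mock", "t"),
                                                 density = c(0, 1e8)))
  qpN <- simulate_qpcr(cfgN, truth = NULL)
  ref1 <- qpN$cq[qpN$cq$gene_id == "REF1", ]
  expect_gte(sd(ref1$cq), 0.17)
  expect_lte(sd(ref1$cq), 0.23)
})

test_that("noise-free CFU simulation lies exactly on the colonization line", {
  cfg <- sim_config(seed = 6, cfu_noise_sd = 0)
  cf <- simulate_cfu(cfg)
  d <- cfu_per_gram(cf$cfu)
  pos <- !d$below_detection
  expect_equal(log10(d$raw_cfu_per_g[pos]),
               unname(log10(cf$true_cfu[pos])))
  # mock plants are recorded as zero colonies, never dropped
  expect_true(all(d$colony_count[d$treatment == "mock"] == 0))
  expect_equal(nrow(d), nrow(cfg$treatments) * cfg$n_cfu_reps)
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 13, n_genes = 100, genome_length = 1e6)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(simulate_cfu(cfg)$cfu, simulate_cfu(cfg)$cfu)
  expect_identical(simulate_qpcr(cfg, a$truth)$cq,
                   simulate_qpcr(cfg, b$truth)$cq)
  f1 <- tempfile(); f2 <- tempfile()
  write_gff3(simulate_genes(cfg, simulate_segmentation(cfg))$genes, f1)
  write_gff3(simulate_genes(cfg, simulate_segmentation(cfg))$genes, f2)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
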