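# Shared fixtures and independent oracles used across the suite.

# A small wide count tibble from a plain matrix.
make_counts <- function(m, genes = NULL) {
  genes <- genes %||% sprintf("g%03d", seq_len(nrow(m)))
  rownames(m) <- genes
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(gene_id = genes), tibble::as_tibble(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wide count tibble -> plain matrix.
counts_matrix_for_test <- function(counts) {
  m <- as.matrix(counts[, -1])
  rownames(m) <- counts$gene_id
  m
}

# Two-group sample sheet.
two_group_samples <- function(n_per = 3) {
  tibble::tibble(
    sample_id = c(sprintf("c%d", seq_len(n_per)), sprintf("t%d", seq_len(n_per))),
    treatment = rep(c("ctrl", "trt"), each = n_per),
    replicate = rep(seq_len(n_per), 2))
}

# NB count simulator used as a fixture independent of simulate_counts().
nb_two_group <- function(n_genes, n_per, baseline, beta, phi, seed) {
  withr::with_seed(seed, {
    mu_c <- rep(baseline, n_genes)
    mu_t <- baseline * 2^beta
    draw <- function(mu) {
      if (phi == 0) stats::rpois(n_genes * n_per, rep(mu, n_per))
      else stats::rnbinom(n_genes * n_per, size = 1 / phi, mu = rep(mu, n_per))
    }
    m <- cbind(matrix(draw(mu_c), n_genes, n_per),
               matrix(draw(mu_t), n_genes, n_per))
    colnames(m) <- c(sprintf("c%d", seq_len(n_per)), sprintf("t%d", seq_len(n_per)))
    make_counts(m)
  })
}

# Per-base chromatin-state labelling oracle: label every base of the genome,
# then count labelled bases per (gene, state) and threshold.
assign_states_oracle <- function(genes, seg, min_overlap = 150) {
  out <- list()
  for (ch in unique(genes$chrom)) {
    s <- seg[seg$chrom == ch, ]
    if (nrow(s) == 0) next
    glen <- max(genes$end[genes$chrom == ch], s$end)
    base <- rep(NA_character_, glen)
    for (i in seq_len(nrow(s))) {
      base[(s$start[i] + 1):s$end[i]] <- s$state[i]
    }
    g <- genes[genes$chrom == ch, ]
    for (i in seq_len(nrow(g))) {
      tab <- table(base[(g$start[i] + 1):g$end[i]])
      tab <- tab[tab >= min_overlap]
      if (length(tab) > 0) {
        out[[length(out) + 1]] <- tibble::tibble(
          gene_id = g$gene_id[i], state = names(tab),
          overlap_bp = as.integer(tab))
      }
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), gene_id, state)
}

# Random segmentation + genes pair for oracle comparisons.
random_annotation <- function(seed, genome = 2e5, n_genes = 200, n_states = 9) {
  withr::with_seed(seed, {
    lens <- pmax(50, round(stats::rexp(ceiling(genome / 400) * 2, 1 / 400)))
    lens <- lens[cumsum(lens) <= genome]
    lens <- c(lens, genome - sum(lens))
    lens <- lens[lens > 0]
    ends <- cumsum(lens)
    seg <- tibble::tibble(chrom = "chr1", start = c(0, ends[-length(ends)]),
                          end = ends,
                          state = as.character(sample.int(n_states,
                                                          length(ends),
                                                          replace = TRUE)))
    starts <- sort(sample.int(genome - 2000, n_genes))
    glen <- sample(200:1800, n_genes, replace = TRUE)
    genes <- tibble::tibble(gene_id = sprintf("g%04d", seq_len(n_genes)),
                            chrom = "chr1", start = starts,
                            end = pmin(starts + glen, genome))
    list(genes = genes, seg = seg)
  })
}

# Independent re-implementation of the doubly-trimmed weighted mean of
# M values (the TMM formula), used as the oracle for tmm_factors().
tmm_oracle <- function(m, logratio_trim = 0.3, abs_trim = 0.05) {
  lib <- colSums(m)
  cpm <- sweep(m, 2, lib, "/") * 1e6
  uq <- apply(cpm, 2, stats::quantile, p = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  one <- function(k) {
    ok <- m[, k] > 0 & m[, ref] > 0
    yk <- m[ok, k]; yr <- m[ok, ref]
    nk <- lib[k]; nr <- lib[ref]
    M <- log2((yk / nk) / (yr / nr))
    A <- 0.5 * log2((yk / nk) * (yr / nr))
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    w <- (nk - yk) / (nk * yk) + (nr - yr) / (nr * yr)
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }
  f <- vapply(seq_len(ncol(m)), one, numeric(1))
  f / exp(mean(log(f)))
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
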