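# Internal coordinates are 0-based half-open throughout; GRanges is 1-based
# closed, so conversion shifts start by +1 on the way in.
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Assign chromatin states to gene bodies by a minimum-overlap rule
#'
#' A gene is assigned a chromatin state when at least `min_overlap` bp
#' (default 150, roughly one nucleosome of wrapped DNA) of its gene body
#' overlaps intervals of that state. Overlaps with multiple segments of the
#' same state are summed before thresholding; a single gene may therefore
#' carry several states. Strand is ignored.
#'
#' @param genes Tibble (gene_id, chrom, start, end), 0-based half-open.
#' @param seg Segmentation tibble (chrom, start, end, state), 0-based
#'   half-open.
#' @param min_overlap Minimum total overlap in bp (default 150).
#' @return Tibble of class `state_assignment` (gene_id, state, overlap_bp),
#'   one row per assigned (gene, state); genes with no assignment simply
#'   have no rows. Attributes `gene_ids` (the full gene universe) and
#'   `states` (all segmentation states) are carried for downstream
#'   proportion calculations.
#' @export
assign_states <- function(genes, seg, min_overlap = 150) {
  assert_cols(genes, c("gene_id", "chrom", "start", "end"), "genes")
  assert_cols(seg, c("chrom", "start", "end", "state"), "seg")
  assert_that(!anyDuplicated(genes$gene_id), "gene IDs must be unique")
  assert_that(all(genes$end > genes$start) && all(seg$end > seg$start),
              "intervals must satisfy end > start")
  off_chrom <- setdiff(unique(genes$chrom), unique(seg$chrom))
  if (length(off_chrom) > 0) {
    warning(sprintf(
      "%d gene(s) on chromosome(s) absent from the segmentation (%s); they receive empty assignments",
      sum(genes$chrom %in% off_chrom), paste(off_chrom, collapse = ", ")))
  }
  gene_gr <- intervals_to_granges(genes)
  seg_gr <- intervals_to_granges(seg)
  hits <- GenomicRanges::findOverlaps(gene_gr, seg_gr, ignore.strand = TRUE)
  ov <- GenomicRanges::pintersect(gene_gr[S4Vectors::queryHits(hits)],
                                  seg_gr[S4Vectors::subjectHits(hits)])
  tab <- tibble(gene_id = genes$gene_id[S4Vectors::queryHits(hits)],
                state = seg$state[S4Vectors::subjectHits(hits)],
                w = IRanges::width(ov)) |>
    dplyr::group_by(.data$gene_id, .data$state) |>
    dplyr::summarise(overlap_bp = sum(.data$w), .groups = "drop") |>
    dplyr::filter(.data$overlap_bp >= min_overlap) |>
    dplyr::arrange(.data$gene_id, .data$state)
  structure(tab, class = c("state_assignment", class(tab)),
            gene_ids = genes$gene_id,
            states = sort(unique(as.character(seg$state))),
            min_overlap = min_overlap)
}

#' Per-state proportions of a gene set
#'
#' For each chromatin state, the number and fraction of genes in the set
#' assigned that state. Because genes may carry several states the
#' proportions need not sum to 1 across states; genes with no assignment
#' still count in the denominator.
#'
#' @param assign A [assign_states()] result.
#' @param gene_set Gene IDs (default: every annotated gene, i.e. the genome
#'   background). IDs outside the annotation are dropped with a warning.
#' @return Tibble (state, x, n, p), one row per segmentation state.
#' @export
state_proportions <- function(assign, gene_set = NULL) {
  universe <- attr(assign, "gene_ids")
  states <- attr(assign, "states")
  assert_that(!is.null(universe) && !is.null(states),
              "`assign` must come from assign_states()")
  gene_set <- gene_set %||% universe
  unknown <- setdiff(gene_set, universe)
  if (length(unknown) > 0) {
    warning(sprintf("%d gene(s) not in the annotation were ignored",
                    length(unknown)))
    gene_set <- intersect(gene_set, universe)
  }
  assert_that(length(gene_set) > 0, "gene set is empty")
  n <- length(unique(gene_set))
  counts <- assign |>
    dplyr::filter(.data$gene_id %in% gene_set) |>
    dplyr::count(.data$state, name = "x")
  tibble(state = states) |>
    dplyr::left_join(counts, by = "state") |>
    dplyr::mutate(x = dplyr::coalesce(.data$x, 0L), n = n, p = .data$x / n)
}

#' Marascuilo simultaneous comparison of proportions
#'
#' For k groups with successes x out of n, every pair (i, j) is compared
#' through the critical range
#' `r_ij = sqrt(chisq(1 - alpha, k - 1)) * sqrt(p_i(1-p_i)/n_i + p_j(1-p_j)/n_j)`;
#' a difference is significant when |p_i - p_j| exceeds its critical
#' range. Simultaneity over all pairs is inherited from the chi-squared
#' quantile with k - 1 degrees of freedom.
#'
#' @param x Successes per group.
#' @param n Trials per group.
#' @param alpha Significance level (default 0.05, i.e. 0.95 confidence).
#' @param labels Optional group labels.
#' @return Tibble (group1, group2, p1, p2, abs_diff, crit_range,
#'   significant).
#' @export
marascuilo <- function(x, n, alpha = 0.05, labels = NULL) {
  k <- length(x)
  assert_that(k >= 2 && length(n) == k, "need k >= 2 groups with matching n")
  assert_that(all(n >= 1), "each group needs n >= 1")
  assert_that(all(x >= 0 & x <= n), "x must satisfy 0 <= x <= n")
  labels <- labels %||% as.character(seq_len(k))
  p <- x / n
  crit <- sqrt(stats::qchisq(1 - alpha, df = k - 1))
  pairs <- which(upper.tri(diag(k)), arr.ind = TRUE)
  i <- pairs[, 1]
  j <- pairs[, 2]
  r <- crit * sqrt(p[i] * (1 - p[i]) / n[i] + p[j] * (1 - p[j]) / n[j])
  tibble(group1 = labels[i], group2 = labels[j], p1 = p[i], p2 = p[j],
         abs_diff = abs(p[i] - p[j]), crit_range = r,
         significant = abs(p[i] - p[j]) > r)
}

#' Chromatin-state enrichment of a gene set against the genome
#'
#' Compares, per chromatin state, the proportion of set genes carrying the
#' state with the proportion among all annotated genes, flagging
#' enrichment or depletion by the Marascuilo procedure. Two family modes:
#' `"per-state-pair"` (default) treats each state as its own two-group
#' comparison (chi-squared with 1 df, i.e. an unpooled z-test at level
#' alpha); `"joint"` treats all 2 x n_states proportions as one family
#' (chi-squared with 2 x n_states - 1 df), giving wider, simultaneous
#' critical ranges.
#'
#' @param assign A [assign_states()] result.
#' @param gene_set Gene IDs of interest (nonempty).
#' @param background Background gene IDs (default: all annotated genes).
#' @param alpha Significance level (default 0.05).
#' @param mode Family mode, `"per-state-pair"` or `"joint"`.
#' @return Tibble of class `enrichment_table` (state, x_set, n_set, p_set,
#'   x_genome, n_genome, p_genome, abs_diff, crit_range, significant,
#'   direction in enriched/depleted/none).
#' @export
enrichment_analysis <- function(assign, gene_set, background = NULL,
                                alpha = 0.05,
                                mode = c("per-state-pair", "joint")) {
  mode <- match.arg(mode)
  assert_that(length(gene_set) > 0, "gene_set must be nonempty")
  ps <- state_proportions(assign, gene_set)
  pg <- state_proportions(assign, background)
  df <- if (mode == "per-state-pair") 1 else 2 * nrow(ps) - 1
  crit <- sqrt(stats::qchisq(1 - alpha, df = df))
  out <- tibble(
    state = ps$state,
    x_set = ps$x, n_set = ps$n, p_set = ps$p,
    x_genome = pg$x, n_genome = pg$n, p_genome = pg$p) |>
    dplyr::mutate(
      abs_diff = abs(.data$p_set - .data$p_genome),
      crit_range = crit * sqrt(.data$p_set * (1 - .data$p_set) / .data$n_set +
                                 .data$p_genome * (1 - .data$p_genome) /
                                   .data$n_genome),
      significant = .data$abs_diff > .data$crit_range,
      direction = dplyr::case_when(
        .data$significant & .data$p_set > .data$p_genome ~ "enriched",
        .data$significant & .data$p_set < .data$p_genome ~ "depleted",
        TRUE ~ "none"))
  structure(out, class = c("enrichment_table", class(out)),
            alpha = alpha, mode = mode)
}
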