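#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its conventional
#' default: expression filter above 0.5 cpm in at least 3 samples, fold
#' change threshold log2(1.3) (or `"auto"` for elbow selection), 5% FDR,
#' prior count 2, 150 bp state-overlap rule, alpha 0.05, density
#' pseudo-count 10^2 CFU g^-1.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param cpm_min,n_min Expression filter.
#' @param tau Fold-change threshold in log2 units, or `"auto"`.
#' @param tau_grid Threshold grid for elbow selection.
#' @param fdr FDR cutoff.
#' @param prior Prior count for moderated log2 cpm.
#' @param k_grid,n_init K-means grid and restarts.
#' @param min_overlap Chromatin-state overlap rule, bp.
#' @param alpha Significance level (qPCR, Marascuilo).
#' @param marascuilo_mode `"per-state-pair"` or `"joint"`.
#' @param pseudo CFU pseudo-count, CFU g^-1.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, cpm_min = 0.5, n_min = 3,
                            tau = log2(1.3),
                            tau_grid = seq(0.1, 1.5, by = 0.02),
                            fdr = 0.05, prior = 2,
                            k_grid = 1:15, n_init = 10,
                            min_overlap = 150, alpha = 0.05,
                            marascuilo_mode = c("per-state-pair", "joint"),
                            pseudo = 100) {
  structure(list(seed = as.integer(seed), cpm_min = cpm_min, n_min = n_min,
                 tau = tau, tau_grid = tau_grid, fdr = fdr, prior = prior,
                 k_grid = k_grid, n_init = n_init,
                 min_overlap = min_overlap, alpha = alpha,
                 marascuilo_mode = match.arg(marascuilo_mode),
                 pseudo = pseudo),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates a synthetic experiment (counts, qPCR, CFU, segmentation) and
#' chains every stage: density quantification and dose regression, qPCR
#' relative quantification, expression filtering, TMM, per-density
#' TREAT-style tests (with elbow-selected threshold when `tau = "auto"`),
#' DEG set algebra (union, sign consistency, UpSet signatures,
#' nestedness), k-means profile clustering, the specific/shared partition
#' of the top-density DEG set, and chromatin-state enrichment of both
#' partitions. Deterministic given the seeds; optionally writes all result
#' tables plus a provenance record.
#'
#' @param config A [pipeline_config()].
#' @param sim A [sim_config()] (default derives its seed from the pipeline
#'   seed).
#' @param out_dir Optional directory for TSV/JSON/BED/GFF3 outputs.
#' @return List of class `pipeline_result` with elements `sim`, `density`,
#'   `qpcr`, `deg` (per-treatment `deg_result`s), `tau_used`, `elbow`,
#'   `sets`, `upset`, `conflicts`, `nestedness`, `clusters`, `partition`,
#'   `enrichment_specific`, `enrichment_shared`, `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         sim = sim_config(seed = config$seed),
                         out_dir = NULL) {
  sc <- simulate_counts(sim)
  cfu <- simulate_cfu(sim)
  qp <- simulate_qpcr(sim, sc$truth)

  density <- cfu_per_gram(cfu$cfu, pseudo = config$pseudo)
  dens_pos <- density |> dplyr::filter(!.data$below_detection)
  inoc <- sim$treatments$density[match(dens_pos$treatment,
                                       sim$treatments$name)]
  dens_fit <- density_regression(
    dplyr::mutate(dens_pos, log10_cfu = log10(.data$cfu_per_g),
                  inoculum = inoc),
    "log10_cfu", "inoculum", log10_density = TRUE)

  qpcr_res <- qpcr_pipeline(qp$cq, qp$reference_genes, mock = qp$mock,
                            alpha = config$alpha)

  filtered <- filter_genes(sc$counts, cpm_min = config$cpm_min,
                           n_min = config$n_min)
  nf <- tmm_factors(filtered)
  trt <- setdiff(unique(sc$samples$treatment), "mock")
  elbow <- NULL
  tau_used <- config$tau
  if (identical(config$tau, "auto")) {
    curves <- deg_count_curve(filtered, sc$samples, treatments = trt,
                              control = "mock", tau_grid = config$tau_grid,
                              fdr = config$fdr, norm_factors = nf)
    elbow <- elbow_threshold(curves)
    tau_used <- elbow$threshold
  }
  deg <- lapply(trt, function(tr) {
    treat_test(filtered, sc$samples, tr, "mock", tau = tau_used,
               fdr = config$fdr, norm_factors = nf)
  })
  names(deg) <- trt

  sets <- deg_sets(deg)
  conflicts <- sign_consistency(sets)
  nest <- nestedness(sets, order = trt)
  ups <- if (nrow(conflicts) == 0) upset_counts(sets) else NULL

  union_genes <- deg_union(sets)
  clusters <- NULL
  if (length(union_genes) >= max(config$k_grid)) {
    logcpm <- moderated_log2cpm(filtered, norm_factors = nf,
                                prior = config$prior)
    profiles <- center_profiles(logcpm,
                                intersect(union_genes, logcpm$gene_id))
    clusters <- kmeans_elbow(profiles, k_grid = config$k_grid,
                             n_init = config$n_init,
                             seed = stage_seed(config$seed, "kmeans"))
  }

  top <- trt[which.max(sim$treatments$density[match(trt,
                                                    sim$treatments$name)])]
  part <- partition_specific(sets, focal = top, direction = "up")
  assign <- sc$truth$gene_states
  enr <- function(ids) {
    if (length(ids) == 0) return(NULL)
    enrichment_analysis(assign, ids, alpha = config$alpha,
                        mode = config$marascuilo_mode)
  }
  enrichment_specific <- enr(part$gene_id[part$status == "specific"])
  enrichment_shared <- enr(part$gene_id[part$status == "shared"])

  provenance <- list(
    package_version = as.character(utils::packageVersion("phyllodeg")),
    seed = config$seed, sim_seed = sim$seed,
    parameters = config[setdiff(names(config), "tau_grid")],
    tau_used = tau_used,
    n_genes_simulated = nrow(sc$counts),
    n_genes_filtered = nrow(filtered),
    n_deg = lapply(deg, function(d) sum(d$call != "ns")),
    n_union = length(union_genes),
    n_conflicts = nrow(conflicts),
    k_chosen = if (!is.null(clusters)) clusters$k else NA)

  res <- structure(list(
    sim = sc, cfu = cfu, density = density, density_fit = dens_fit,
    qpcr = qpcr_res, filtered = filtered, norm_factors = nf,
    deg = deg, tau_used = tau_used, elbow = elbow, sets = sets,
    upset = ups, conflicts = conflicts, nestedness = nest,
    clusters = clusters, partition = part,
    enrichment_specific = enrichment_specific,
    enrichment_shared = enrichment_shared,
    provenance = provenance), class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# Write every result table with fixed formatting so identical runs are
# byte-identical.
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_counts(res$sim$counts, p("counts.tsv"))
  readr::write_tsv(res$sim$samples, p("samples.tsv"))
  write_bed(res$sim$truth$segmentation, p("segmentation.bed"))
  write_gff3(res$sim$truth$genes, p("genes.gff3"))
  readr::write_tsv(res$cfu$cfu, p("cfu.tsv"))
  readr::write_tsv(res$density, p("density_estimates.tsv"))
  readr::write_tsv(res$qpcr$expression, p("qpcr_expression.tsv"))
  readr::write_tsv(res$qpcr$significance, p("qpcr_significance.tsv"))
  for (tr in names(res$deg)) {
    readr::write_tsv(res$deg[[tr]], p(sprintf("deg_%s.tsv", tr)))
  }
  readr::write_tsv(res$nestedness, p("nestedness.tsv"))
  if (!is.null(res$upset)) readr::write_tsv(res$upset, p("upset.tsv"))
  if (!is.null(res$clusters)) {
    readr::write_tsv(res$clusters$clusters, p("clusters.tsv"))
  }
  readr::write_tsv(res$partition, p("partition.tsv"))
  if (!is.null(res$enrichment_specific)) {
    readr::write_tsv(res$enrichment_specific, p("enrichment_specific.tsv"))
  }
  if (!is.null(res$enrichment_shared)) {
    readr::write_tsv(res$enrichment_shared, p("enrichment_shared.tsv"))
  }
  g <- glance(res$density_fit)
  write_json_file(as.list(g), p("density_fit.json"))
  write_json_file(res$provenance, p("provenance.json"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("phyllodeg pipeline result\n")
  cat(sprintf("  genes simulated/filtered: %d / %d\n",
              x$provenance$n_genes_simulated, x$provenance$n_genes_filtered))
  cat(sprintf("  tau used: %.4f; DEGs per treatment: %s; union: %d\n",
              x$tau_used,
              paste(sprintf("%s=%d", names(x$deg),
                            unlist(x$provenance$n_deg)), collapse = ", "),
              x$provenance$n_union))
  cat(sprintf("  sign conflicts: %d; k-means k: %s\n",
              x$provenance$n_conflicts, x$provenance$k_chosen))
  invisible(x)
}
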