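#' Build DEG sets from per-treatment test results
#'
#' Collects the up- and down-regulated gene sets of several treatments into
#' one tidy table, the input to the set-algebra operations.
#'
#' @param ... Named `deg_result` objects (names become set labels), or a
#'   single named list of them.
#' @return Tibble of class `deg_sets` (set, gene_id, direction).
#' @export
deg_sets <- function(...) {
  dots <- list(...)
  if (length(dots) == 1 && is.list(dots[[1]]) &&
      !inherits(dots[[1]], "data.frame")) {
    dots <- dots[[1]]
  }
  assert_that(!is.null(names(dots)) && all(names(dots) != ""),
              "every DEG result must be named")
  out <- purrr::imap_dfr(dots, function(deg, nm) {
    assert_cols(deg, c("gene_id", "call"), nm)
    deg |>
      dplyr::filter(.data$call != "ns") |>
      dplyr::transmute(set = nm, gene_id = .data$gene_id,
                       direction = .data$call)
  })
  structure(out, class = c("deg_sets", class(out)))
}

#' Union of all DEG sets
#'
#' @param sets A [deg_sets()] table.
#' @return Character vector of gene IDs differentially expressed in any set.
#' @export
deg_union <- function(sets) unique(sets$gene_id)

#' Center expression profiles per gene
#'
#' Restricts a moderated log2 cpm table to a gene set and subtracts each
#' gene's mean across samples, so profiles describe relative movement only.
#' Idempotent.
#'
#' @param logcpm Wide tibble from [moderated_log2cpm()].
#' @param genes Gene IDs to keep (default: all).
#' @return Wide tibble of centered profiles (row means 0).
#' @export
center_profiles <- function(logcpm, genes = NULL) {
  m <- counts_matrix(logcpm)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    assert_that(length(missing) == 0,
                paste("genes absent from the expression table:",
                      paste(utils::head(missing, 5), collapse = ", ")))
    m <- m[rownames(m) %in% genes, , drop = FALSE]
  }
  matrix_to_counts(m - rowMeans(m))
}

# k-means++ initial centers (Arthur & Vassilvitskii seeding).
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  first <- sample.int(n, 1)
  centers[1, ] <- x[first, ]
  if (k > 1) {
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      pick <- if (sum(d2) == 0) sample.int(n, 1) else
        sample.int(n, 1, prob = d2)
      centers[j, ] <- x[pick, ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  centers
}

run_kmeans_once <- function(x, k) {
  if (k == 1) {
    mu <- colMeans(x)
    return(list(cluster = rep(1L, nrow(x)),
                tot.withinss = sum(sweep(x, 2, mu)^2), centers = rbind(mu)))
  }
  for (try in 1:20) {
    init <- kmeanspp_centers(x, k)
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = init,
                                     algorithm = "Lloyd", iter.max = 100)),
      error = function(e) NULL)
    # an empty cluster aborts Lloyd's algorithm; redraw the seeding
    if (!is.null(fit) && all(fit$size > 0)) return(fit)
  }
  stop("k-means failed to find a non-degenerate clustering", call. = FALSE)
}

#' K-means clustering of expression profiles with elbow-selected k
#'
#' Lloyd's algorithm with k-means++ seeding, best of `n_init` restarts per
#' k (by total within-cluster sum of squares), over a grid of k. The number
#' of clusters is chosen at the elbow (maximum discrete second difference)
#' of the within-SS curve, the same rule used for the fold-change
#' threshold. Deterministic given `seed`.
#'
#' @param profiles Wide tibble of centered profiles (from
#'   [center_profiles()]).
#' @param k_grid Candidate numbers of clusters (default 1:15).
#' @param n_init Restarts per k (default 10).
#' @param seed Integer RNG seed.
#' @return List of class `kmeans_profile`: `k`, `clusters` (tibble:
#'   gene_id, cluster), `sizes`, `tot_withinss`, `tss_curve` (tibble: k,
#'   tot_withinss), `seed`.
#' @export
kmeans_elbow <- function(profiles, k_grid = 1:15, n_init = 10, seed = 1L) {
  x <- counts_matrix(profiles)
  assert_that(nrow(x) >= max(k_grid),
              "fewer genes than the largest candidate k")
  withr::with_seed(as.integer(seed), {
    fits <- purrr::map(k_grid, function(k) {
      best <- NULL
      for (r in seq_len(n_init)) {
        fit <- run_kmeans_once(x, k)
        if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
      }
      best
    })
    tss <- vapply(fits, function(f) f$tot.withinss, numeric(1))
    k_best <- find_elbow(as.numeric(k_grid), tss)$elbow
    fit <- fits[[match(k_best, k_grid)]]
    structure(list(
      k = as.integer(k_best),
      clusters = tibble(gene_id = rownames(x),
                        cluster = as.integer(fit$cluster)),
      sizes = as.integer(fit$size %||% nrow(x)),
      tot_withinss = fit$tot.withinss,
      tss_curve = tibble(k = as.integer(k_grid), tot_withinss = tss),
      seed = as.integer(seed)), class = "kmeans_profile")
  })
}

#' @export
print.kmeans_profile <- function(x, ...) {
  cat(sprintf("k-means profile clustering: k = %d (elbow), %d genes\n",
              x$k, nrow(x$clusters)))
  cat("cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @method glance kmeans_profile
#' @export
glance.kmeans_profile <- function(x, ...) {
  tibble(k = x$k, n_genes = nrow(x$clusters),
         tot_withinss = x$tot_withinss, seed = x$seed)
}

#' UpSet-style membership signature counts
#'
#' Partitions the union of the DEG sets by exact membership signature
#' (which sets a gene belongs to) and counts genes, split by direction.
#' Signature counts sum exactly to the union size. Direction conflicts
#' between sets abort (run [sign_consistency()] first).
#'
#' @param sets A [deg_sets()] table.
#' @return Tibble (signature, degree, n, n_up, n_down), sorted by
#'   decreasing n.
#' @export
upset_counts <- function(sets) {
  conf <- sign_consistency(sets)
  assert_that(nrow(conf) == 0,
              paste("direction conflicts between sets for gene(s):",
                    paste(utils::head(conf$gene_id, 5), collapse = ", ")))
  per_gene <- sets |>
    dplyr::distinct(.data$set, .data$gene_id, .data$direction) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      signature = paste(sort(unique(.data$set)), collapse = "&"),
      degree = dplyr::n_distinct(.data$set),
      direction = .data$direction[1], .groups = "drop")
  per_gene |>
    dplyr::group_by(.data$signature, .data$degree) |>
    dplyr::summarise(n = dplyr::n(),
                     n_up = sum(.data$direction == "up"),
                     n_down = sum(.data$direction == "down"),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n))
}

#' Genes with conflicting direction calls between sets
#'
#' Returns every gene significantly up-regulated in one set and
#' down-regulated in another; an empty result means the responses are
#' sign-consistent across treatments.
#'
#' @param sets A [deg_sets()] table.
#' @return Tibble (gene_id, up_in, down_in); zero rows when consistent.
#' @export
sign_consistency <- function(sets) {
  sets |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      up_in = paste(sort(unique(.data$set[.data$direction == "up"])),
                    collapse = ","),
      down_in = paste(sort(unique(.data$set[.data$direction == "down"])),
                      collapse = ","),
      .groups = "drop") |>
    dplyr::filter(.data$up_in != "" & .data$down_in != "")
}

#' Partition a focal DEG set into specific and shared genes
#'
#' Splits the focal treatment's DEGs by whether they are also
#' differentially expressed in any of the other treatments (shared) or in
#' none of them (specific), optionally restricted to one direction.
#'
#' @param sets A [deg_sets()] table.
#' @param focal Focal set label.
#' @param others Other set labels (default: all non-focal sets).
#' @param direction Optional "up" or "down" restriction (applies to the
#'   focal calls).
#' @return Tibble (gene_id, status in specific/shared).
#' @export
partition_specific <- function(sets, focal, others = NULL, direction = NULL) {
  assert_that(focal %in% sets$set, sprintf("unknown focal set '%s'", focal))
  others <- others %||% setdiff(unique(sets$set), focal)
  focal_tbl <- sets |> dplyr::filter(.data$set == focal)
  if (!is.null(direction)) {
    focal_tbl <- focal_tbl |> dplyr::filter(.data$direction == !!direction)
  }
  other_genes <- unique(sets$gene_id[sets$set %in% others])
  focal_tbl |>
    dplyr::distinct(.data$gene_id) |>
    dplyr::mutate(status = ifelse(.data$gene_id %in% other_genes,
                                  "shared", "specific"))
}

#' Pairwise containment of dose-ordered DEG sets
#'
#' For every ordered pair (weaker, stronger) of sets, the fraction of the
#' weaker set's genes also present in the stronger set. Full containment
#' (1.0 everywhere above the diagonal) is the signature of a nested,
#' graded dose response.
#'
#' @param sets A [deg_sets()] table.
#' @param order Set labels from weakest to strongest (default: order of
#'   appearance).
#' @return Tibble (weaker, stronger, n_weaker, n_overlap, containment).
#' @export
nestedness <- function(sets, order = NULL) {
  order <- order %||% unique(sets$set)
  assert_that(all(order %in% sets$set), "unknown set label in `order`")
  ids <- lapply(order, function(s) unique(sets$gene_id[sets$set == s]))
  names(ids) <- order
  pairs <- which(upper.tri(matrix(0, length(order), length(order))),
                 arr.ind = TRUE)
  purrr::map_dfr(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]
    j <- pairs[r, 2]
    nw <- length(ids[[i]])
    ov <- length(intersect(ids[[i]], ids[[j]]))
    tibble(weaker = order[i], stronger = order[j], n_weaker = nw,
           n_overlap = ov,
           containment = if (nw == 0) NA_real_ else ov / nw)
  })
}
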