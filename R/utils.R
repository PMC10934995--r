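#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Derive a reproducible per-stage seed from the master seed so that each
# pipeline stage has its own RNG stream. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 131) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  assert_that(length(missing) == 0,
              sprintf("%s is missing required column(s): %s",
                      what, paste(missing, collapse = ", ")))
  invisible(df)
}

# counts helpers ------------------------------------------------------------

counts_matrix <- function(counts) {
  assert_cols(counts, "gene_id", "counts")
  m <- as.matrix(counts[, setdiff(names(counts), "gene_id"), drop = FALSE])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}

matrix_to_counts <- function(m) {
  dplyr::bind_cols(tibble(gene_id = rownames(m)), as_tibble(m))
}

library_sizes <- function(counts) {
  m <- counts_matrix(counts)
  colSums(m)
}
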