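#' Read a gene count matrix from TSV
#'
#' Expects a header row with `gene_id` followed by one column per sample;
#' counts must be non-negative integers.
#'
#' @param path TSV file path.
#' @return Wide count tibble.
#' @export
read_counts <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(df, "gene_id", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid count at row %d, column '%s' of %s",
                 bad[1, 1], colnames(m)[bad[1, 2]], path), call. = FALSE)
  }
  df
}

#' Write a count matrix (or any wide gene table) to TSV
#' @param counts Wide tibble with gene_id first.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read a sample sheet from TSV
#'
#' @param path TSV with columns sample_id, treatment and optionally
#'   density, replicate.
#' @return Tibble.
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(df, c("sample_id", "treatment"), path)
  df
}

#' Read a BED file of labelled intervals
#'
#' BED is 0-based half-open, which is also the package's internal
#' convention, so coordinates pass through unchanged. The fourth column is
#' the interval label.
#'
#' @param path BED file path (no header).
#' @param label Name for the label column (default "state").
#' @return Tibble (chrom, start, end, <label>).
#' @export
read_bed <- function(path, label = "state") {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", label),
                        col_types = readr::cols(
                          chrom = "c", start = "d", end = "d",
                          .default = "c"),
                        show_col_types = FALSE)
  bad <- which(df$end <= df$start)
  assert_that(length(bad) == 0,
              sprintf("malformed interval (end <= start) at line %d of %s",
                      bad[1], path))
  df
}

#' Write labelled intervals as BED
#' @param df Tibble (chrom, start, end, label...), 0-based half-open.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read gene coordinates from GFF3
#'
#' Imports `gene` features via rtracklayer and converts them to the
#' internal 0-based half-open convention (GFF3 is 1-based closed, so the
#' start shifts by -1 and lengths are preserved).
#'
#' @param path GFF3 file path.
#' @param feature Feature type to keep (default "gene").
#' @return Tibble (gene_id, chrom, start, end, strand).
#' @export
read_gff3 <- function(path, feature = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature]
  assert_that(length(gr) > 0,
              sprintf("no '%s' features in %s", feature, path))
  ids <- gr$ID %||% gr$Name
  assert_that(!is.null(ids) && !anyNA(ids),
              sprintf("'%s' features in %s need ID attributes", feature, path))
  tibble(gene_id = as.character(ids),
         chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1,
         end = as.numeric(GenomicRanges::end(gr)),
         strand = as.character(GenomicRanges::strand(gr)))
}

#' Write gene coordinates as GFF3
#' @param genes Tibble (gene_id, chrom, start, end, strand), 0-based
#'   half-open.
#' @param path Output path.
#' @param feature Feature type (default "gene").
#' @export
write_gff3 <- function(genes, path, feature = "gene") {
  strand <- if ("strand" %in% names(genes)) genes$strand else "+"
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end),
    strand = strand)
  gr$type <- feature
  gr$ID <- genes$gene_id
  gr$source <- "phyllodeg"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a qPCR Cq table from TSV
#' @param path TSV with columns sample_id, treatment, timepoint_h,
#'   replicate, gene_id, cq, efficiency.
#' @return Tibble.
#' @export
read_qpcr <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(df, c("sample_id", "treatment", "timepoint_h", "replicate",
                    "gene_id", "cq", "efficiency"), path)
  assert_that(all(df$cq > 0), sprintf("non-positive Cq in %s", path))
  assert_that(all(df$efficiency > 1 & df$efficiency <= 2),
              sprintf("primer efficiency outside (1, 2] in %s", path))
  df
}

#' Read a CFU plate-count table from TSV
#' @param path TSV with columns sample_id, treatment, colony_count,
#'   dilution_factor, plated_fraction, resuspension_volume, plant_weight.
#' @return Tibble.
#' @export
read_cfu <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(df, c("sample_id", "treatment", "colony_count",
                    "dilution_factor", "plated_fraction", "plant_weight"),
              path)
  df
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
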