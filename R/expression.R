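#' Significance thresholds for differential expression classes
#'
#' Defaults follow the common DESeq2-style filtering used for knockdown
#' RNA-seq contrasts: a gene is called up/down only when it is reasonably
#' expressed (basemean > 100), changes at least two-fold (|log2FC| > 1) and is
#' significant after BH adjustment (padj < 0.05). "Unaltered" genes are the
#' clearly static complement (padj > 0.05 and |log2FC| < 0.5); everything else
#' is "other".
#'
#' @param basemean_min minimum mean normalized count for up/down calls.
#' @param lfc_min minimum |log2FC| for up/down calls.
#' @param padj_max maximum adjusted p for up/down calls.
#' @param unaltered_padj_min minimum adjusted p for an unaltered call.
#' @param unaltered_lfc_max maximum |log2FC| for an unaltered call.
#' @return a list of thresholds.
#' @export
expression_thresholds <- function(basemean_min = 100, lfc_min = 1, padj_max = 0.05,
                                  unaltered_padj_min = 0.05, unaltered_lfc_max = 0.5) {
  list(basemean_min = basemean_min, lfc_min = lfc_min, padj_max = padj_max,
       unaltered_padj_min = unaltered_padj_min, unaltered_lfc_max = unaltered_lfc_max)
}

#' Assign expression classes from basemean / log2FC / padj
#'
#' The rules are mutually exclusive by construction: up and down require
#' padj < padj_max while unaltered requires padj > unaltered_padj_min, and the
#' defaults keep those bands disjoint. Every gene receives exactly one class.
#'
#' @param basemean,log2FC,padj numeric vectors of equal length.
#' @param thresholds see [expression_thresholds()].
#' @return character vector in {"up", "down", "unaltered", "other"}.
#' @export
classify_expression <- function(basemean, log2FC, padj, thresholds = expression_thresholds()) {
  n <- length(basemean)
  stopifnot(length(log2FC) == n, length(padj) == n)
  assert_that(!anyNA(padj), "missing adjusted p-values are not accepted")
  assert_that(all(padj >= 0 & padj <= 1), "padj outside [0, 1]")
  assert_that(all(basemean >= 0), "basemean must be >= 0")
  th <- thresholds
  cls <- rep("other", n)
  sig <- basemean > th$basemean_min & padj < th$padj_max
  cls[sig & log2FC > th$lfc_min] <- "up"
  cls[sig & log2FC < -th$lfc_min] <- "down"
  cls[cls == "other" & padj > th$unaltered_padj_min &
        abs(log2FC) < th$unaltered_lfc_max] <- "unaltered"
  cls
}

#' Read a differential expression table and assign classes
#'
#' Expects a tab-separated file with header columns
#' `gene_id, chrom, tss, strand, basemean, log2FC, padj` (TSS in 0-based
#' coordinates; for a minus-strand gene the TSS is interval end - 1).
#' Rows with missing padj are rejected rather than silently imputed.
#'
#' @param path TSV path.
#' @param thresholds see [expression_thresholds()].
#' @return data.frame of class `expression_table` with a `class` column.
#' @export
load_expression_table <- function(path, thresholds = expression_thresholds()) {
  assert_that(file.exists(path), paste("file not found:", path))
  df <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  req <- c("gene_id", "chrom", "tss", "strand", "basemean", "log2FC", "padj")
  missing_cols <- setdiff(req, names(df))
  assert_that(length(missing_cols) == 0,
              paste("expression table missing columns:", paste(missing_cols, collapse = ", ")))
  expression_table(df, thresholds)
}

#' Construct a validated expression table
#'
#' @param df data.frame with gene_id, chrom, tss, strand, basemean, log2FC, padj.
#' @param thresholds see [expression_thresholds()].
#' @return data.frame of class `expression_table`.
#' @export
expression_table <- function(df, thresholds = expression_thresholds()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$class <- classify_expression(df$basemean, df$log2FC, df$padj, thresholds)
  class(df) <- c("expression_table", "data.frame")
  df
}

#' Write an expression table as TSV
#' @param expr an `expression_table` (or compatible data.frame).
#' @param path output path.
#' @export
write_expression_table <- function(expr, path) {
  data.table::fwrite(as.data.frame(expr), path, sep = "\t", quote = FALSE)
  invisible(path)
}
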