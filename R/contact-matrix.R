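#' Binned Hi-C contact matrices
#'
#' A contact matrix holds symmetric cis contact counts for one chromosome at a
#' fixed resolution, together with a per-bin validity mask. Masked bins
#' (unmappable or zero-coverage) are excluded from every downstream statistic.
#'
#' @param counts square numeric matrix of contact counts (symmetric, >= 0).
#' @param chrom chromosome name.
#' @param resolution bin size in bp.
#' @param mask logical vector, TRUE for valid bins (default: all valid).
#' @return object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, chrom, resolution, mask = NULL) {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts))
  assert_that(all(counts >= 0, na.rm = TRUE), "contact counts must be >= 0")
  assert_that(isTRUE(all.equal(counts, t(counts), tolerance = 1e-8,
                               check.attributes = FALSE)),
              "contact matrix must be symmetric")
  n <- nrow(counts)
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(is.logical(mask), length(mask) == n)
  structure(list(chrom = as.character(chrom), resolution = as.numeric(resolution),
                 counts = counts, mask = mask),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins @ %g bp, %d masked, total %.4g counts\n",
              x$chrom, nrow(x$counts), x$resolution, sum(!x$mask), sum(x$counts)))
  invisible(x)
}

n_bins <- function(cm) nrow(cm$counts)

#' Read a contact matrix from sparse triplet text
#'
#' The file holds `bin_i TAB bin_j TAB count` rows (0-based bin indices);
#' missing entries are zero and the matrix is symmetrized, so each pair needs
#' to appear only once in either orientation.
#'
#' @param path triplet text file.
#' @param chrom chromosome name (keyed into `chrom_sizes`).
#' @param resolution bin size in bp.
#' @param chrom_sizes named vector of chromosome lengths in bp.
#' @return a `contact_matrix` with `ceiling(size / resolution)` bins.
#' @export
load_contact_matrix <- function(path, chrom, resolution, chrom_sizes) {
  assert_that(file.exists(path), paste("file not found:", path))
  assert_that(chrom %in% names(chrom_sizes), paste("unknown chromosome:", chrom))
  n <- as.integer(ceiling(chrom_sizes[[chrom]] / resolution))
  dt <- suppressWarnings(
    data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE))
  m <- matrix(0, n, n)
  if (nrow(dt) > 0) {
    assert_that(ncol(dt) >= 3, "triplet file needs 3 columns (bin_i, bin_j, count)")
    i <- as.integer(dt[[1]]); j <- as.integer(dt[[2]]); v <- as.numeric(dt[[3]])
    assert_that(all(v >= 0), "negative contact count")
    assert_that(all(i >= 0 & i < n & j >= 0 & j < n),
                "bin index outside chromosome extent")
    m[cbind(i + 1L, j + 1L)] <- v
    m[cbind(j + 1L, i + 1L)] <- v
  }
  contact_matrix(m, chrom, resolution)
}

#' Write a contact matrix as sparse triplet text
#'
#' Upper-triangle (including diagonal) nonzero entries, 0-based bin indices.
#'
#' @param cm a `contact_matrix`.
#' @param path output path.
#' @export
write_contact_matrix <- function(cm, path) {
  m <- cm$counts
  idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  out <- data.frame(bin_i = idx[, 1] - 1L, bin_j = idx[, 2] - 1L,
                    count = m[idx])
  out <- out[order(out$bin_i, out$bin_j), ]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
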