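#' Genomic feature sets
#'
#' A feature set is a validated data.frame of genomic intervals in 0-based
#' half-open coordinates (`start` inclusive, `end` exclusive), sorted by
#' (chrom, start), with optional `strand` and arbitrary per-feature score
#' columns. This is the container used for peaks, boundaries, gene models and
#' binned signal tracks throughout the package.
#'
#' @param df data.frame with at least `chrom`, `start`, `end` columns.
#' @return a data.frame of class `feature_set`, sorted by (chrom, start).
#' @export
feature_set <- function(df) {
  stopifnot(is.data.frame(df))
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(df))
  assert_that(length(missing_cols) == 0,
              paste("feature_set: missing columns:", paste(missing_cols, collapse = ", ")))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (nrow(df) > 0) {
    assert_that(all(nzchar(df$chrom)), "feature_set: empty chromosome name")
    assert_that(all(df$start >= 0), "feature_set: negative start coordinate")
    assert_that(all(df$start < df$end), "feature_set: start must be < end")
    if ("strand" %in% names(df))
      assert_that(all(df$strand %in% c("+", "-", ".")),
                  "feature_set: strand must be one of +, -, .")
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("feature_set", "data.frame")
  df
}

#' Read a BED or bedGraph file into a feature set
#'
#' BED columns beyond the first three are mapped to `name`, `score`, `strand`
#' per the BED standard; bedGraph's fourth column is stored as `score`.
#' Unsorted input is sorted, not rejected. Coordinates are kept as-is
#' (BED/bedGraph are already 0-based half-open).
#'
#' @param path file path.
#' @param format "bed", "bedgraph", or "auto" (by file extension).
#' @return a `feature_set`.
#' @export
load_feature_set <- function(path, format = c("auto", "bed", "bedgraph")) {
  format <- match.arg(format)
  assert_that(file.exists(path), paste("file not found:", path))
  if (format == "auto") {
    format <- if (grepl("\\.(bedgraph|bdg)$", tolower(path))) "bedgraph" else "bed"
  }
  dt <- tryCatch(
    suppressWarnings(
      data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                        blank.lines.skip = TRUE, data.table = FALSE)),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e), call. = FALSE))
  if (nrow(dt) == 0) {
    return(feature_set(data.frame(chrom = character(), start = numeric(), end = numeric())))
  }
  assert_that(ncol(dt) >= 3, paste("parse error: fewer than 3 columns in", path))
  bad <- which(is.na(suppressWarnings(as.numeric(dt[[2]]))) |
               is.na(suppressWarnings(as.numeric(dt[[3]]))))
  assert_that(length(bad) == 0,
              paste0("parse error at line ", if (length(bad)) bad[1] else 0,
                     " of ", path, ": non-numeric coordinates"))
  out <- data.frame(chrom = as.character(dt[[1]]),
                    start = as.numeric(dt[[2]]),
                    end = as.numeric(dt[[3]]),
                    stringsAsFactors = FALSE)
  if (format == "bedgraph") {
    assert_that(ncol(dt) >= 4, paste("parse error: bedGraph needs 4 columns in", path))
    sc <- suppressWarnings(as.numeric(dt[[4]]))
    assert_that(!anyNA(sc), paste("parse error: non-numeric bedGraph value in", path))
    out$score <- sc
  } else {
    if (ncol(dt) >= 4) out$name <- as.character(dt[[4]])
    if (ncol(dt) >= 5) out$score <- suppressWarnings(as.numeric(dt[[5]]))
    if (ncol(dt) >= 6) out$strand <- as.character(dt[[6]])
  }
  feature_set(out)
}

#' Write a feature set as BED or bedGraph
#'
#' @param fs a `feature_set`.
#' @param path output path.
#' @param format "bed" or "bedgraph" ("bedgraph" requires a `score` column).
#' @export
write_feature_set <- function(fs, path, format = c("bed", "bedgraph")) {
  format <- match.arg(format)
  fs <- feature_set(fs)
  if (format == "bedgraph") {
    assert_that("score" %in% names(fs), "bedgraph output requires a score column")
    out <- fs[, c("chrom", "start", "end", "score")]
  } else {
    cols <- c("chrom", "start", "end",
              intersect(c("name", "score", "strand"), names(fs)))
    # BED is positional: name/score need placeholders if later columns present
    if ("strand" %in% cols && !"score" %in% cols) fs$score <- 0
    if (("score" %in% names(fs) || "strand" %in% cols) && !"name" %in% names(fs))
      fs$name <- "."
    cols <- c("chrom", "start", "end",
              intersect(c("name", "score", "strand"), names(fs)))
    out <- fs[, cols, drop = FALSE]
  }
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a chrom.sizes file
#'
#' @param path two-column (name, length in bp) tab-separated file.
#' @return named numeric vector of chromosome lengths.
#' @export
load_chrom_sizes <- function(path) {
  assert_that(file.exists(path), paste("file not found:", path))
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE)
  assert_that(ncol(dt) >= 2, "chrom.sizes needs 2 columns")
  sizes <- as.numeric(dt[[2]])
  assert_that(all(sizes > 0), "chromosome sizes must be positive")
  stats::setNames(sizes, as.character(dt[[1]]))
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, tab-separated gene ids).
#' @return named list of character vectors.
#' @export
load_gmt <- function(path) {
  assert_that(file.exists(path), paste("file not found:", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    assert_that(length(f) >= 3, "GMT line needs name, description and >= 1 gene")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
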