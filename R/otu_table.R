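#' Construct and validate an OTU count table
#'
#' The central data object of the package: a samples x OTUs matrix of
#' non-negative integer read counts with unique sample and OTU identifiers.
#' Files on disk follow the BIOM-TSV convention (OTUs as rows, samples as
#' columns, first header cell `#OTU_ID`); in memory the orientation is
#' samples x OTUs because every statistic iterates over samples.
#'
#' @param counts Numeric matrix of non-negative integers, samples in rows,
#'   OTUs in columns. Dimnames supply the identifiers unless given explicitly.
#' @param sample_ids,otu_ids Optional identifier vectors overriding dimnames.
#' @return An integer matrix of class `otu_table`.
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids) || is.null(otu_ids))
    stop("sample and OTU identifiers are required", call. = FALSE)
  if (length(sample_ids) != nrow(counts) || length(otu_ids) != ncol(counts))
    stop("identifier lengths do not match the count matrix", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(otu_ids)) stop("duplicate OTU ids", call. = FALSE)
  if (any(!is.finite(counts))) stop("non-finite counts", call. = FALSE)
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative or non-integer count at sample '", sample_ids[bad[1, 1]],
         "', OTU '", otu_ids[bad[1, 2]], "'", call. = FALSE)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, otu_ids)
  class(counts) <- c("otu_table", class(counts))
  counts
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table:", nrow(x), "samples x", ncol(x), "OTUs;",
      "total reads", sum(x), "\n")
  invisible(x)
}

# drop the class for plain matrix work
unclass_otu <- function(x) {
  class(x) <- "matrix"
  x
}

#' Read an OTU table from BIOM-style TSV
#'
#' Tab-separated, UTF-8; lines starting with `#` are comments except the
#' header line whose first cell is literally `#OTU_ID`. Rows are OTUs,
#' columns are samples; the reader transposes to the internal
#' samples x OTUs orientation.
#'
#' @param path File path.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  header_i <- which(startsWith(lines, "#OTU_ID"))
  if (length(header_i) != 1L)
    stop("OTU table format error: expected exactly one '#OTU_ID' header line",
         call. = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  body <- lines[keep]
  header <- strsplit(lines[header_i], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (length(sample_ids) < 1L)
    stop("OTU table format error: no sample columns", call. = FALSE)
  cells <- strsplit(body, "\t", fixed = TRUE)
  n_col <- length(header)
  if (any(lengths(cells) != n_col))
    stop("OTU table format error: ragged rows", call. = FALSE)
  otu_ids <- vapply(cells, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(cells, function(r) as.numeric(r[-1]), numeric(n_col - 1L)))
  if (any(is.na(vals)))
    stop("OTU table value error: non-numeric count", call. = FALSE)
  m <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = n_col - 1L)
  rownames(m) <- otu_ids
  colnames(m) <- sample_ids
  otu_table(t(m))
}

#' Write an OTU table as BIOM-style TSV
#'
#' Inverse of [read_otu_table()]: `read_otu_table(write_otu_table(x, f))`
#' returns a table identical to `x`, ids in the same order.
#'
#' @param table An [otu_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  m <- t(unclass_otu(table))  # OTUs x samples on disk
  lines <- c(
    paste(c("#OTU_ID", colnames(m)), collapse = "\t"),
    vapply(seq_len(nrow(m)),
           function(i) paste(c(rownames(m)[i], m[i, ]), collapse = "\t"),
           character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
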