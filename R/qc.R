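#' Read-level quality filter
#'
#' Retains a read iff it (i) carries a perfect match to a known barcode
#' followed by the 16S primer, (ii) is at least 300 bp long after the
#' barcode + primer prefix is trimmed, and (iii) contains no more than two
#' undetermined (`N`) bases. The criteria are tested in the order
#' (i), (ii), (iii) and a failing read is attributed to the first violated
#' criterion (the order only affects the report, not retention). Retained
#' reads are assigned to samples by barcode and returned trimmed.
#'
#' @param reads Named character vector of reads (or a
#'   `Biostrings::DNAStringSet`).
#' @param barcode_map Named character vector `barcode -> sample_id` (or a
#'   data frame with columns `barcode`, `sample_id`); all barcodes must
#'   share one length and be unique.
#' @param primer Primer sequence expected right after the barcode.
#' @param min_length Minimum trimmed read length (default 300).
#' @param max_ambiguous Maximum `N` bases allowed (default 2).
#' @return List with `reads` (data frame: `read_id`, `sample_id`,
#'   `sequence`) and `report` (a `filter_report`).
#' @export
filter_reads <- function(reads, barcode_map, primer, min_length = 300,
                         max_ambiguous = 2) {
  if (inherits(reads, "DNAStringSet")) {
    nm <- names(reads)
    reads <- as.character(reads)
    names(reads) <- nm
  }
  if (is.data.frame(barcode_map))
    barcode_map <- setNames(barcode_map$sample_id, barcode_map$barcode)
  barcodes <- names(barcode_map)
  if (anyDuplicated(barcodes)) stop("duplicate barcodes", call. = FALSE)
  blen <- unique(nchar(barcodes))
  if (length(blen) != 1L)
    stop("all barcodes must have the same length", call. = FALSE)
  plen <- nchar(primer)
  if (any(nchar(reads) < blen + plen))
    stop("primer longer than some reads", call. = FALSE)

  bc <- substr(reads, 1L, blen)
  pr <- substr(reads, blen + 1L, blen + plen)
  ok_bc <- bc %in% barcodes & pr == primer
  trimmed <- substring(reads, blen + plen + 1L)
  ok_len <- nchar(trimmed) >= min_length
  n_amb <- nchar(trimmed) - nchar(gsub("N", "", trimmed, fixed = TRUE))
  ok_amb <- n_amb <= max_ambiguous

  # first-failing-criterion attribution
  fail_bc <- !ok_bc
  fail_len <- ok_bc & !ok_len
  fail_amb <- ok_bc & ok_len & !ok_amb
  keep <- ok_bc & ok_len & ok_amb

  report <- filter_report(n_input = length(reads),
                          n_failed_barcode = sum(fail_bc),
                          n_failed_length = sum(fail_len),
                          n_failed_ambiguity = sum(fail_amb),
                          n_retained = sum(keep))
  out <- data.frame(read_id = names(reads)[keep] %||%
                      as.character(which(keep)),
                    sample_id = unname(barcode_map[bc[keep]]),
                    sequence = unname(trimmed[keep]),
                    stringsAsFactors = FALSE)
  list(reads = out, report = report)
}

filter_report <- function(n_input, n_failed_barcode, n_failed_length,
                          n_failed_ambiguity, n_retained) {
  stopifnot(n_retained == n_input - n_failed_barcode - n_failed_length -
              n_failed_ambiguity)
  rep <- list(n_input = n_input,
              n_failed_barcode = n_failed_barcode,
              n_failed_length = n_failed_length,
              n_failed_ambiguity = n_failed_ambiguity,
              n_retained = n_retained,
              retained_fraction = if (n_input > 0) n_retained / n_input
                                  else NA_real_)
  class(rep) <- "filter_report"
  rep
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "Read filter: %d input, %d retained (%.1f%%); failed barcode/primer %d, length %d, ambiguity %d\n",
    x$n_input, x$n_retained, 100 * x$retained_fraction,
    x$n_failed_barcode, x$n_failed_length, x$n_failed_ambiguity))
  invisible(x)
}

#' Remove negative-control OTUs from a study table
#'
#' Every OTU detected (count >= 1, no abundance threshold) in the
#' reagent-only negative control is dropped from all samples, and the
#' control sample itself is dropped from the output table. This is the
#' decontamination step that treats blank-control content as reagent or
#' handling contamination.
#'
#' @param table An [otu_table()] containing the control sample.
#' @param metadata `study_metadata` designating exactly one
#'   `negative_control` sample present in the table.
#' @return List with `table` (filtered [otu_table()]) and `removed_otus`
#'   (sorted character vector).
#' @export
remove_control_otus <- function(table, metadata) {
  stopifnot(inherits(table, "otu_table"))
  md <- validate_metadata(metadata)
  ctrl <- md$sample_id[md$sample_type == "negative_control"]
  if (length(ctrl) != 1L)
    stop("metadata must designate exactly one negative_control sample",
         call. = FALSE)
  if (!ctrl %in% rownames(table))
    stop("negative control '", ctrl, "' not present in the table",
         call. = FALSE)
  m <- unclass_otu(table)
  ctrl_counts <- m[ctrl, ]
  if (sum(ctrl_counts) == 0) {
    warning("negative control has zero total counts; nothing removed")
    removed <- character(0)
  } else {
    removed <- sort(colnames(m)[ctrl_counts > 0])
  }
  keep_samples <- setdiff(rownames(m), ctrl)
  keep_otus <- setdiff(colnames(m), removed)
  list(table = otu_table(m[keep_samples, keep_otus, drop = FALSE]),
       removed_otus = removed)
}
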