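#' Read per-sample study metadata
#'
#' TSV with columns `sample_id`, `location_id`, `sample_type`
#' (`egg`, `water` or `negative_control`), `river_group` (`main_river`,
#' `tributary` or `other_basin`), `latitude`, `longitude` (decimal degrees,
#' WGS84), `elevation_m`, `spawn_date`, `sample_date` (ISO dates).
#' Validates the sample-type vocabulary, date ordering and that at most one
#' negative control is present.
#'
#' @param path File path.
#' @return A `data.frame` of class `study_metadata`.
#' @export
read_metadata <- function(path) {
  md <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, comment.char = "#")
  validate_metadata(md)
}

#' Validate study metadata
#' @param md Metadata data frame (see [read_metadata()] for columns).
#' @return The validated data frame, classed `study_metadata`.
#' @export
validate_metadata <- function(md) {
  need <- c("sample_id", "location_id", "sample_type", "river_group",
            "latitude", "longitude", "elevation_m", "spawn_date",
            "sample_date")
  miss <- setdiff(need, names(md))
  if (length(miss) > 0)
    stop("metadata missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample ids in metadata", call. = FALSE)
  bad_type <- setdiff(md$sample_type, c("egg", "water", "negative_control"))
  if (length(bad_type) > 0)
    stop("unknown sample_type: ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  bad_group <- setdiff(md$river_group,
                       c("main_river", "tributary", "other_basin"))
  if (length(bad_group) > 0)
    stop("unknown river_group: ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  if (sum(md$sample_type == "negative_control") > 1L)
    stop("more than one negative_control sample", call. = FALSE)
  md$spawn_date <- as.Date(md$spawn_date)
  md$sample_date <- as.Date(md$sample_date)
  ok <- is.na(md$spawn_date) | is.na(md$sample_date) |
    md$sample_date >= md$spawn_date
  if (!all(ok))
    stop("sample_date earlier than spawn_date for: ",
         paste(md$sample_id[!ok], collapse = ", "), call. = FALSE)
  class(md) <- c("study_metadata", "data.frame")
  md
}

#' Write study metadata as TSV
#' @param md A `study_metadata` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(md, path) {
  write.table(as.data.frame(md), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a square labelled distance matrix from TSV
#'
#' The first column holds ids, the header repeats them. Asymmetries up to
#' `1e-8` are symmetrized by averaging; anything larger is an error, as is a
#' non-zero diagonal.
#'
#' @param path File path.
#' @return A symmetric numeric matrix with zero diagonal and id dimnames.
#' @export
read_distance_matrix <- function(path) {
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, row.names = 1, comment.char = "#")
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  as_distance_matrix(m)
}

#' Write a distance matrix as labelled TSV
#' @param d Symmetric numeric matrix with id dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  d <- as_distance_matrix(d)
  df <- data.frame(id = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read temperature-logger series
#'
#' TSV with columns `location_id`, `timestamp` (ISO 8601), `temperature_c`.
#' Within each location timestamps must be strictly increasing (nominal
#' spacing 10 minutes) and temperatures inside a plausibility window.
#'
#' @param path File path.
#' @param window Plausibility window in degrees Celsius.
#' @return A `data.frame` of class `temperature_series`.
#' @export
read_temperature_series <- function(path, window = c(-5, 30)) {
  ts <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, comment.char = "#")
  validate_temperature_series(ts, window = window)
}

#' Validate a temperature series table
#' @param ts Data frame with `location_id`, `timestamp`, `temperature_c`.
#' @param window Plausibility window in degrees Celsius.
#' @return The validated data frame, classed `temperature_series`.
#' @export
validate_temperature_series <- function(ts, window = c(-5, 30)) {
  need <- c("location_id", "timestamp", "temperature_c")
  miss <- setdiff(need, names(ts))
  if (length(miss) > 0)
    stop("temperature series missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.character(ts$timestamp))
    ts$timestamp <- as.POSIXct(ts$timestamp, tz = "UTC",
                               tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                              "%Y-%m-%d %H:%M:%OS",
                                              "%Y-%m-%d %H:%M",
                                              "%Y-%m-%d"))
  else ts$timestamp <- as.POSIXct(ts$timestamp, tz = "UTC")
  if (any(is.na(ts$timestamp)))
    stop("unparseable timestamps", call. = FALSE)
  for (loc in unique(ts$location_id)) {
    tt <- ts$timestamp[ts$location_id == loc]
    if (is.unsorted(tt, strictly = TRUE))
      stop("timestamps not strictly increasing for location ", loc,
           call. = FALSE)
  }
  out <- ts$temperature_c < window[1] | ts$temperature_c > window[2]
  if (any(out))
    stop(sum(out), " temperature readings outside the plausibility window [",
         window[1], ", ", window[2], "] degC", call. = FALSE)
  class(ts) <- c("temperature_series", "data.frame")
  ts
}

#' Write a temperature series as TSV
#' @param ts A `temperature_series` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_temperature_series <- function(ts, path) {
  df <- as.data.frame(ts)
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
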