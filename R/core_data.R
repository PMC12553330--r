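#' Barcode time-series container
#'
#' Holds read counts for a set of barcoded lineages observed at a series of
#' timepoints, as produced by amplicon sequencing of a chromosomally barcoded
#' population. Counts are stored as a dense (barcode x timepoint) integer
#' matrix; (barcode, time) pairs never observed in the input are zero counts
#' (sequencing non-detection), not missing data.
#'
#' @param counts Integer matrix, barcodes in rows, timepoints in columns.
#'   Row names are the barcode identifiers.
#' @param timepoints Strictly increasing numeric vector of sample times
#'   (generations or days; treated as opaque ordered reals), one per column.
#' @param ids Optional character vector of barcode identifiers; defaults to
#'   `rownames(counts)`.
#'
#' @return An object of class `barcode_ts` with fields `ids`, `timepoints`,
#'   `counts` (dimnamed matrix) and `totals` (reads per timepoint).
#' @examples
#' ts <- barcode_timeseries(matrix(c(10, 30, 20, 0), 2,
#'                                 dimnames = list(c("A", "B"), NULL)),
#'                          timepoints = c(0, 1))
#' ts$totals
#' @export
barcode_timeseries <- function(counts, timepoints, ids = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(ids)) ids <- sprintf("bc%d", seq_len(nrow(counts)))
  ids <- as.character(ids)
  timepoints <- as.numeric(timepoints)
  if (length(ids) != nrow(counts))
    stop("`ids` must have one entry per row of `counts`", call. = FALSE)
  if (length(timepoints) != ncol(counts))
    stop("`timepoints` must have one entry per column of `counts`", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate barcode IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (any(diff(timepoints) <= 0))
    stop("`timepoints` must be strictly increasing", call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "double"  # holds integers exactly; avoids overflow on sums
  dimnames(counts) <- list(ids, as.character(timepoints))
  structure(
    list(ids = ids, timepoints = timepoints, counts = counts,
         totals = colSums(counts)),
    class = "barcode_ts"
  )
}

#' @export
print.barcode_ts <- function(x, ...) {
  cat(sprintf("<barcode_ts> %d barcodes x %d timepoints\n",
              length(x$ids), length(x$timepoints)))
  cat("  timepoints:", paste(utils::head(x$timepoints, 8), collapse = ", "),
      if (length(x$timepoints) > 8) "...\n" else "\n")
  cat("  total reads per timepoint:",
      paste(utils::head(x$totals, 8), collapse = ", "),
      if (length(x$totals) > 8) "...\n" else "\n")
  invisible(x)
}

#' Read a long-format barcode count table
#'
#' Reads a delimited text file with one row per (barcode, timepoint)
#' observation — the standard export format of lineage-tracking pipelines —
#' and assembles the full (barcode x timepoint) count grid. Pairs absent from
#' the file get count zero.
#'
#' @param path Path to a delimited text file with a header row.
#' @param delimiter Field separator, default `","`.
#' @param column_names Character vector of length 3 naming the barcode ID,
#'   time, and read-count columns, in that order. Default
#'   `c("ID", "Time", "Reads")`.
#'
#' @return A [barcode_timeseries()] object. Barcodes keep their order of
#'   first appearance in the file; timepoints are sorted increasing.
#' @export
read_barcode_table <- function(path, delimiter = ",",
                               column_names = c("ID", "Time", "Reads")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(length(column_names) == 3)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "", fileEncoding = "UTF-8")
  missing_cols <- setdiff(column_names, names(df))
  if (length(missing_cols))
    stop("input table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  id <- df[[column_names[1]]]
  tm <- suppressWarnings(as.numeric(df[[column_names[2]]]))
  if (any(is.na(tm)))
    stop("non-numeric time value at row(s): ",
         paste(utils::head(which(is.na(tm)), 5), collapse = ", "), call. = FALSE)
  reads_chr <- df[[column_names[3]]]
  reads <- suppressWarnings(as.numeric(reads_chr))
  bad <- which(is.na(reads) | reads < 0 | reads != round(reads))
  if (length(bad))
    stop("count column must contain non-negative integers; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  key <- paste(id, tm, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicate (barcode, time) row(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  ids <- unique(id)                     # order of first appearance
  times <- sort(unique(tm))
  counts <- matrix(0, length(ids), length(times),
                   dimnames = list(ids, as.character(times)))
  counts[cbind(match(id, ids), match(tm, times))] <- reads
  barcode_timeseries(counts, times)
}

#' Write a barcode time series as a long-format table
#'
#' Inverse of [read_barcode_table()]: rows with zero counts are elided, so
#' `read_barcode_table(write_barcode_table(ts))` reproduces `ts` exactly as
#' long as no barcode (or timepoint) is zero everywhere.
#'
#' @param ts A [barcode_timeseries()] object.
#' @param path Output file path.
#' @param delimiter Field separator, default `","`.
#' @param column_names Header names for the ID, time and count columns.
#' @return `path`, invisibly.
#' @export
write_barcode_table <- function(ts, path, delimiter = ",",
                                column_names = c("ID", "Time", "Reads")) {
  stopifnot(inherits(ts, "barcode_ts"), length(column_names) == 3)
  nz <- which(ts$counts > 0, arr.ind = TRUE)
  nz <- nz[order(nz[, 1], nz[, 2]), , drop = FALSE]
  df <- data.frame(ts$ids[nz[, 1]], ts$timepoints[nz[, 2]],
                   ts$counts[nz], check.names = FALSE)
  names(df) <- column_names
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert read counts to per-timepoint frequencies
#'
#' Normalises each timepoint's counts to frequencies summing to one, and
#' fixes the pseudo-frequency "floor" substituted for zeros by log-scale
#' consumers (log-transformed distances, log-scale plots). The floor is never
#' applied to the stored frequencies themselves — diversity indices, for
#' example, see exact zeros.
#'
#' @param ts A [barcode_timeseries()] object with positive total reads at
#'   every timepoint.
#' @param floor_policy Either `"half_min_detectable"` (default), setting the
#'   floor to half of the smallest detectable frequency,
#'   `1 / (2 * max(totals))`, or `"fixed"`, using `floor_value`.
#' @param floor_value Positive number used when `floor_policy = "fixed"`.
#'
#' @return An object of class `frequency_matrix` with fields `freqs`
#'   (barcode x timepoint, columns summing to 1), `floor`, `ids` and
#'   `timepoints`.
#' @examples
#' ts <- barcode_timeseries(matrix(c(10, 30, 5, 15), 2,
#'                                 dimnames = list(c("A", "B"), NULL)), c(0, 1))
#' to_frequencies(ts)$freqs
#' @export
to_frequencies <- function(ts, floor_policy = c("half_min_detectable", "fixed"),
                           floor_value = NULL) {
  stopifnot(inherits(ts, "barcode_ts"))
  floor_policy <- match.arg(floor_policy)
  zero_t <- which(ts$totals <= 0)
  if (length(zero_t))
    stop("timepoint(s) with zero total reads: ",
         paste(ts$timepoints[zero_t], collapse = ", "), call. = FALSE)
  floor <- if (floor_policy == "half_min_detectable") {
    1 / (2 * max(ts$totals))
  } else {
    if (is.null(floor_value) || floor_value <= 0)
      stop("`floor_value` must be a positive number", call. = FALSE)
    floor_value
  }
  freqs <- sweep(ts$counts, 2, ts$totals, "/")
  frequency_matrix(freqs, ts$timepoints, floor)
}

#' Construct a frequency matrix directly
#'
#' Low-level constructor used by [to_frequencies()] and by the filtering
#' step. Columns must sum to 1 (or be flagged as an unnormalised subset via
#' `subset_of_population = TRUE`, as after filtering, when the surviving
#' barcodes deliberately remain fractions of the whole population).
#'
#' @param freqs Numeric matrix (barcode x timepoint) with barcode row names.
#' @param timepoints Strictly increasing numeric vector.
#' @param floor Positive pseudo-frequency used for zeros in log space.
#' @param subset_of_population Logical; `TRUE` when rows are a filtered
#'   subset so columns legitimately sum to less than 1.
#' @return A `frequency_matrix` object.
#' @export
frequency_matrix <- function(freqs, timepoints, floor,
                             subset_of_population = FALSE) {
  freqs <- as.matrix(freqs)
  if (is.null(rownames(freqs)))
    rownames(freqs) <- sprintf("bc%d", seq_len(nrow(freqs)))
  if (any(freqs < 0) || any(freqs > 1 + 1e-9))
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  if (!subset_of_population && nrow(freqs) > 0) {
    cs <- colSums(freqs)
    if (any(abs(cs - 1) > 1e-9))
      stop("frequency columns must sum to 1 (got ",
           paste(signif(cs[abs(cs - 1) > 1e-9], 6), collapse = ", "), ")",
           call. = FALSE)
  }
  if (!is.numeric(floor) || floor <= 0)
    stop("`floor` must be positive", call. = FALSE)
  colnames(freqs) <- as.character(timepoints)
  structure(
    list(freqs = freqs, timepoints = as.numeric(timepoints), floor = floor,
         ids = rownames(freqs), subset_of_population = subset_of_population),
    class = "frequency_matrix"
  )
}

#' @export
print.frequency_matrix <- function(x, ...) {
  cat(sprintf("<frequency_matrix> %d barcodes x %d timepoints (floor %.3g%s)\n",
              nrow(x$freqs), ncol(x$freqs), x$floor,
              if (x$subset_of_population) ", filtered subset" else ""))
  invisible(x)
}
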