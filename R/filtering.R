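#' Noise-suppression filter specification
#'
#' Barcode read-count series are noisy at low frequency: sporadic detections
#' near the sequencing floor reflect sampling noise more than lineage
#' dynamics. Before clustering, barcodes are therefore required to exceed a
#' mean-frequency threshold and to be detected (nonzero reads) in a minimum
#' number of timepoints.
#'
#' @param min_mean_frequency Barcodes must have arithmetic mean frequency
#'   (over all timepoints, zeros included) strictly above this value.
#'   Default `1e-4`.
#' @param min_persistence Barcodes must have nonzero frequency in at least
#'   this many timepoints. Default `12`.
#' @param n_timepoints Total number of timepoints the spec applies to.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(min_mean_frequency = 1e-4, min_persistence = 12,
                        n_timepoints) {
  stopifnot(min_mean_frequency >= 0, min_mean_frequency <= 1,
            min_persistence >= 0, n_timepoints >= 1,
            min_persistence <= n_timepoints)
  structure(list(min_mean_frequency = min_mean_frequency,
                 min_persistence = as.integer(min_persistence),
                 n_timepoints = as.integer(n_timepoints)),
            class = "filter_spec")
}

#' Apply mean-frequency and persistence filters
#'
#' A barcode survives iff its arithmetic mean frequency across all timepoints
#' is strictly greater than `spec$min_mean_frequency` AND it is detected
#' (frequency > 0, i.e. at least one read) in at least `spec$min_persistence`
#' timepoints. Surviving rows are NOT renormalised: they remain fractions of
#' the whole population, so downstream cluster abundances are population
#' fractions.
#'
#' @param fm A [frequency_matrix()].
#' @param spec A [filter_spec()] whose `n_timepoints` matches `fm`.
#' @return A list with `fm` (the restricted `frequency_matrix`, flagged as a
#'   population subset) and `report` (a data frame of rejected barcodes with
#'   columns `id`, `mean_frequency`, `persistence`, `failed`, the latter one
#'   of `"mean_frequency"`, `"persistence"`, `"both"`).
#' @examples
#' ts <- barcode_timeseries(matrix(c(500, 500, 1, 999), 2, byrow = TRUE,
#'                                 dimnames = list(c("hi", "lo"), NULL)), 0:1)
#' apply_filters(to_frequencies(ts), filter_spec(0.1, 2, 2))$report
#' @export
apply_filters <- function(fm, spec) {
  stopifnot(inherits(fm, "frequency_matrix"), inherits(spec, "filter_spec"))
  if (spec$n_timepoints != ncol(fm$freqs))
    stop("filter spec is for ", spec$n_timepoints, " timepoints but the ",
         "series has ", ncol(fm$freqs), call. = FALSE)
  mean_freq <- rowMeans(fm$freqs)
  persistence <- rowSums(fm$freqs > 0)
  pass_mean <- mean_freq > spec$min_mean_frequency
  pass_pers <- persistence >= spec$min_persistence
  keep <- pass_mean & pass_pers
  rejected <- which(!keep)
  failed <- ifelse(!pass_mean[rejected] & !pass_pers[rejected], "both",
                   ifelse(!pass_mean[rejected], "mean_frequency", "persistence"))
  report <- data.frame(id = fm$ids[rejected],
                       mean_frequency = unname(mean_freq[rejected]),
                       persistence = unname(persistence[rejected]),
                       failed = failed,
                       row.names = NULL, stringsAsFactors = FALSE)
  out <- frequency_matrix(fm$freqs[keep, , drop = FALSE], fm$timepoints,
                          fm$floor, subset_of_population = TRUE)
  list(fm = out, report = report)
}
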