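#' Hill number (effective diversity) of a frequency vector
#'
#' The effective diversity of order `q` of a set of lineage frequencies
#' `f_k` is `D_q = (sum_k f_k^q)^(1/(1-q))`, the number of equally frequent
#' lineages that would give the same diversity. `q = 0` counts the lineages
#' present (richness), `q = 1` is the exponential of Shannon entropy (the
#' analytic limit), `q = 2` the inverse Simpson index, and `q = Inf` the
#' inverse of the largest frequency (dominance). Zero frequencies are
#' excluded from the power sum, the standard Hill-number convention.
#'
#' @param f Numeric vector of frequencies, non-negative and summing to 1.
#' @param q Diversity order: a single non-negative real, or `Inf`.
#' @return The effective diversity, a real number `>= 1`.
#' @examples
#' hill_number(rep(0.25, 4), 2)   # uniform: D_q = richness for every q
#' hill_number(c(0.8, 0.2), Inf)  # 1 / max f
#' @export
hill_number <- function(f, q) {
  stopifnot(is.numeric(f), length(q) == 1, is.numeric(q), q >= 0)
  if (any(is.na(f)) || any(f < 0))
    stop("frequencies must be non-negative and non-missing", call. = FALSE)
  if (abs(sum(f) - 1) > 1e-9)
    stop("frequencies must sum to 1 (got ", signif(sum(f), 8), ")",
         call. = FALSE)
  f <- f[f > 0]
  if (is.infinite(q)) return(1 / max(f))
  if (q == 1) return(exp(-sum(f * log(f))))
  sum(f^q)^(1 / (1 - q))
}

#' Effective diversity over time
#'
#' Applies [hill_number()] to each timepoint of a frequency matrix for a set
#' of diversity orders, giving the diversity trajectory of the population.
#'
#' @param fm A [frequency_matrix()]. Filtered (subset) matrices are accepted:
#'   each column is renormalised over the barcodes present before the index
#'   is computed.
#' @param orders Numeric vector of diversity orders; may include `Inf`.
#'   Default `c(0, 1, 2, Inf)`.
#' @return An object of class `diversity_profile`: list with `orders`,
#'   `timepoints`, and `values`, an (order x timepoint) matrix. Timepoints
#'   where every barcode has zero frequency yield `NA` with a warning.
#' @export
diversity_timeseries <- function(fm, orders = c(0, 1, 2, Inf)) {
  stopifnot(inherits(fm, "frequency_matrix"), length(orders) >= 1)
  values <- matrix(NA_real_, length(orders), ncol(fm$freqs),
                   dimnames = list(ifelse(is.infinite(orders), "Inf", orders),
                                   colnames(fm$freqs)))
  for (j in seq_len(ncol(fm$freqs))) {
    col <- fm$freqs[, j]
    tot <- sum(col)
    if (tot <= 0) {
      warning("timepoint ", fm$timepoints[j],
              " has no barcodes present; diversity undefined", call. = FALSE)
      next
    }
    col <- col / tot
    for (i in seq_along(orders)) values[i, j] <- hill_number(col, orders[i])
  }
  structure(list(orders = orders, timepoints = fm$timepoints, values = values),
            class = "diversity_profile")
}

#' @export
print.diversity_profile <- function(x, ...) {
  cat(sprintf("<diversity_profile> orders {%s} over %d timepoints\n",
              paste(x$orders, collapse = ", "), length(x$timepoints)))
  print(signif(x$values, 4))
  invisible(x)
}

#' Tidy a diversity profile
#'
#' @param profile A `diversity_profile`.
#' @return A long data frame with columns `time`, `q`, `diversity`.
#' @export
as.data.frame.diversity_profile <- function(x, ...) {
  data.frame(
    time = rep(x$timepoints, each = length(x$orders)),
    q = rep(ifelse(is.infinite(x$orders), "Inf", as.character(x$orders)),
            times = length(x$timepoints)),
    diversity = as.vector(x$values),
    stringsAsFactors = FALSE
  )
}
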