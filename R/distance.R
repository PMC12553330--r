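#' Transform frequency trajectories for distance computation
#'
#' Barcode frequencies span orders of magnitude, so trajectory comparison is
#' done on log10 frequencies by default, with zeros replaced by the
#' detection floor of the frequency matrix. The linear scale is available
#' for data where absolute frequency differences matter.
#'
#' @param fm A [frequency_matrix()].
#' @param transform `"log10_floored"` (default) or `"linear"`.
#' @return A numeric matrix (barcode x timepoint) of transformed
#'   trajectories.
#' @export
transform_trajectories <- function(fm,
                                   transform = c("log10_floored", "linear")) {
  stopifnot(inherits(fm, "frequency_matrix"))
  transform <- match.arg(transform)
  if (transform == "linear") return(fm$freqs)
  log10(pmax(fm$freqs, fm$floor))
}

#' Pearson correlation distance between two trajectories
#'
#' `1 - r(x, y)`, where `r` is the Pearson correlation coefficient: 0 for
#' perfectly correlated dynamics, 2 for perfectly anti-correlated ones.
#' Anti-correlated trajectories are maximally dissimilar lineage behaviours
#' (one rises as the other collapses), hence `1 - r` rather than `1 - |r|`.
#'
#' @param x,y Numeric trajectories of equal length `>= 3`, each with nonzero
#'   variance.
#' @param ids Optional length-2 character vector naming the trajectories for
#'   error messages.
#' @return Distance in `[0, 2]`.
#' @export
pearson_distance <- function(x, y, ids = c("x", "y")) {
  if (length(x) != length(y)) stop("trajectories differ in length", call. = FALSE)
  if (length(x) < 3)
    stop("need at least 3 timepoints for a correlation distance", call. = FALSE)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 || vy == 0)
    stop("constant trajectory for barcode '", ids[if (vx == 0) 1 else 2],
         "': correlation undefined; remove flat trajectories by filtering",
         call. = FALSE)
  1 - stats::cor(x, y)
}

#' Dynamic time warping distance between two trajectories
#'
#' Classic DTW with local cost `|x_i - y_j|` and symmetric steps
#' (insertion, deletion, match): `D(i,j) = cost(i,j) +
#' min(D(i-1,j), D(i,j-1), D(i-1,j-1))`, returning the cumulative cost
#' `D(n,m)` of the cheapest monotone alignment of the two series. No
#' path-length normalisation is applied. An optional Sakoe-Chiba band of
#' half-width `window` restricts the alignment to `|i - j| <= window`.
#'
#' @param x,y Numeric trajectories (lengths may differ).
#' @param window Optional integer band half-width; must be at least
#'   `abs(length(x) - length(y))` so that at least one path exists.
#' @return Non-negative cumulative alignment cost.
#' @export
dtw_distance <- function(x, y, window = NULL) {
  n <- length(x); m <- length(y)
  stopifnot(n >= 1, m >= 1)
  if (!is.null(window)) {
    window <- as.integer(window)
    if (window < abs(n - m))
      stop("window (", window, ") too small: no warping path can reach (",
           n, ",", m, ")", call. = FALSE)
  }
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    jr <- if (is.null(window)) 1:m else max(1, i - window):min(m, i + window)
    for (j in jr) {
      D[i + 1, j + 1] <- abs(x[i] - y[j]) +
        min(D[i, j + 1], D[i + 1, j], D[i, j])
    }
  }
  D[n + 1, m + 1]
}

#' Pairwise trajectory distance matrix
#'
#' Computes all unordered pairwise distances between barcode trajectories on
#' the chosen scale with the chosen metric, the input to hierarchical
#' clustering.
#'
#' @param fm A [frequency_matrix()] with at least 2 barcodes (typically the
#'   filtered matrix).
#' @param metric `"pearson"` (default) or `"dtw"`.
#' @param transform Trajectory scale, see [transform_trajectories()].
#' @param window Optional Sakoe-Chiba band for DTW.
#' @return An object of class `trajectory_dist`: list with `ids`, `d` (a
#'   symmetric matrix with zero diagonal), `metric`, `transform`,
#'   `trajectories` (the transformed matrix the distances were computed on)
#'   and `floor`.
#' @export
build_distance_matrix <- function(fm, metric = c("pearson", "dtw"),
                                  transform = c("log10_floored", "linear"),
                                  window = NULL) {
  stopifnot(inherits(fm, "frequency_matrix"))
  metric <- match.arg(metric)
  transform <- match.arg(transform)
  traj <- transform_trajectories(fm, transform)
  n <- nrow(traj)
  if (n < 2) stop("need at least 2 barcodes to build a distance matrix",
                  call. = FALSE)
  ids <- rownames(traj)
  if (metric == "pearson") {
    if (ncol(traj) < 3)
      stop("need at least 3 timepoints for a correlation distance", call. = FALSE)
    rv <- apply(traj, 1, stats::var)
    if (any(rv == 0))
      stop("constant trajectory for barcode(s) ",
           paste(ids[rv == 0], collapse = ", "),
           ": correlation undefined; remove flat trajectories by filtering",
           call. = FALSE)
    d <- 1 - stats::cor(t(traj))
    d[d < 0] <- 0                       # guard tiny negative rounding
    diag(d) <- 0
    d <- (d + t(d)) / 2
  } else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- dtw_distance(traj[i, ], traj[j, ], window)
      }
    }
  }
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d, metric = metric, transform = transform,
                 trajectories = traj, floor = fm$floor,
                 timepoints = fm$timepoints),
            class = "trajectory_dist")
}

#' @export
print.trajectory_dist <- function(x, ...) {
  cat(sprintf("<trajectory_dist> %d barcodes, metric %s on %s scale\n",
              length(x$ids), x$metric, x$transform))
  invisible(x)
}
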