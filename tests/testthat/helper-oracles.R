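# Independent reference implementations used as oracles. These deliberately
# share no code with the package: brute-force recursion for DTW, literal
# recomputation of average linkage from the original matrix for UPGMA.

# minimum warping-path cost by plain recursion over all monotone paths
bf_dtw <- function(x, y) {
  rec <- function(i, j) {
    c0 <- abs(x[i] - y[j])
    if (i == 1 && j == 1) return(c0)
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    c0 + best
  }
  rec(length(x), length(y))
}

# naive O(n^3) average linkage: every step recomputes every cluster-pair
# mean cross-distance from the original matrix
naive_upgma_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        cross <- mean(d[clusters[[i]], clusters[[j]]])
        if (cross < best) { best <- cross; bi <- i; bj <- j }
      }
    }
    heights[step] <- best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# random symmetric distance matrix with zero diagonal
random_dist <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.05, 2)
  d <- d + t(d)
  dimnames(d) <- list(sprintf("L%02d", 1:n), sprintf("L%02d", 1:n))
  d
}

# random point on the simplex (frequency vector)
random_simplex <- function(k) {
  x <- rexp(k)
  x / sum(x)
}

# small frequency_matrix built from a count matrix
fm_from_counts <- function(counts, timepoints = seq_len(ncol(counts)) - 1) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("bc%02d", seq_len(nrow(counts)))
  clonetrack::to_frequencies(
    clonetrack::barcode_timeseries(counts, timepoints))
}

# random barcode table for round-trip tests: every barcode and timepoint
# has at least one positive count so the long format preserves the grid
random_barcode_ts <- function(n_bc, n_t) {
  repeat {
    counts <- matrix(rpois(n_bc * n_t, 3), n_bc, n_t)
    if (all(rowSums(counts) > 0) && all(colSums(counts) > 0)) break
  }
  rownames(counts) <- sprintf("BC%03d", seq_len(n_bc))
  clonetrack::barcode_timeseries(counts, sort(sample(0:99, n_t)))
}
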