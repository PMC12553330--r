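#' Agglomerative clustering of barcode trajectories
#'
#' Builds the merge history (dendrogram) of the barcode trajectories from
#' their pairwise distance matrix, by unweighted average linkage (UPGMA) or
#' centroid linkage (UPGMC).
#'
#' UPGMA defines the distance between two clusters as the unweighted mean of
#' all cross-pair distances, updated by the Lance-Williams recurrence, and
#' guarantees monotone merge heights. UPGMC defines it as the metric
#' distance between cluster centroid trajectories, where a centroid is the
#' pointwise mean of member trajectories in the transformed trajectory
#' space. Centroids are deliberately computed in trajectory space rather
#' than via the Lance-Williams centroid update, because the latter is only
#' valid for squared Euclidean distances and the correlation and DTW metrics
#' used here are not Euclidean. UPGMC heights may show inversions; that is
#' intrinsic to centroid linkage.
#'
#' Merge order is deterministic: exact ties in minimum distance are broken
#' by the lexicographically smallest pair of smallest member IDs.
#'
#' @param dm A [build_distance_matrix()] result.
#' @param method `"upgma"` (default) or `"upgmc"`.
#' @return An object of class `linkage_tree`: list with `merges` (an
#'   (n-1) x 2 matrix in `hclust` convention: negative entries are leaves,
#'   positive entries earlier merges), `heights`, `sizes`, `leaf_ids` and
#'   `method`.
#' @export
linkage <- function(dm, method = c("upgma", "upgmc")) {
  stopifnot(inherits(dm, "trajectory_dist"))
  method <- match.arg(method)
  d <- dm$d
  if (any(is.na(d)) || any(!is.finite(d)))
    stop("distance matrix contains NA/non-finite entries", call. = FALSE)
  n <- nrow(d)
  stopifnot(n >= 2)
  ids <- dm$ids

  # active-cluster state; slot i of W holds distances for cluster `slot i`
  W <- d
  diag(W) <- Inf
  active <- rep(TRUE, n)
  node <- -seq_len(n)            # hclust code of the cluster in each slot
  size <- rep(1L, n)
  min_id <- ids                  # smallest member ID per slot, for tie-breaks
  members <- as.list(seq_len(n)) # leaf indices per slot (upgmc centroids)
  traj <- dm$trajectories

  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  sizes <- integer(n - 1)

  centroid_dist <- function(ci, cj) {
    if (dm$metric == "pearson") {
      if (stats::var(ci) == 0 || stats::var(cj) == 0)
        stop("a cluster centroid trajectory is constant: correlation-based ",
             "centroid linkage undefined; use UPGMA or the DTW metric",
             call. = FALSE)
      max(0, 1 - stats::cor(ci, cj))
    } else {
      dtw_distance(ci, cj)
    }
  }

  for (step in seq_len(n - 1)) {
    Wa <- W[active, active, drop = FALSE]
    mn <- min(Wa)
    idx_a <- which(active)
    hit <- which(Wa == mn, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    i <- idx_a[hit[, 1]]; j <- idx_a[hit[, 2]]
    if (length(i) > 1) {                       # deterministic tie-break
      lo <- ifelse(min_id[i] <= min_id[j], min_id[i], min_id[j])
      hi <- ifelse(min_id[i] <= min_id[j], min_id[j], min_id[i])
      ord <- order(lo, hi)[1]
      i <- i[ord]; j <- j[ord]
    }
    merges[step, ] <- sort(c(node[i], node[j]))  # leaves (<0) before merges
    heights[step] <- mn
    sizes[step] <- size[i] + size[j]

    others <- idx_a[idx_a != i & idx_a != j]
    if (method == "upgma") {
      newd <- (size[i] * W[i, others] + size[j] * W[j, others]) /
        (size[i] + size[j])
    } else {
      members[[i]] <- c(members[[i]], members[[j]])
      ci <- colMeans(traj[members[[i]], , drop = FALSE])
      newd <- vapply(others, function(k) {
        ck <- if (size[k] == 1L) traj[members[[k]], ] else
          colMeans(traj[members[[k]], , drop = FALSE])
        centroid_dist(ci, ck)
      }, numeric(1))
    }
    W[i, others] <- newd; W[others, i] <- newd
    active[j] <- FALSE
    node[i] <- step
    size[i] <- size[i] + size[j]
    if (min_id[j] < min_id[i]) min_id[i] <- min_id[j]
  }

  structure(list(merges = merges, heights = heights, sizes = sizes,
                 leaf_ids = ids, method = method,
                 metric = dm$metric, transform = dm$transform),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("<linkage_tree> %s on %d leaves (%s metric), merge heights %.3g .. %.3g\n",
              toupper(x$method), length(x$leaf_ids), x$metric,
              min(x$heights), max(x$heights)))
  invisible(x)
}

# leaf index sets of every internal node, in merge order
.merge_members <- function(tree) {
  n1 <- nrow(tree$merges)
  out <- vector("list", n1)
  for (s in seq_len(n1)) {
    grab <- function(code) if (code < 0) -code else out[[code]]
    out[[s]] <- c(grab(tree$merges[s, 1]), grab(tree$merges[s, 2]))
  }
  out
}

#' Cut a linkage tree at a height
#'
#' Clusters are the maximal subtrees all of whose internal merge heights are
#' `<= height` — for monotone (UPGMA) trees this is the ordinary dendrogram
#' cut; the subtree formulation also remains well defined for centroid-
#' linkage trees with height inversions. Each cluster is labelled by its
#' smallest member barcode ID.
#'
#' @param tree A [linkage()] result.
#' @param height Non-negative cut height.
#' @return Named character vector mapping each barcode ID to its cluster
#'   label.
#' @export
cut_linkage <- function(tree, height) {
  stopifnot(inherits(tree, "linkage_tree"), height >= 0)
  n1 <- nrow(tree$merges)
  n <- n1 + 1
  # a merge node is "good" iff its height <= cut and both children are good
  good <- logical(n1)
  for (s in seq_len(n1)) {
    kids_good <- all(vapply(tree$merges[s, ], function(code)
      code < 0 || good[code], logical(1)))
    good[s] <- kids_good && tree$heights[s] <= height
  }
  cl <- seq_len(n)                       # cluster id per leaf, start singleton
  memb <- .merge_members(tree)
  for (s in seq_len(n1)) if (good[s]) cl[memb[[s]]] <- min(cl[memb[[s]]])
  labels <- vapply(split(tree$leaf_ids, cl), min, character(1))
  out <- labels[as.character(cl)]
  names(out) <- tree$leaf_ids
  out
}

# mean silhouette width of a partition given a distance matrix;
# singleton members contribute 0 by the usual convention
.mean_silhouette <- function(d, asg) {
  f <- factor(asg)
  k <- nlevels(f)
  if (k < 2) return(NA_real_)
  sizes <- tabulate(f)
  # mean distance from every point to every cluster
  M <- t(rowsum(d, as.integer(f)) / sizes)  # n x k
  own <- as.integer(f)
  idx <- cbind(seq_along(own), own)
  a <- M[idx] * sizes[own] / pmax(sizes[own] - 1, 1)
  Mo <- M; Mo[idx] <- Inf
  b <- apply(Mo, 1, min)
  s <- ifelse(sizes[own] == 1, 0, (b - a) / pmax(a, b))
  mean(s)
}

#' Sweep cut heights and quantify the clusterings
#'
#' Evaluates dendrogram cuts on an evenly spaced grid of heights from 0 to
#' the maximum merge height, recording per cut the cluster count, the
#' minimum pairwise metric distance between cluster centroid trajectories
#' (the pointwise mean of member trajectories), and the mean silhouette
#' width of the partition. The resulting profile shows where cluster counts
#' plateau and how separated the resulting consensus behaviours are,
#' supporting the user's threshold choice.
#'
#' @param tree A [linkage()] result.
#' @param dm The [build_distance_matrix()] result the tree was built from.
#' @param grid_size Number of grid points, `>= 2`. Default 100.
#' @return An object of class `cluster_quantification`: data frame with
#'   columns `threshold`, `n_clusters`, `centroid_separation` (`NA` when a
#'   single cluster remains or a correlation centroid is degenerate) and
#'   `mean_silhouette` (`NA` when a single cluster remains).
#' @export
quantify_thresholds <- function(tree, dm, grid_size = 100) {
  stopifnot(inherits(tree, "linkage_tree"), inherits(dm, "trajectory_dist"),
            grid_size >= 2)
  grid <- seq(0, max(tree$heights), length.out = grid_size)
  traj <- dm$trajectories
  res <- lapply(grid, function(h) {
    asg <- cut_linkage(tree, h)
    groups <- split(names(asg), asg)
    k <- length(groups)
    sep <- NA_real_
    if (k > 1) {
      cent <- t(vapply(groups, function(g)
        colMeans(traj[g, , drop = FALSE]), numeric(ncol(traj))))
      sep <- tryCatch({
        if (dm$metric == "pearson") {
          dd <- 1 - stats::cor(t(cent))
          min(dd[upper.tri(dd)])
        } else {
          mind <- Inf
          for (a in seq_len(k - 1)) for (b in (a + 1):k)
            mind <- min(mind, dtw_distance(cent[a, ], cent[b, ]))
          mind
        }
      }, error = function(e) NA_real_)
    }
    c(n_clusters = k, centroid_separation = sep,
      mean_silhouette = .mean_silhouette(dm$d[names(asg), names(asg)], asg))
  })
  res <- do.call(rbind, res)
  out <- data.frame(threshold = grid,
                    n_clusters = as.integer(res[, "n_clusters"]),
                    centroid_separation = res[, "centroid_separation"],
                    mean_silhouette = res[, "mean_silhouette"])
  class(out) <- c("cluster_quantification", "data.frame")
  out
}

#' Pick a cut height from a threshold sweep
#'
#' Threshold choice is fundamentally the user's: the quantification profile
#' is meant to be inspected. Three convenience heuristics are provided.
#' `"silhouette"` (default) picks the grid point maximising the mean
#' silhouette width — the standard internal-validation criterion balancing
#' cluster cohesion against separation. `"knee"` picks the grid point
#' maximising the second difference of the cluster count (the sharpest
#' elbow of the count curve). `"plateau"` picks the midpoint of the longest
#' run of constant cluster count with more than one cluster — the most
#' stable clustering in the sweep.
#'
#' @param quant A [quantify_thresholds()] result.
#' @param method `"silhouette"`, `"knee"` or `"plateau"`.
#' @return A single cut height.
#' @export
select_threshold <- function(quant, method = c("silhouette", "knee",
                                               "plateau")) {
  stopifnot(inherits(quant, "cluster_quantification"))
  method <- match.arg(method)
  k <- quant$n_clusters
  if (method == "silhouette") {
    sil <- quant$mean_silhouette
    if (all(is.na(sil))) return(quant$threshold[length(k)])
    quant$threshold[which.max(sil)]
  } else if (method == "knee") {
    if (length(k) < 3) return(quant$threshold[1])
    d2 <- k[-c(length(k) - 1, length(k))] - 2 * k[-c(1, length(k))] +
      k[-c(1, 2)]
    quant$threshold[which.max(d2) + 1]
  } else {
    r <- rle(k)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    ok <- which(r$values > 1)
    if (!length(ok)) return(quant$threshold[length(k)])
    best <- ok[which.max(r$lengths[ok])]
    quant$threshold[floor((starts[best] + ends[best]) / 2)]
  }
}

#' LOESS consensus trajectory of a cluster
#'
#' Pools the (time, value) points of all member trajectories, unweighted,
#' and fits a locally weighted polynomial regression (tricube weights)
#' evaluated at the common timepoints. The consensus is computed on the same
#' scale (log or linear) the clustering used.
#'
#' @param members Numeric matrix of member trajectories (members x
#'   timepoints), already on the clustering scale.
#' @param timepoints Numeric vector of sample times.
#' @param span LOESS span in (0, 1]; default 0.75.
#' @param degree Local polynomial degree, 1 or 2; default 2.
#' @return Numeric consensus trajectory at `timepoints`. When the pooled
#'   points cannot support the local fit the pointwise mean is returned with
#'   a warning.
#' @export
loess_consensus <- function(members, timepoints, span = 0.75, degree = 2) {
  members <- rbind(members)
  stopifnot(ncol(members) == length(timepoints), nrow(members) >= 1,
            span > 0, span <= 1, degree %in% c(1, 2))
  df <- data.frame(t = rep(timepoints, each = nrow(members)),
                   y = as.vector(members))
  if (nrow(df) < degree + 2) {
    warning("too few points for the local LOESS window; ",
            "falling back to the pointwise mean", call. = FALSE)
    return(unname(colMeans(members)))
  }
  fit <- tryCatch(
    suppressWarnings(stats::predict(
      stats::loess(y ~ t, data = df, span = span, degree = degree,
                   family = "gaussian",
                   control = stats::loess.control(surface = "direct")),
      newdata = data.frame(t = timepoints))),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit))) {
    warning("too few points for the local LOESS window; ",
            "falling back to the pointwise mean", call. = FALSE)
    fit <- colMeans(members)
  }
  unname(fit)
}

#' Call ranked clonal clusters
#'
#' Cuts the dendrogram at the chosen height, fits a LOESS consensus per
#' cluster, and ranks clusters `C1, C2, ...` by descending summed member
#' frequency at the final timepoint — `C1` is the dominant clonal lineage.
#' Because filtered frequencies are never renormalised, these summed
#' frequencies are fractions of the whole population. Clusters whose final
#' summed frequency falls below `min_cluster_frequency` are kept but flagged
#' as minor, never dropped.
#'
#' @param fm The (filtered) [frequency_matrix()] that was clustered.
#' @param dm The [build_distance_matrix()] result.
#' @param tree The [linkage()] result.
#' @param height Cut height in `[0, max merge height]`.
#' @param span,degree LOESS consensus parameters, see [loess_consensus()].
#' @param min_cluster_frequency Final-frequency threshold below which a
#'   cluster is flagged minor. Default 0.01.
#' @return An object of class `clonal_cluster_set`: list with `assignment`
#'   (barcode -> cluster label, e.g. `"C1"`), `clusters` (data frame: label,
#'   n_members, final_frequency, minor flag, smallest member), `consensus`
#'   (cluster x timepoint matrix on the frequency scale, back-transformed
#'   from log and floored at the detection floor when the clustering was on
#'   the log scale), `consensus_scale` (the clustering-scale consensus),
#'   `timepoints` and `cut_height`.
#' @export
call_clonal_clusters <- function(fm, dm, tree, height, span = 0.75,
                                 degree = 2, min_cluster_frequency = 0.01) {
  stopifnot(inherits(fm, "frequency_matrix"), inherits(dm, "trajectory_dist"),
            inherits(tree, "linkage_tree"))
  if (height < 0 || height > max(tree$heights))
    stop("cut height must lie in [0, ", signif(max(tree$heights), 6), "]",
         call. = FALSE)
  asg <- cut_linkage(tree, height)
  groups <- split(names(asg), asg)

  final_f <- fm$freqs[, ncol(fm$freqs)]
  gf <- vapply(groups, function(g) sum(final_f[g]), numeric(1))
  smallest <- vapply(groups, min, character(1))
  ord <- order(-gf, smallest)            # ties: smallest member ID first
  labels <- paste0("C", seq_along(groups))
  names(labels) <- names(groups)[ord]

  assignment <- labels[asg]
  names(assignment) <- names(asg)

  tp <- fm$timepoints
  cons_scale <- t(vapply(names(groups)[ord], function(g)
    loess_consensus(dm$trajectories[groups[[g]], , drop = FALSE], tp,
                    span = span, degree = degree),
    numeric(length(tp))))
  rownames(cons_scale) <- labels
  colnames(cons_scale) <- as.character(tp)
  cons_freq <- if (dm$transform == "log10_floored") {
    pmax(10^cons_scale, fm$floor)
  } else {
    pmax(cons_scale, 0)
  }

  clusters <- data.frame(
    label = labels,
    n_members = vapply(groups[ord], length, integer(1)),
    final_frequency = unname(gf[ord]),
    minor = unname(gf[ord]) < min_cluster_frequency,
    smallest_member = unname(smallest[ord]),
    row.names = NULL, stringsAsFactors = FALSE
  )

  structure(list(assignment = assignment, clusters = clusters,
                 consensus = cons_freq, consensus_scale = cons_scale,
                 timepoints = tp, cut_height = height),
            class = "clonal_cluster_set")
}

#' @export
print.clonal_cluster_set <- function(x, ...) {
  cat(sprintf("<clonal_cluster_set> %d clusters at cut height %.4g\n",
              nrow(x$clusters), x$cut_height))
  print(x$clusters)
  invisible(x)
}

#' Convert a linkage tree to an `hclust` object
#'
#' Enables the standard dendrogram toolchain (`plot()`, `stats::cutree()`
#' for monotone trees, export via \pkg{ape}).
#'
#' @param x A `linkage_tree`.
#' @param ... Unused.
#' @return An object of class `hclust`.
#' @export
as.hclust.linkage_tree <- function(x, ...) {
  n1 <- nrow(x$merges)
  order_of <- function(code) {
    if (code < 0) return(-code)
    c(order_of(x$merges[code, 1]), order_of(x$merges[code, 2]))
  }
  structure(list(merge = x$merges, height = x$heights,
                 order = order_of(n1), labels = x$leaf_ids,
                 method = x$method, dist.method = x$metric),
            class = "hclust")
}

#' Export a dendrogram in Newick format
#'
#' Writes the linkage tree as a Newick string with branch lengths derived
#' from merge heights, readable by any phylogenetics viewer.
#'
#' @param tree A `linkage_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_newick <- function(tree, path) {
  stopifnot(inherits(tree, "linkage_tree"))
  phy <- ape::as.phylo(stats::as.hclust(tree))
  ape::write.tree(phy, file = path)
  invisible(path)
}
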