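dm_from_matrix <- function(d, traj = NULL, metric = "pearson") {
  n <- nrow(d)
  if (is.null(traj)) {
    traj <- matrix(rnorm(n * 8), n, 8)
    rownames(traj) <- rownames(d)
  }
  structure(list(ids = rownames(d), d = d, metric = metric,
                 transform = "linear", trajectories = traj, floor = 1e-4,
                 timepoints = seq_len(ncol(traj)) - 1),
            class = "trajectory_dist")
}

test_that("UPGMA reproduces the hand-executed three-leaf merge history", {
  d <- matrix(c(0, 1, 4,
                1, 0, 4,
                4, 4, 0), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- linkage(dm_from_matrix(d), "upgma")
  expect_equal(tree$heights, c(1, 4))
  expect_equal(tree$merges[1, ], c(-2, -1))
  expect_equal(tree$merges[2, ], c(-3, 1))
  expect_equal(tree$sizes, c(2L, 3L))

  # cut between the merges separates {A,B} from {C}
  asg <- cut_linkage(tree, 2)
  expect_equal(unname(asg[c("A", "B", "C")]), c("A", "A", "C"))
})

test_that("two leaves merge once at their distance", {
  d <- matrix(c(0, 0.7, 0.7, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  tree <- linkage(dm_from_matrix(d), "upgma")
  expect_equal(tree$heights, 0.7)
})

test_that("UPGMA merge heights equal the naive O(n^3) oracle", {
  set.seed(20)
  for (i in 1:40) {
    n <- sample(3:8, 1)
    d <- random_dist(n)
    tree <- linkage(dm_from_matrix(d), "upgma")
    expect_equal(tree$heights, naive_upgma_heights(d), tolerance = 1e-12)
  }
})

test_that("UPGMA agrees with stats::hclust average linkage", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    d <- random_dist(n)
    tree <- linkage(dm_from_matrix(d), "upgma")
    ref <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(tree$heights, ref$height, tolerance = 1e-12)
  }
})

test_that("UPGMA heights are monotone and tie-breaking is by member ID", {
  set.seed(22)
  for (i in 1:20) {
    d <- random_dist(sample(4:9, 1))
    tree <- linkage(dm_from_matrix(d), "upgma")
    expect_true(all(diff(tree$heights) >= -1e-12))
  }
  # all-equal distances: first merge must involve the two smallest IDs
  d <- matrix(1, 4, 4); diag(d) <- 0
  dimnames(d) <- list(c("d", "c", "b", "a"), c("d", "c", "b", "a"))
  tree <- linkage(dm_from_matrix(d), "upgma")
  first <- sort(-tree$merges[1, tree$merges[1, ] < 0])
  expect_setequal(tree$leaf_ids[first], c("a", "b"))
})

test_that("UPGMC merges by centroid distance computed in trajectory space", {
  # three trajectories: two nearly parallel (high correlation), one opposite
  traj <- rbind(a = c(1, 2, 3, 4), b = c(1.1, 2, 3.2, 4), c = c(4, 3, 2, 1))
  d <- 1 - stats::cor(t(traj))
  dimnames(d) <- list(rownames(traj), rownames(traj))
  tree <- linkage(dm_from_matrix(d, traj, metric = "pearson"), "upgmc")
  expect_equal(tree$merges[1, ], c(-2, -1))
  # second height = pearson distance between centroid(a,b) and c
  cent <- colMeans(traj[c("a", "b"), ])
  expect_equal(tree$heights[2], 1 - stats::cor(cent, traj["c", ]),
               tolerance = 1e-12)
})

test_that("NaN distances are refused", {
  d <- random_dist(4); d[2, 3] <- d[3, 2] <- NaN
  expect_error(linkage(dm_from_matrix(d)), "NA")
})

test_that("cuts respect the dendrogram refinement order", {
  set.seed(23)
  d <- random_dist(10)
  tree <- linkage(dm_from_matrix(d), "upgma")
  heights <- c(0, sort(tree$heights) + 1e-9)
  prev <- NULL
  for (h in heights) {
    asg <- cut_linkage(tree, h)
    if (!is.null(prev)) {
      # every finer cluster must sit inside one coarser cluster
      tab <- table(prev, asg)
      expect_true(all(colSums(tab > 0) >= 1))
      for (cl in unique(prev)) {
        expect_lte(length(unique(asg[prev == cl])), 1)
      }
    }
    prev <- asg
  }
  expect_equal(length(unique(cut_linkage(tree, 0))), 10)
  expect_equal(length(unique(cut_linkage(tree, max(tree$heights)))), 1)
})

test_that("threshold sweep endpoints and monotonicity hold", {
  set.seed(24)
  d <- random_dist(12)
  dm <- dm_from_matrix(d)
  tree <- linkage(dm, "upgma")
  q <- quantify_thresholds(tree, dm, grid_size = 50)
  expect_equal(q$n_clusters[1], 12)
  expect_equal(q$n_clusters[50], 1)
  expect_true(all(diff(q$n_clusters) <= 0))
  expect_true(is.na(q$centroid_separation[50]))
  q2 <- quantify_thresholds(tree, dm, grid_size = 2)
  expect_equal(q2$n_clusters, c(12L, 1L))
})

test_that("two well-separated families give a plateau at two clusters", {
  set.seed(25)
  t0 <- seq(0, 1, length.out = 12)
  fam1 <- t(sapply(1:6, function(i) t0 * 2 + rnorm(12, 0, 0.02)))
  fam2 <- t(sapply(1:6, function(i) sin(t0 * 6) + rnorm(12, 0, 0.02)))
  traj <- rbind(fam1, fam2)
  rownames(traj) <- sprintf("m%02d", 1:12)
  d <- 1 - stats::cor(t(traj)); diag(d) <- 0
  dm <- dm_from_matrix(pmax(d, 0), traj)
  tree <- linkage(dm, "upgma")
  q <- quantify_thresholds(tree, dm, grid_size = 100)
  # the 2-cluster plateau spans the gap between within- and between-family
  # merge heights, computable from the linkage itself
  h_within <- tree$heights[10]        # last within-family merge
  h_between <- tree$heights[11]       # the final cross-family merge
  expect_gt(h_between, h_within * 2)
  in_gap <- q$threshold > h_within & q$threshold < h_between
  expect_true(all(q$n_clusters[in_gap] == 2))
  # silhouette-based selection lands in that gap
  h <- select_threshold(q, "silhouette")
  expect_true(h > h_within && h < h_between)
})

test_that("threshold heuristics return grid points", {
  set.seed(26)
  d <- random_dist(8)
  dm <- dm_from_matrix(d)
  tree <- linkage(dm, "upgma")
  q <- quantify_thresholds(tree, dm, 40)
  for (m in c("silhouette", "knee", "plateau")) {
    expect_true(select_threshold(q, m) %in% q$threshold)
  }
})

test_that("LOESS consensus reproduces constants, lines and symmetric pairs", {
  tp <- 0:10
  const <- loess_consensus(matrix(3.5, 4, 11), tp, span = 1, degree = 1)
  expect_equal(const, rep(3.5, 11), tolerance = 1e-9)

  line <- 2 + 0.5 * tp
  single <- loess_consensus(matrix(line, 1), tp, span = 1, degree = 1)
  expect_equal(single, line, tolerance = 1e-9)

  centre <- sin(tp / 3)
  pair <- rbind(centre + 0.4, centre - 0.4)
  cons <- loess_consensus(pair, tp, span = 0.75, degree = 2)
  expect_equal(cons, centre, tolerance = 0.05)
})

test_that("LOESS consensus falls back to the pointwise mean when degenerate", {
  m <- matrix(c(1, 2), 1, 2)
  expect_warning(cons <- loess_consensus(m, c(0, 1), span = 0.5, degree = 2),
                 "pointwise mean")
  expect_equal(cons, c(1, 2))
})

test_that("clonal clusters are ranked by final abundance with C1 first", {
  freqs <- rbind(a1 = c(0.10, 0.30), a2 = c(0.12, 0.40),
                 b1 = c(0.50, 0.20), b2 = c(0.28, 0.10))
  fm <- frequency_matrix(freqs, c(0, 1), floor = 1e-4)
  traj <- rbind(a1 = c(0, 1), a2 = c(0, 1.1), b1 = c(1, 0), b2 = c(1.1, 0))
  d <- rbind(c(0, .01, 1.9, 1.9), c(.01, 0, 1.9, 1.9),
             c(1.9, 1.9, 0, .01), c(1.9, 1.9, .01, 0))
  dimnames(d) <- list(rownames(freqs), rownames(freqs))
  dm <- dm_from_matrix(d, traj)
  tree <- linkage(dm, "upgma")
  ccs <- call_clonal_clusters(fm, dm, tree, height = 0.5,
                              min_cluster_frequency = 0.15)
  expect_equal(ccs$clusters$label, c("C1", "C2"))
  expect_equal(ccs$clusters$final_frequency, c(0.7, 0.3))
  expect_equal(unname(ccs$assignment[c("a1", "a2")]), c("C1", "C1"))
  expect_equal(unname(ccs$assignment[c("b1", "b2")]), c("C2", "C2"))
  expect_equal(ccs$clusters$minor, c(FALSE, FALSE))
  # every barcode appears exactly once and ranks are a permutation
  expect_setequal(names(ccs$assignment), rownames(freqs))
  expect_equal(sort(ccs$clusters$label), paste0("C", 1:2))
})

test_that("equal final frequencies break ties by smallest member ID", {
  freqs <- rbind(zz = c(0.5, 0.5), aa = c(0.5, 0.5))
  fm <- frequency_matrix(freqs, c(0, 1), floor = 1e-4)
  traj <- rbind(zz = c(0, 1), aa = c(1, 0))
  d <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("zz", "aa"), c("zz", "aa")))
  dm <- dm_from_matrix(d, traj)
  tree <- linkage(dm, "upgma")
  ccs <- suppressWarnings(call_clonal_clusters(fm, dm, tree, height = 0))
  expect_equal(ccs$clusters$smallest_member[ccs$clusters$label == "C1"], "aa")
})

test_that("minor clusters are flagged, never dropped", {
  freqs <- rbind(big = c(0.5, 0.9), tiny = c(0.5, 0.005))
  fm <- frequency_matrix(freqs, c(0, 1), floor = 1e-4,
                         subset_of_population = TRUE)
  traj <- rbind(big = c(0, 1), tiny = c(1, 0))
  d <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("big", "tiny"), c("big", "tiny")))
  dm <- dm_from_matrix(d, traj)
  tree <- linkage(dm, "upgma")
  ccs <- suppressWarnings(call_clonal_clusters(fm, dm, tree, height = 0))
  expect_equal(nrow(ccs$clusters), 2)
  expect_equal(ccs$clusters$minor, c(FALSE, TRUE))
})

test_that("log-scale consensus is reported on the frequency scale, floored", {
  fm <- frequency_matrix(rbind(a = c(0.01, 0.0001, 0.1),
                               b = c(0.012, 0.00008, 0.11)),
                         c(0, 1, 2), floor = 1e-3,
                         subset_of_population = TRUE)
  dm <- build_distance_matrix(fm, metric = "dtw", transform = "log10_floored")
  tree <- linkage(dm, "upgma")
  ccs <- call_clonal_clusters(fm, dm, tree, height = max(tree$heights))
  expect_true(all(ccs$consensus >= fm$floor - 1e-12))
  expect_equal(dim(ccs$consensus), c(1L, 3L))
})

test_that("newick export writes a tree readable by ape", {
  set.seed(27)
  d <- random_dist(6)
  tree <- linkage(dm_from_matrix(d), "upgma")
  path <- withr::local_tempfile(fileext = ".nwk")
  export_newick(tree, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, rownames(d))
})
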