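#' Distributions of fitness effects for de novo mutations
#'
#' Beneficial-mutation supply for the simulator: selection coefficients are
#' drawn from an exponential distribution (the classic extreme-value
#' expectation for beneficial effects), fixed at a single value, or absent.
#'
#' @param mean Mean selection coefficient of the exponential.
#' @param s Fixed selection coefficient.
#' @return A `dfe` specification list.
#' @export
dfe_exponential <- function(mean) {
  stopifnot(mean > 0)
  structure(list(kind = "exponential", mean = mean), class = "dfe")
}

#' @rdname dfe_exponential
#' @export
dfe_fixed <- function(s) {
  stopifnot(s >= 0)
  structure(list(kind = "fixed", s = s), class = "dfe")
}

#' @rdname dfe_exponential
#' @export
dfe_none <- function() structure(list(kind = "none"), class = "dfe")

.draw_s <- function(dfe, n) {
  switch(dfe$kind,
         exponential = stats::rexp(n, rate = 1 / dfe$mean),
         fixed = rep(dfe$s, n),
         none = numeric(0))
}

#' Wright-Fisher simulation configuration
#'
#' Parameters of a forward simulation of a constant-size, asexually
#' reproducing barcoded population: every generation, lineage cell counts
#' are resampled multinomially with probabilities proportional to
#' `n_i * w_i` (fitness-weighted Wright-Fisher reproduction), and new
#' beneficial mutations arise at rate `mutation_rate` per cell per
#' generation, each founding a sub-lineage that carries its parent's barcode
#' — sequencing reads only the barcode, so sub-lineage structure must be
#' inferred from trajectory dynamics. Fitness is multiplicative across the
#' population and additive within a genome: `w = 1 + sum(s)`.
#'
#' @param N Population size (cells), constant.
#' @param n_barcodes Number of distinct founding barcodes; cells are split
#'   as evenly as possible among them at generation 0.
#' @param n_generations Number of generations to evolve.
#' @param mutation_rate Beneficial mutation rate per cell per generation.
#' @param dfe Distribution of selection coefficients, see
#'   [dfe_exponential()].
#' @param sampling_times Increasing integer generations (within
#'   `[0, n_generations]`) at which barcode read counts are recorded.
#' @param reads_per_sample Sequencing depth: reads drawn multinomially from
#'   barcode frequencies at each sampling time.
#' @param seed Optional integer seed; a fixed seed gives a bit-identical
#'   result.
#' @param founder_fitness Optional numeric vector (length `n_barcodes`) of
#'   founder fitness values `w` (default all 1), for benchmark scenarios
#'   with pre-existing fitness classes.
#' @param initial_cells Optional integer vector (length `n_barcodes`,
#'   summing to `N`) of founding cell counts per barcode, for the uneven
#'   barcode libraries real experiments start from; default as even as
#'   possible.
#' @param fitness_events Optional data frame with columns `barcode`
#'   (founder index), `generation`, `s`: programmed fitness increments
#'   applied to every cell of the barcode at the start of that generation.
#'   A deterministic device for constructing benchmark scenarios with known
#'   trajectory shapes; recorded in the truth output like any mutation.
#' @return A `sim_config` object.
#' @export
simulation_config <- function(N, n_barcodes, n_generations,
                              mutation_rate = 0, dfe = dfe_none(),
                              sampling_times, reads_per_sample,
                              seed = NULL, founder_fitness = NULL,
                              fitness_events = NULL, initial_cells = NULL) {
  stopifnot(N >= 1, n_barcodes >= 1, n_barcodes <= N, n_generations >= 1,
            mutation_rate >= 0, inherits(dfe, "dfe"), reads_per_sample >= 1)
  sampling_times <- as.integer(sampling_times)
  stopifnot(all(sampling_times >= 0), all(sampling_times <= n_generations),
            all(diff(sampling_times) > 0))
  if (!is.null(founder_fitness))
    stopifnot(length(founder_fitness) == n_barcodes, all(founder_fitness > 0))
  if (!is.null(initial_cells)) {
    initial_cells <- as.integer(initial_cells)
    stopifnot(length(initial_cells) == n_barcodes, all(initial_cells >= 1),
              sum(initial_cells) == N)
  }
  if (!is.null(fitness_events)) {
    stopifnot(is.data.frame(fitness_events),
              all(c("barcode", "generation", "s") %in% names(fitness_events)),
              all(fitness_events$barcode %in% seq_len(n_barcodes)),
              all(fitness_events$generation >= 1),
              all(fitness_events$generation <= n_generations))
  }
  structure(list(N = N, n_barcodes = as.integer(n_barcodes),
                 n_generations = as.integer(n_generations),
                 mutation_rate = mutation_rate, dfe = dfe,
                 sampling_times = sampling_times,
                 reads_per_sample = reads_per_sample, seed = seed,
                 founder_fitness = founder_fitness,
                 fitness_events = fitness_events,
                 initial_cells = initial_cells),
            class = "sim_config")
}

#' Simulate a barcoded population forward in time
#'
#' Runs the Wright-Fisher dynamics described in [simulation_config()]:
#' per generation (i) programmed fitness events are applied, (ii) the next
#' generation's lineage cell counts are drawn from
#' `Multinomial(N, n_i w_i / sum_j n_j w_j)`, (iii) each lineage acquires
#' `Poisson(mutation_rate * n_i)` new beneficial mutations, each moving one
#' cell into a new sub-lineage with `w + s`, and (iv) at sampling times a
#' single multinomial read sample of depth `reads_per_sample` is drawn from
#' the barcode cell frequencies (no PCR artifact model). When the population
#' becomes monomorphic and no further mutation is possible the remaining
#' generations are filled in deterministically.
#'
#' @param config A [simulation_config()].
#' @return An object of class `sim_result`: list with
#'   \describe{
#'     \item{observed}{a [barcode_timeseries()] of sampled read counts}
#'     \item{truth}{list with `mutations` (data frame: barcode, generation,
#'       s, programmed flag), `founder_fitness`, `fate` per barcode
#'       (`fixed` / `extinct` / `segregating`), `cell_counts` and
#'       `mean_fitness` (barcode x sampling time; cell-weighted mean `w`,
#'       `NA` where extinct), and `pop_mean_fitness` per sampling time}
#'     \item{config}{the input configuration}
#'   }
#' @export
simulate_barcoded_evolution <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  N <- config$N
  nb <- config$n_barcodes
  ids <- sprintf("BC%0*d", max(4, nchar(nb)), seq_len(nb))
  st <- config$sampling_times
  nt <- length(st)

  # lineage state: barcode index, fitness, cell count
  lin_bc <- seq_len(nb)
  lin_w <- if (is.null(config$founder_fitness)) rep(1, nb) else
    as.numeric(config$founder_fitness)
  lin_n <- if (is.null(config$initial_cells)) {
    base <- N %/% nb
    rep(base, nb) + c(rep(1, N %% nb), rep(0, nb - N %% nb))
  } else {
    as.numeric(config$initial_cells)
  }

  counts <- matrix(0, nb, nt, dimnames = list(ids, as.character(st)))
  cell_counts <- matrix(0, nb, nt, dimnames = list(ids, as.character(st)))
  mean_fitness <- matrix(NA_real_, nb, nt, dimnames = list(ids, as.character(st)))
  pop_mean_fitness <- numeric(nt)
  mut_bc <- integer(0); mut_gen <- integer(0); mut_s <- numeric(0)
  mut_prog <- logical(0)

  ev <- config$fitness_events
  record <- function(s_idx) {
    cells <- rowsum(lin_n, lin_bc)
    bc_here <- as.integer(rownames(cells))
    cell_counts[bc_here, s_idx] <<- cells[, 1]
    wsum <- rowsum(lin_n * lin_w, lin_bc)
    mean_fitness[bc_here[cells[, 1] > 0], s_idx] <<-
      (wsum[, 1] / cells[, 1])[cells[, 1] > 0]
    pop_mean_fitness[s_idx] <<- sum(lin_n * lin_w) / N
    reads <- stats::rmultinom(1, config$reads_per_sample, lin_n / N)[, 1]
    rd <- rowsum(reads, lin_bc)
    counts[as.integer(rownames(rd)), s_idx] <<- rd[, 1]
  }
  if (0L %in% st) record(match(0L, st))

  can_mutate <- config$mutation_rate > 0 && config$dfe$kind != "none"
  for (g in seq_len(config$n_generations)) {
    if (!is.null(ev)) {
      here <- ev[ev$generation == g, , drop = FALSE]
      for (r in seq_len(nrow(here))) {
        hit <- lin_bc == here$barcode[r]
        if (any(hit)) {
          lin_w[hit] <- lin_w[hit] + here$s[r]
          mut_bc <- c(mut_bc, here$barcode[r])
          mut_gen <- c(mut_gen, g); mut_s <- c(mut_s, here$s[r])
          mut_prog <- c(mut_prog, TRUE)
        }
      }
    }
    # selection + drift
    p <- lin_n * lin_w
    lin_n <- stats::rmultinom(1, N, p)[, 1]
    alive <- lin_n > 0
    if (!all(alive)) {
      lin_bc <- lin_bc[alive]; lin_w <- lin_w[alive]; lin_n <- lin_n[alive]
    }
    # de novo beneficial mutations
    if (can_mutate) {
      m <- stats::rpois(length(lin_n), config$mutation_rate * lin_n)
      m <- pmin(m, lin_n)
      hit <- which(m > 0)
      if (length(hit)) {
        tot <- sum(m[hit])
        s_new <- .draw_s(config$dfe, tot)
        parent <- rep(hit, m[hit])
        lin_n[hit] <- lin_n[hit] - m[hit]
        lin_bc <- c(lin_bc, lin_bc[parent])
        lin_w <- c(lin_w, lin_w[parent] + s_new)
        lin_n <- c(lin_n, rep(1, tot))
        keep <- lin_n > 0
        mut_bc <- c(mut_bc, lin_bc[parent]); mut_gen <- c(mut_gen, rep(g, tot))
        mut_s <- c(mut_s, s_new); mut_prog <- c(mut_prog, rep(FALSE, tot))
        if (!all(keep)) {
          lin_bc <- lin_bc[keep]; lin_w <- lin_w[keep]; lin_n <- lin_n[keep]
        }
      }
    }
    s_idx <- match(g, st)
    if (!is.na(s_idx)) record(s_idx)
    # absorbing state: monomorphic and nothing left to happen
    future_ev <- !is.null(ev) && any(ev$generation > g)
    if (length(lin_n) == 1 && !can_mutate && !future_ev) {
      for (s_idx in which(st > g)) record(s_idx)
      break
    }
  }

  end_cells <- numeric(nb)
  cc <- rowsum(lin_n, lin_bc)
  end_cells[as.integer(rownames(cc))] <- cc[, 1]
  fate <- ifelse(end_cells == N, "fixed",
                 ifelse(end_cells == 0, "extinct", "segregating"))
  truth <- list(
    mutations = data.frame(barcode = ids[mut_bc], generation = mut_gen,
                           s = mut_s, programmed = mut_prog,
                           stringsAsFactors = FALSE),
    founder_fitness = stats::setNames(
      if (is.null(config$founder_fitness)) rep(1, nb) else
        as.numeric(config$founder_fitness), ids),
    fate = stats::setNames(fate, ids),
    cell_counts = cell_counts,
    mean_fitness = mean_fitness,
    pop_mean_fitness = stats::setNames(pop_mean_fitness, as.character(st))
  )
  structure(list(observed = barcode_timeseries(counts, st),
                 truth = truth, config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> N=%g, %d barcodes, %d generations, %d sampling times\n",
              x$config$N, x$config$n_barcodes, x$config$n_generations,
              length(x$config$sampling_times)))
  cat("  fates:", paste(names(table(x$truth$fate)), table(x$truth$fate),
                        sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Benchmark scenario configurations
#'
#' Ready-made simulation configurations exercising the regimes the pipeline
#' is validated on. `scale` multiplies the full-scale population size
#' (1e7 cells), barcode count (1e5) and sequencing depth down to desk
#' scale; the run length contracts smoothly with scale
#' (`round(1125 * scale^0.45)` generations, the full 1125 at scale 1) so
#' that trajectory shapes stay resolvable when drift per lineage grows at
#' small population sizes. 17 evenly spaced sampling times are always used.
#'
#' \describe{
#'   \item{neutral}{no mutation, equal founder fitness and cell counts:
#'     pure drift.}
#'   \item{fixation}{a clonal-interference cascade over an uneven founding
#'     library: six groups of high-count barcodes acquire successively
#'     stronger programmed beneficial mutations at staggered times, each
#'     rising and then being overtaken by the next, with the last and
#'     strongest sweeping towards fixation; a large background of
#'     low-count neutral barcodes decays below the noise filters. The six
#'     groups end with distinct, descending population fractions — one
#'     sweeping winner, one late outcompeted riser, and four transient
#'     risers that lost out.}
#'   \item{clonal_interference}{the same cascade truncated before the
#'     sweep resolves, so several beneficial groups still coexist at
#'     comparable frequencies.}
#' }
#'
#' @param name One of `"fixation"`, `"clonal_interference"`, `"neutral"`.
#' @param scale Multiplier in (0, 1] on population size and barcode count.
#' @param seed Optional seed stored in the config.
#' @return A [simulation_config()]. For the cascade scenarios the config
#'   carries a `group_labels` attribute: a named character vector mapping
#'   each barcode ID to its true group (`"G1"`..`"G6"` or `"neutral"`).
#' @export
make_benchmark_scenario <- function(name = c("fixation", "clonal_interference",
                                             "neutral"),
                                    scale = 1, seed = NULL) {
  name <- match.arg(name)
  stopifnot(scale > 0, scale <= 1)
  N <- round(1e7 * scale)
  nb <- max(100L, round(1e5 * scale))
  T_full <- max(34L, round(1125 * scale^0.45))
  depth <- max(1e5, round(1e6 * scale))

  if (name == "neutral") {
    st <- unique(round(seq(0, T_full, length.out = 17)))
    return(simulation_config(N, nb, T_full, mutation_rate = 0,
                             dfe = dfe_none(), sampling_times = st,
                             reads_per_sample = depth, seed = seed))
  }

  # cascade of six programmed beneficial groups: the strongest (G1) arises
  # last, each group rises once its programmed advantage exceeds the
  # current mean fitness and declines once overtaken, giving six trajectory
  # families with dips/peaks at distinct times; founding fractions chosen
  # so the final fractions descend from ~0.37 (G1) to ~0.04 (G6)
  s_ladder <- c(0.16, 0.115, 0.085, 0.063, 0.046, 0.03)
  onset_frac <- c(0.70, 0.55, 0.41, 0.27, 0.15, 0.035)
  group_frac <- c(0.2666, 0.0962, 0.0735, 0.0807, 0.1305, 0.3232)
  g_sz <- max(1L, round(0.004 * nb))      # barcodes per group
  groups <- lapply(seq_len(6), function(i) ((i - 1) * g_sz + 1):(i * g_sz))
  n_neutral <- nb - 6L * g_sz
  # uneven founding library: neutral barcodes start near the detection
  # limit, group barcodes start large enough that drift noise is modest
  neutral_cells <- max(1L, min(round(2e-5 * N),
                               floor(0.4 * N / max(n_neutral, 1L))))
  group_total <- N - n_neutral * neutral_cells
  per_bc <- rep(round(group_frac * group_total / g_sz), each = g_sz)
  cells <- c(per_bc, rep(neutral_cells, n_neutral))
  cells[1] <- cells[1] + (N - sum(cells))

  Tg <- if (name == "fixation") T_full else max(20L, round(0.8 * T_full))
  onsets <- pmax(1L, pmin(as.integer(round(onset_frac * T_full)), Tg))
  ev <- do.call(rbind, lapply(seq_len(6), function(i)
    data.frame(barcode = groups[[i]], generation = onsets[i],
               s = s_ladder[i])))
  st <- unique(round(seq(0, Tg, length.out = 17)))
  cfg <- simulation_config(N, nb, Tg, mutation_rate = 0, dfe = dfe_none(),
                           sampling_times = st, reads_per_sample = depth,
                           seed = seed, fitness_events = ev,
                           initial_cells = cells)
  ids <- sprintf("BC%0*d", max(4, nchar(nb)), seq_len(nb))
  labels <- rep("neutral", nb)
  for (i in seq_len(6)) labels[groups[[i]]] <- paste0("G", i)
  attr(cfg, "group_labels") <- stats::setNames(labels, ids)
  cfg
}

#' Fitness-class benchmark configuration
#'
#' A population whose founding barcodes fall into a few discrete fitness
#' classes, used to test whether trajectory clustering recovers the classes.
#' The default composition mirrors an adapting asexual population: a
#' majority of neutral lineages and successively smaller classes of
#' increasingly beneficial ones, so the beneficial classes rise against a
#' decaying neutral background with distinct trajectory shapes.
#'
#' @param s_classes Selection coefficients of the classes (relative to 1).
#' @param class_sizes Barcodes per class (same length as `s_classes`).
#' @param N Population size.
#' @param n_generations Length of the run.
#' @param n_samples Number of evenly spaced sampling times (including 0).
#' @param reads_per_sample Sequencing depth per sample.
#' @param seed Optional seed.
#' @return A list with `config` (a [simulation_config()]) and
#'   `class_labels` (named character vector: barcode -> class).
#' @export
make_fitness_class_config <- function(s_classes = c(0, 0.05, 0.10),
                                      class_sizes = c(40, 15, 5), N = 1e5,
                                      n_generations = 60, n_samples = 17,
                                      reads_per_sample = 1e6, seed = NULL) {
  stopifnot(length(class_sizes) == length(s_classes), all(class_sizes >= 1))
  nb <- sum(class_sizes)
  founder <- 1 + rep(s_classes, times = class_sizes)
  st <- unique(round(seq(0, n_generations, length.out = n_samples)))
  cfg <- simulation_config(N, nb, n_generations, mutation_rate = 0,
                           dfe = dfe_none(), sampling_times = st,
                           reads_per_sample = reads_per_sample, seed = seed,
                           founder_fitness = founder)
  ids <- sprintf("BC%0*d", max(4, nchar(nb)), seq_len(nb))
  labels <- stats::setNames(paste0("s=", rep(s_classes, times = class_sizes)), ids)
  list(config = cfg, class_labels = labels)
}

#' Evaluate cluster recovery against simulation ground truth
#'
#' Compares a clustering of the observed barcode trajectories with the true
#' lineage labels from the simulation, via the Adjusted Rand Index (chance-
#' corrected agreement between partitions), and summarises the true fitness
#' of each cluster's members over time — the cluster-versus-fitness
#' comparison used to validate the pipeline.
#'
#' @param result A [simulate_barcoded_evolution()] result.
#' @param assignment Named vector mapping barcode IDs to cluster labels
#'   (e.g. the `assignment` field of [call_clonal_clusters()]); must be a
#'   subset of the simulated barcodes.
#' @param truth_labels Optional named vector of true labels per barcode.
#'   Default: the founder fitness class when founders are heterogeneous,
#'   otherwise the lineage fate (`fixed`/`extinct`/`segregating`).
#' @return A list with `ari`, `n_barcodes`, `truth_labels` (restricted), and
#'   `cluster_fitness`, a data frame of cell-weighted mean true fitness per
#'   cluster per sampling time.
#' @export
evaluate_recovery <- function(result, assignment, truth_labels = NULL) {
  stopifnot(inherits(result, "sim_result"))
  ids <- names(assignment)
  if (is.null(ids) || !all(ids %in% result$observed$ids))
    stop("assignment names must be simulated barcode IDs", call. = FALSE)
  if (is.null(truth_labels)) {
    ff <- result$truth$founder_fitness
    truth_labels <- if (length(unique(ff)) > 1) {
      stats::setNames(paste0("w=", signif(ff, 6)), names(ff))
    } else {
      result$truth$fate
    }
  }
  truth_labels <- truth_labels[ids]
  ari <- mclust::adjustedRandIndex(as.character(assignment),
                                   as.character(truth_labels))
  st <- colnames(result$truth$mean_fitness)
  cf <- do.call(rbind, lapply(split(ids, assignment), function(g) {
    w <- result$truth$mean_fitness[g, , drop = FALSE]
    n <- result$truth$cell_counts[g, , drop = FALSE]
    wn <- colSums(ifelse(is.na(w), 0, w) * n)
    nn <- colSums(n)
    data.frame(cluster = assignment[g[1]], time = as.numeric(st),
               mean_fitness = ifelse(nn > 0, wn / nn, NA_real_),
               n_cells = nn, row.names = NULL, stringsAsFactors = FALSE)
  }))
  rownames(cf) <- NULL
  list(ari = ari, n_barcodes = length(ids), truth_labels = truth_labels,
       cluster_fitness = cf)
}

#' Best-cut cluster recovery over a height grid
#'
#' Sweeps dendrogram cut heights and reports the Adjusted Rand Index of each
#' resulting partition against true labels; useful to ask whether *any* cut
#' recovers the true classes.
#'
#' @param tree A [linkage()] result.
#' @param truth_labels Named vector of true labels covering the tree leaves.
#' @param grid_size Number of evenly spaced heights. Default 100.
#' @return Data frame with columns `threshold`, `n_clusters`, `ari`.
#' @export
ari_over_cuts <- function(tree, truth_labels, grid_size = 100) {
  stopifnot(inherits(tree, "linkage_tree"))
  if (!all(tree$leaf_ids %in% names(truth_labels)))
    stop("truth_labels must cover every leaf ID", call. = FALSE)
  truth <- as.character(truth_labels[tree$leaf_ids])
  grid <- seq(0, max(tree$heights), length.out = grid_size)
  rows <- lapply(grid, function(h) {
    asg <- cut_linkage(tree, h)
    data.frame(threshold = h, n_clusters = length(unique(asg)),
               ari = mclust::adjustedRandIndex(as.character(asg), truth))
  })
  do.call(rbind, rows)
}
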