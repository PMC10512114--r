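# Fixtures and independent oracles, built in code.
#
# Random forests here have randomly generated STRUCTURE (random splits from
# small per-feature threshold pools, random leaf labels) so the discretized
# space stays exhaustively enumerable while the decision functions vary
# wildly; trained forests at full cohort scale are exercised separately.

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_features <- function(p = 5) {
  feature_spec(paste0("f", seq_len(p)), rep("u", p),
               z_mean = rep(0, p), z_sd = rep(1, p))
}

random_tree_node <- function(pools, depth) {
  if (depth == 0L || stats::runif(1) < 0.2)
    return(list(leaf = sample(c("positive", "negative"), 1)))
  f <- sample.int(length(pools), 1)
  list(feature = f, threshold = sample(pools[[f]], 1),
       low = random_tree_node(pools, depth - 1L),
       high = random_tree_node(pools, depth - 1L))
}

# Paper-scale structure (13 trees, depth <= 3, 5 features) over small
# threshold pools; set.seed before calling.
random_forest_fixture <- function(n_trees = 13, max_depth = 3, p = 5,
                                  pool_size = 3) {
  pools <- lapply(seq_len(p), function(i) sort(stats::runif(pool_size, -2, 2)))
  repeat {
    trees <- replicate(n_trees, random_tree_node(pools, max_depth),
                       simplify = FALSE)
    if (!all(vapply(trees, function(t) !is.null(t$leaf), logical(1)))) break
  }
  forest(trees, toy_features(p), max_depth)
}

# All cells of a partition, one per row (linear-index order).
all_cells <- function(partition) {
  as.matrix(expand.grid(lapply(partition$n_intervals, seq_len)))
}

# Independent truth table: forest majority label on every cell, computed by
# routing a representative point through predict_forest (no diagram code).
label_array_slow <- function(forest, partition) {
  cells <- all_cells(partition)
  labs <- vapply(seq_len(nrow(cells)), function(r)
    predict_forest(forest, cell_representative(partition, cells[r, ])) == "positive",
    logical(1))
  array(labs, dim = partition$n_intervals)
}

# Fast independent truth table via direct tree-vote accumulation (shares no
# code with the diagram).
label_array <- function(forest, partition) {
  array(forest_cell_labels(forest, partition), dim = partition$n_intervals)
}

# Oracle sufficiency: every completion of the partial assignment (NA = free)
# has the given label, checked by slicing the truth table.
oracle_sufficient <- function(arr, partial, label) {
  idx <- lapply(seq_along(partial), function(f)
    if (is.na(partial[f])) seq_len(dim(arr)[f]) else partial[f])
  vals <- do.call(`[`, c(list(arr), idx))
  all(vals == (label == "positive"))
}

# Oracle shortest compatible prime implicant: scan all feature subsets in
# increasing size (lexicographic within a size).
oracle_shortest <- function(arr, cell, label) {
  p <- length(cell)
  for (size in 0:p) {
    subsets <- if (size == 0) matrix(integer(0), 0, 1) else utils::combn(p, size)
    for (j in seq_len(ncol(subsets))) {
      s <- subsets[, j]
      partial <- rep(NA_integer_, p); partial[s] <- cell[s]
      if (oracle_sufficient(arr, partial, label))
        return(list(features = s, size = size))
    }
  }
}
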