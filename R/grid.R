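# Full-grid evaluation over every cell of a partition.
#
# Cells are linearized with feature 1 varying fastest (the expand.grid
# convention): linear index = 1 + sum_f (cell_f - 1) * stride_f with
# stride_1 = 1, stride_f = prod(n_intervals[1:(f-1)]). Both evaluators below
# return one value per cell in that order, so exhaustive equivalence between
# a forest and its compiled diagram is a vector comparison. The two routes
# are deliberately independent: forest votes are accumulated straight from
# the tree structures by array expansion, never via the diagram; the diagram
# sweep walks the node table level by level, never via the trees.

#' Per-cell vote counts of a forest, over the whole discretized space
#'
#' For each tree, the tree's label is evaluated once per cell of the tree's
#' own (much coarser) threshold grid and then broadcast to the full grid by
#' index mapping, so the cost is linear in the number of cells.
#'
#' @param forest a `primo_forest`.
#' @param partition a `primo_partition` whose thresholds include all of the
#'   forest's (default: [extract_partition()]).
#' @return Integer vector: positive votes per cell, in linear-index order.
#' @export
forest_cell_votes <- function(forest, partition = NULL) {
  if (is.null(partition)) partition <- extract_partition(forest)
  nv <- partition$n_intervals
  p <- length(nv)
  total <- prod(nv)
  # a strictly-interior representative per full interval, per feature
  reps <- lapply(seq_len(p), function(f)
    vapply(seq_len(nv[f]), function(j)
      cell_representative(partition, replace(rep(1L, p), f, j))[f], numeric(1)))
  votes <- integer(total)
  for (tr in forest$trees) {
    tth <- tree_thresholds(tr, p)
    m <- lengths(tth) + 1L
    # map: full interval index -> tree interval index, per feature
    maps <- lapply(seq_len(p), function(f)
      if (length(tth[[f]])) findInterval(reps[[f]], tth[[f]]) + 1L
      else rep(1L, nv[f]))
    # tree labels on its own subgrid
    sub <- as.matrix(expand.grid(lapply(seq_len(p), function(f) {
      subpart_reps(tth[[f]])
    })))
    lab <- array(apply(sub, 1, function(x) predict_tree(tr, x) == "positive"),
                 dim = m)
    votes <- votes + as.integer(do.call(`[`, c(list(lab), maps)))
  }
  votes
}

tree_thresholds <- function(tree, p) {
  th <- lapply(seq_len(p), function(i) numeric(0))
  rec <- function(node) {
    if (is_leaf(node)) return(invisible(NULL))
    th[[node$feature]] <<- c(th[[node$feature]], node$threshold)
    rec(node$low); rec(node$high)
  }
  rec(tree)
  lapply(th, function(v) sort(unique(v)))
}

subpart_reps <- function(th) {
  if (!length(th)) return(0)
  c(th[1] - 1, if (length(th) > 1) (th[-length(th)] + th[-1]) / 2, th[length(th)] + 1)
}

#' Majority-vote labels per cell
#'
#' @param forest a `primo_forest`.
#' @param partition as in [forest_cell_votes()].
#' @return Logical vector: `TRUE` where a strict majority of trees vote
#'   positive, in linear-index order.
#' @export
forest_cell_labels <- function(forest, partition = NULL) {
  forest_cell_votes(forest, partition) >= floor(forest$n_trees / 2) + 1
}

#' Evaluate a diagram on every cell at once
#'
#' Sweeps the levels of the variable order, advancing a vector of current
#' node ids for all cells simultaneously.
#'
#' @param odd a `primo_odd`.
#' @return Logical vector, one value per cell in linear-index order.
#' @export
odd_cell_values <- function(odd) {
  mgr <- odd$mgr
  nv <- mgr$nvals
  total <- prod(nv)
  strides <- cumprod(c(1, nv[-length(nv)]))
  cur <- rep.int(odd$root, total)
  base <- 0:(total - 1)
  for (l in seq_along(mgr$order)) {
    v <- mgr$order[l]
    internal <- which(cur > 2L)
    if (!length(internal)) break
    at_v <- internal[mgr$var[cur[internal]] == v]
    if (!length(at_v)) next
    ids_v <- sort(unique(cur[at_v]))
    kidmat <- do.call(rbind, mgr$kids[ids_v])
    rowmap <- integer(max(ids_v)); rowmap[ids_v] <- seq_along(ids_v)
    idx_v <- (base[at_v] %/% strides[v]) %% nv[v] + 1L
    cur[at_v] <- kidmat[cbind(rowmap[cur[at_v]], idx_v)]
  }
  cur == TRUE_ID
}

#' Exhaustive forest-diagram equivalence check
#'
#' Compares, cell by cell over the entire discretized space, the forest's
#' majority vote (computed straight from the trees) with the compiled
#' diagram's value.
#'
#' @param forest a `primo_forest`.
#' @param odd its compiled `primo_odd`.
#' @return List with `equal` (logical), `n_cells`, and `n_disagreements`.
#' @export
check_equivalence <- function(forest, odd) {
  ref <- forest_cell_labels(forest, odd$mgr$partition)
  got <- odd_cell_values(odd)
  list(equal = identical(ref, got), n_cells = length(ref),
       n_disagreements = sum(ref != got))
}
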