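# Reduced ordered decision diagrams over multi-valued discretized features.
#
# One manager (an environment) owns all nodes for a given (partition, order):
# a unique-node table enforces reduction on construction, so two ODDs in the
# same manager compute the same function iff they have the same root id —
# canonicity is what makes equivalence checks O(1). Terminals are shared:
# id 1 is the 0-terminal ("negative"), id 2 the 1-terminal ("positive").
# Each internal node tests one feature and has one child per interval of that
# feature; along every path features appear according to `order`, each at
# most once; skipped features are don't-cares.

FALSE_ID <- 1L
TRUE_ID <- 2L

#' Create a decision-diagram manager
#'
#' @param partition a `primo_partition` (or an integer vector of per-feature
#'   interval counts for synthetic tests).
#' @param order variable order: a permutation of the feature indices; nodes on
#'   earlier features appear nearer the root. Defaults to the natural feature
#'   order (with only five features, order optimization is unnecessary and a
#'   fixed order keeps compilation deterministic).
#' @return An environment of class `primo_odd_manager`.
#' @export
odd_manager <- function(partition, order = NULL) {
  nvals <- if (inherits(partition, "primo_partition")) partition$n_intervals
           else as.integer(partition)
  if (!inherits(partition, "primo_partition"))
    partition <- partition(lapply(nvals, function(k) seq_len(k - 1L)))
  p <- length(nvals)
  if (is.null(order)) order <- seq_len(p)
  stopifnot(length(order) == p, all(sort(order) == seq_len(p)), all(nvals >= 1))
  mgr <- new.env(parent = emptyenv())
  mgr$nvals <- nvals
  mgr$order <- as.integer(order)
  mgr$pos <- integer(p); mgr$pos[order] <- seq_len(p)   # pos[f] = level of f
  mgr$var <- c(NA_integer_, NA_integer_)                # terminals
  mgr$kids <- list(NULL, NULL)
  mgr$n <- 2L
  mgr$unique <- new.env(parent = emptyenv(), size = 4096L)
  mgr$cache <- new.env(parent = emptyenv(), size = 4096L)
  mgr$partition <- partition
  # suffix products of interval counts by level, for model counting:
  # spx[l] = prod over levels l..p of nvals[order[l..p]]; spx[p + 1] = 1
  mgr$spx <- rev(cumprod(c(1, rev(nvals[order]))))
  class(mgr) <- "primo_odd_manager"
  mgr
}

node_level <- function(mgr, id) {
  if (id <= 2L) length(mgr$order) + 1L else mgr$pos[mgr$var[id]]
}

# Unique-table constructor: enforces reduction (no redundant node, no
# duplicate node) so equal functions get equal ids.
mk_node <- function(mgr, var, kids) {
  if (all(kids == kids[1L])) return(kids[1L])
  key <- paste0(var, "|", paste(kids, collapse = ","))
  id <- mgr$unique[[key]]
  if (!is.null(id)) return(id)
  id <- mgr$n + 1L
  mgr$n <- id
  mgr$var[id] <- var
  mgr$kids[[id]] <- kids
  mgr$unique[[key]] <- id
  id
}

new_odd <- function(mgr, root) structure(list(mgr = mgr, root = root),
                                         class = "primo_odd")

#' Constant diagrams
#' @param mgr a `primo_odd_manager`.
#' @param value logical: `TRUE` for the always-positive function.
#' @return A `primo_odd`.
#' @export
odd_constant <- function(mgr, value) new_odd(mgr, if (value) TRUE_ID else FALSE_ID)

#' @export
print.primo_odd <- function(x, ...) {
  cat("Ordered decision diagram:", odd_size(x), "internal node(s),",
      "model count", model_count(x), "of", prod(x$mgr$nvals), "cells\n")
  invisible(x)
}

#' Number of internal nodes reachable from the root
#' @param odd a `primo_odd`.
#' @return Integer count (0 for a constant diagram).
#' @export
odd_size <- function(odd) {
  seen <- new.env(parent = emptyenv())
  walk <- function(id) {
    if (id <= 2L) return(invisible(NULL))
    key <- as.character(id)
    if (!is.null(seen[[key]])) return(invisible(NULL))
    seen[[key]] <- TRUE
    for (k in odd$mgr$kids[[id]]) walk(k)
  }
  walk(odd$root)
  length(ls(seen))
}

same_manager <- function(a, b) identical(a$mgr, b$mgr)

check_operands <- function(a, b) {
  if (!same_manager(a, b)) {
    if (!identical(a$mgr$nvals, b$mgr$nvals) || !identical(a$mgr$order, b$mgr$order))
      stop("operands have mismatched variable orders or partitions")
    b <- new_odd(a$mgr, migrate(a$mgr, b$mgr, b$root))
  }
  b
}

migrate <- function(to, from, id) {
  if (id <= 2L) return(id)
  mk_node(to, from$var[id],
          vapply(from$kids[[id]], function(k) migrate(to, from, k), integer(1)))
}

#' Pointwise Boolean combination of diagrams
#'
#' Standard memoized pairwise apply: expands the top variable of the operands
#' and recurses on the children, so the cost is bounded by the product of the
#' operand sizes. Operands must share the manager's partition and variable
#' order.
#'
#' @param op one of `"and"`, `"or"`, `"xor"`.
#' @param a,b `primo_odd` operands.
#' @return A `primo_odd` computing the pointwise combination.
#' @export
odd_apply <- function(op, a, b) {
  op <- match.arg(op, c("and", "or", "xor"))
  b <- check_operands(a, b)
  mgr <- a$mgr
  zero <- FALSE_ID; one <- TRUE_ID
  rec <- function(x, y) {
    # terminal shortcuts
    if (op == "and") {
      if (x == zero || y == zero) return(zero)
      if (x == one) return(y)
      if (y == one) return(x)
      if (x == y) return(x)
    } else if (op == "or") {
      if (x == one || y == one) return(one)
      if (x == zero) return(y)
      if (y == zero) return(x)
      if (x == y) return(x)
    } else {
      if (x == y) return(zero)
      if (x == zero) return(y)
      if (y == zero) return(x)
      if (x <= 2L && y <= 2L) return(if (x == y) zero else one)
    }
    key <- if (x < y) paste0(op, "|", x, "|", y) else paste0(op, "|", y, "|", x)
    hit <- mgr$cache[[key]]
    if (!is.null(hit)) return(hit)
    lx <- node_level(mgr, x); ly <- node_level(mgr, y)
    l <- min(lx, ly)
    v <- mgr$order[l]
    nv <- mgr$nvals[v]
    kx <- if (lx == l) mgr$kids[[x]] else rep.int(x, nv)
    ky <- if (ly == l) mgr$kids[[y]] else rep.int(y, nv)
    res <- mk_node(mgr, v, vapply(seq_len(nv),
                                  function(k) rec(kx[k], ky[k]), integer(1)))
    mgr$cache[[key]] <- res
    res
  }
  new_odd(mgr, rec(a$root, b$root))
}

#' @rdname odd_apply
#' @export
odd_and <- function(a, b) odd_apply("and", a, b)

#' @rdname odd_apply
#' @export
odd_or <- function(a, b) odd_apply("or", a, b)

#' @rdname odd_apply
#' @export
odd_not <- function(a) {
  mgr <- a$mgr
  rec <- function(id) {
    if (id == FALSE_ID) return(TRUE_ID)
    if (id == TRUE_ID) return(FALSE_ID)
    key <- paste0("not|", id)
    hit <- mgr$cache[[key]]
    if (!is.null(hit)) return(hit)
    res <- mk_node(mgr, mgr$var[id],
                   vapply(mgr$kids[[id]], rec, integer(1)))
    mgr$cache[[key]] <- res
    res
  }
  new_odd(mgr, rec(a$root))
}

# Diagram for the single proposition x_f >= t_j (interval index > j).
literal_geq <- function(mgr, feature, threshold_index) {
  nv <- mgr$nvals[feature]
  j <- threshold_index
  mk_node(mgr, feature, c(rep.int(FALSE_ID, j), rep.int(TRUE_ID, nv - j)))
}

#' Compile a single decision tree into a diagram
#'
#' The propositional formula of a tree's positive label is the disjunction,
#' over paths to positive leaves, of the conjunction of the path's tests
#' `x_i >= t` / `x_i < t`; each test maps to the set of interval values at or
#' above / below `t`. Compilation proceeds by if-then-else over these
#' literals, so the result is the reduced canonical diagram that is true on
#' exactly the cells the tree routes to a positive leaf.
#'
#' @param tree a tree root node (see [forest()]).
#' @param partition a `primo_partition` containing every threshold of the tree.
#' @param order optional variable order (see [odd_manager()]).
#' @param manager an existing manager to build into (overrides
#'   `partition`/`order`).
#' @return A `primo_odd`.
#' @export
compile_tree <- function(tree, partition, order = NULL, manager = NULL) {
  mgr <- if (is.null(manager)) odd_manager(partition, order) else manager
  new_odd(mgr, compile_tree_root(tree, mgr))
}

compile_tree_root <- function(tree, mgr) {
  part <- mgr$partition
  rec <- function(node) {
    if (is_leaf(node))
      return(if (node$leaf == "positive") TRUE_ID else FALSE_ID)
    j <- match(node$threshold, part$thresholds[[node$feature]])
    if (is.na(j))
      stop("internal consistency error: threshold ", node$threshold,
           " of feature ", node$feature, " is absent from the partition")
    ge <- new_odd(mgr, literal_geq(mgr, node$feature, j))
    hi <- new_odd(mgr, rec(node$high))
    lo <- new_odd(mgr, rec(node$low))
    odd_or(odd_and(ge, hi), odd_and(odd_not(ge), lo))$root
  }
  rec(tree)
}

#' Compile a forest's majority vote into a diagram
#'
#' Builds the diagram that is true on exactly the cells where a strict
#' majority (`>= floor(n_trees/2) + 1`) of the trees vote positive. The
#' majority gate is realized by dynamic programming over the trees: a layer
#' of diagrams tracks "at least c positive votes among the first k trees"
#' (the vote-count diagram), and only counts that can still reach or still
#' miss the majority threshold are kept. This is polynomial in the number of
#' trees, unlike expanding the majority gate into all majority subsets.
#'
#' @param forest a `primo_forest`.
#' @param partition a `primo_partition`; defaults to
#'   [extract_partition()] of the forest.
#' @param order optional variable order.
#' @return A `primo_odd` equivalent to [predict_forest()] on every cell.
#' @export
compile_forest <- function(forest, partition = NULL, order = NULL) {
  stopifnot(inherits(forest, "primo_forest"))
  if (is.null(partition)) partition <- extract_partition(forest)
  mgr <- odd_manager(partition, order)
  n <- forest$n_trees
  need <- floor(n / 2) + 1          # votes needed for "positive"
  # atleast[[c + 1]] = diagram of "at least c positive votes so far"
  atleast <- vector("list", need + 1L)
  atleast[[1L]] <- odd_constant(mgr, TRUE)           # at least 0: always
  for (c in seq_len(need)) atleast[[c + 1L]] <- odd_constant(mgr, FALSE)
  for (k in seq_len(n)) {
    tk <- new_odd(mgr, compile_tree_root(forest$trees[[k]], mgr))
    ntk <- odd_not(tk)
    # highest count worth tracking after k trees is min(k, need);
    # update top-down so atleast[[c]] still holds the k-1 value when used
    for (c in seq(min(k, need), 1L)) {
      atleast[[c + 1L]] <- odd_or(odd_and(tk, atleast[[c]]),
                                  odd_and(ntk, atleast[[c + 1L]]))
    }
  }
  atleast[[need + 1L]]
}

#' Evaluate a diagram on a cell
#'
#' Follows, at each node, the child for the cell's interval index on that
#' node's feature; features not tested along the way are don't-cares.
#'
#' @param odd a `primo_odd`.
#' @param cell integer vector of interval indices (one per feature).
#' @return `"positive"` or `"negative"`.
#' @export
odd_evaluate <- function(odd, cell) {
  mgr <- odd$mgr
  if (length(cell) != length(mgr$nvals)) stop("cell has wrong length")
  if (any(cell < 1L) || any(cell > mgr$nvals)) stop("cell index out of range")
  id <- odd$root
  while (id > 2L) id <- mgr$kids[[id]][cell[mgr$var[id]]]
  if (id == TRUE_ID) "positive" else "negative"
}

#' Count the cells a diagram maps to 1
#'
#' Single bottom-up pass; a feature skipped between a node and its child
#' contributes a factor of its interval count.
#'
#' @param odd a `primo_odd`.
#' @return The number of cells (as a double; exact for the sizes at hand).
#' @export
model_count <- function(odd) {
  mgr <- odd$mgr
  spx <- mgr$spx
  memo <- new.env(parent = emptyenv())
  # completions over levels >= level(id)
  cnt <- function(id) {
    if (id == FALSE_ID) return(0)
    if (id == TRUE_ID) return(1)
    key <- as.character(id)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    l <- node_level(mgr, id)
    tot <- 0
    for (k in mgr$kids[[id]]) {
      lk <- node_level(mgr, k)
      tot <- tot + cnt(k) * spx[l + 1L] / spx[lk]
    }
    memo[[key]] <- tot
    tot
  }
  lr <- node_level(mgr, odd$root)
  cnt(odd$root) * spx[1L] / spx[lr]
}

#' Restrict a diagram by a partial cell
#'
#' Substitutes the given interval indices for a subset of the features and
#' returns the diagram of the restricted function over the remaining
#' features (in the same manager).
#'
#' @param odd a `primo_odd`.
#' @param partial integer vector with one entry per feature, `NA` for
#'   unassigned features; or a named list/vector of feature index ->
#'   interval index.
#' @return A `primo_odd` not mentioning the assigned features.
#' @export
odd_condition <- function(odd, partial) {
  mgr <- odd$mgr
  partial <- as_partial(mgr, partial)
  memo <- new.env(parent = emptyenv())
  rec <- function(id) {
    if (id <= 2L) return(id)
    key <- as.character(id)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    v <- mgr$var[id]
    res <- if (!is.na(partial[v])) rec(mgr$kids[[id]][partial[v]])
           else mk_node(mgr, v, vapply(mgr$kids[[id]], rec, integer(1)))
    memo[[key]] <- res
    res
  }
  new_odd(mgr, rec(odd$root))
}

# Normalize a partial assignment to an integer vector with NAs.
as_partial <- function(mgr, partial) {
  p <- length(mgr$nvals)
  if (is.list(partial) || !is.null(names(partial))) {
    out <- rep(NA_integer_, p)
    idx <- names(partial)
    if (!is.null(idx)) {
      fi <- suppressWarnings(as.integer(idx))
      if (anyNA(fi) && !is.null(mgr$partition$features))
        fi <- match(idx, mgr$partition$features$name)
      out[fi] <- as.integer(unlist(partial))
    } else stop("partial assignment needs names or a full-length vector")
    partial <- out
  }
  partial <- as.integer(partial)
  stopifnot(length(partial) == p)
  bad <- !is.na(partial) & (partial < 1L | partial > mgr$nvals)
  if (any(bad)) stop("partial assignment interval index out of range")
  partial
}

#' Serialize a diagram as a node list
#'
#' @param odd a `primo_odd`.
#' @return A list with `root`, `terminals`, and `nodes` (each
#'   `{id, feature, children}`), suitable for JSON export; `as_dot` renders
#'   the same structure in Graphviz DOT.
#' @export
odd_node_list <- function(odd) {
  mgr <- odd$mgr
  seen <- new.env(parent = emptyenv())
  nodes <- list()
  walk <- function(id) {
    if (id <= 2L || !is.null(seen[[as.character(id)]])) return(invisible(NULL))
    seen[[as.character(id)]] <- TRUE
    nodes[[length(nodes) + 1L]] <<- list(id = id, feature = mgr$var[id],
                                         children = mgr$kids[[id]])
    for (k in mgr$kids[[id]]) walk(k)
  }
  walk(odd$root)
  list(root = odd$root, terminals = list(`0` = FALSE_ID, `1` = TRUE_ID),
       nodes = nodes)
}

#' @rdname odd_node_list
#' @export
as_dot <- function(odd) {
  nl <- odd_node_list(odd)
  nm <- if (!is.null(odd$mgr$partition$features))
    odd$mgr$partition$features$name else paste0("x", seq_along(odd$mgr$nvals))
  lines <- c("digraph odd {",
             "  node1 [label=\"0\", shape=box];",
             "  node2 [label=\"1\", shape=box];")
  for (nd in nl$nodes) {
    lines <- c(lines, sprintf("  node%d [label=\"%s\"];", nd$id, nm[nd$feature]))
    for (k in seq_along(nd$children))
      lines <- c(lines, sprintf("  node%d -> node%d [label=\"%d\"];",
                                nd$id, nd$children[k], k))
  }
  paste(c(lines, "}"), collapse = "\n")
}
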