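#' Threshold-induced interval partition of the feature space
#'
#' Every threshold appearing anywhere in the forest splits its feature's axis.
#' Collecting the (exactly deduplicated) sorted thresholds `t_1 < ... < t_k`
#' of a feature induces the mutually exclusive and exhaustive intervals
#' `(-Inf, t_1), [t_1, t_2), ..., [t_k, Inf)` — a discretization of the
#' continuous feature on which the forest is constant. A feature tested
#' nowhere gets the single interval `(-Inf, Inf)`. Intervals are half-open on
#' the left-closed convention, matching `x >= t` being the high branch.
#'
#' @param forest a `primo_forest`.
#' @return An object of class `primo_partition`: a list with `thresholds`
#'   (list of sorted numeric vectors, one per feature), `n_intervals`
#'   (integer vector, `= lengths(thresholds) + 1`), and `features`.
#' @export
extract_partition <- function(forest) {
  stopifnot(inherits(forest, "primo_forest"))
  p <- nrow(forest$features)
  th <- lapply(seq_len(p), function(i) numeric(0))
  collect <- function(node) {
    if (is_leaf(node)) return(invisible(NULL))
    th[[node$feature]] <<- c(th[[node$feature]], node$threshold)
    collect(node$low); collect(node$high)
  }
  for (tr in forest$trees) collect(tr)
  th <- lapply(th, function(v) sort(unique(v)))
  partition(th, forest$features)
}

#' @rdname extract_partition
#' @param thresholds list of sorted, strictly increasing numeric vectors.
#' @param features a `primo_features` table (optional for synthetic
#'   partitions used in testing).
#' @export
partition <- function(thresholds, features = NULL) {
  for (v in thresholds) {
    if (is.unsorted(v, strictly = TRUE)) stop("thresholds must be strictly increasing")
    if (length(v) && any(!is.finite(v))) stop("thresholds must be finite")
  }
  structure(list(thresholds = thresholds,
                 n_intervals = lengths(thresholds) + 1L,
                 features = features),
            class = "primo_partition")
}

#' @export
print.primo_partition <- function(x, ...) {
  nm <- if (!is.null(x$features)) x$features$name else
    paste0("feature_", seq_along(x$thresholds))
  cat("Interval partition:", prod(x$n_intervals), "cells\n")
  for (i in seq_along(x$thresholds))
    cat(sprintf("  %s: %d interval(s)%s\n", nm[i], x$n_intervals[i],
                if (length(x$thresholds[[i]]))
                  paste0(" | thresholds ",
                         paste(signif(x$thresholds[[i]], 4), collapse = ", "))
                else ""))
  invisible(x)
}

#' Map instances to cells of the partition
#'
#' A cell is one interval index per feature (1-based). A value `x` on a
#' feature with thresholds `t_1 < ... < t_k` falls in interval
#' `1 + #\{j : x >= t_j\}`; a boundary value `t_j` therefore belongs to the
#' interval whose left edge it is.
#'
#' @param partition a `primo_partition`.
#' @param instance numeric vector, or matrix/data frame with one row per
#'   instance (natural units).
#' @return Integer vector (or matrix) of interval indices.
#' @export
discretize <- function(partition, instance) {
  one <- function(x) {
    vapply(seq_along(x), function(i)
      1L + sum(x[i] >= partition$thresholds[[i]]), integer(1))
  }
  if (is.matrix(instance) || is.data.frame(instance)) {
    instance <- as.matrix(instance)
    t(apply(instance, 1, one))
  } else one(instance)
}

#' Representative point of a cell
#'
#' Returns a finite instance strictly inside each of the cell's intervals:
#' the midpoint of bounded intervals, and `edge - 1` / `edge + 1` for the
#' unbounded first / last intervals (`0` for a feature with no thresholds).
#' The representative always discretizes back to its own cell.
#'
#' @param partition a `primo_partition`.
#' @param cell integer vector of interval indices.
#' @return Numeric instance in natural units.
#' @export
cell_representative <- function(partition, cell) {
  vapply(seq_along(cell), function(i) {
    th <- partition$thresholds[[i]]
    j <- cell[i]
    if (j < 1L || j > length(th) + 1L) stop("cell index out of range for feature ", i)
    if (length(th) == 0) return(0)
    if (j == 1L) return(th[1] - 1)
    if (j == length(th) + 1L) return(th[length(th)] + 1)
    (th[j - 1] + th[j]) / 2
  }, numeric(1))
}

#' Interval bounds of a cell or interval index
#'
#' @param partition a `primo_partition`.
#' @param feature feature index.
#' @param index interval index (1-based).
#' @return `c(low, high)`: the half-open interval `[low, high)`, with
#'   `-Inf`/`Inf` for unbounded ends.
#' @export
interval_bounds <- function(partition, feature, index) {
  th <- partition$thresholds[[feature]]
  lo <- if (index == 1L) -Inf else th[index - 1]
  hi <- if (index == length(th) + 1L) Inf else th[index]
  c(lo, hi)
}
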