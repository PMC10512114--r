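# Baseline explainability metrics shown alongside the prime-implicant tool:
# per-feature monotonicity percentages and best-worst case conditional
# proportions.

#' Monotonicity percentage of a feature
#'
#' For each instance (cell), the feature is swept across its ordered
#' intervals with the other features held fixed, producing a binary
#' prediction sequence. The instance counts as monotone iff that sequence has
#' at most one transition (i.e. is non-decreasing or non-increasing), and the
#' metric is 100 times the monotone fraction. A feature with a single
#' interval is vacuously monotone (100, flagged).
#'
#' @param odd a `primo_odd`.
#' @param feature feature index to sweep.
#' @param cells instance set: integer matrix of cells (one per row), or
#'   `NULL` for the default — every cell when the product space has at most
#'   `exhaustive_limit` cells, otherwise a seeded uniform sample of
#'   `sample_size` cells.
#' @param exhaustive_limit,sample_size,seed instance-set controls.
#' @return Percent in \[0, 100\], with attribute `vacuous` when the feature
#'   has one interval and attribute `n_instances`.
#' @export
monotonicity <- function(odd, feature, cells = NULL, exhaustive_limit = 1e5,
                         sample_size = 10000L, seed = 1L) {
  mgr <- odd$mgr
  nv <- mgr$nvals
  if (nv[feature] == 1L) {
    out <- 100
    attr(out, "vacuous") <- TRUE
    attr(out, "n_instances") <- 0L
    return(out)
  }
  if (is.null(cells)) cells <- default_cells(nv, exhaustive_limit, sample_size, seed)
  if (nrow(cells) == 0) stop("instance set is empty")
  monotone <- vapply(seq_len(nrow(cells)), function(r) {
    cell <- cells[r, ]
    seqv <- vapply(seq_len(nv[feature]), function(j) {
      cell[feature] <- j
      odd_evaluate(odd, cell) == "positive"
    }, logical(1))
    sum(abs(diff(seqv))) <= 1L
  }, logical(1))
  out <- 100 * mean(monotone)
  attr(out, "vacuous") <- FALSE
  attr(out, "n_instances") <- nrow(cells)
  out
}

default_cells <- function(nvals, exhaustive_limit, sample_size, seed) {
  total <- prod(nvals)
  if (total <= exhaustive_limit) {
    as.matrix(expand.grid(lapply(nvals, seq_len)))
  } else {
    with_seed(seed, vapply(nvals, function(k)
      sample.int(k, sample_size, replace = TRUE), integer(sample_size)))
  }
}

# Evaluate code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Best-worst case conditional proportions
#'
#' For a fixed (feature, interval) pair, the proportion of completions of the
#' remaining features classified positive and negative — the information an
#' observer gains about the class from seeing that feature-value pair alone.
#' Under `weighting = "uniform"` completions are counted uniformly over cells
#' via model counting; under `weighting = "empirical"` the proportions are
#' computed over the dataset rows whose feature value falls in the interval.
#'
#' @param odd a `primo_odd`.
#' @param feature feature index.
#' @param interval_index interval of that feature (1-based).
#' @param weighting `"uniform"` (default) or `"empirical"`.
#' @param data data frame of instances in natural units (feature columns in
#'   partition order), required for empirical weighting.
#' @return Named numeric `c(p_positive, p_negative)`, summing to 1.
#' @export
best_worst <- function(odd, feature, interval_index,
                       weighting = c("uniform", "empirical"), data = NULL) {
  weighting <- match.arg(weighting)
  mgr <- odd$mgr
  if (interval_index < 1L || interval_index > mgr$nvals[feature])
    stop("interval index out of range for feature ", feature)
  if (weighting == "uniform") {
    partial <- rep(NA_integer_, length(mgr$nvals))
    partial[feature] <- as.integer(interval_index)
    # the conditioned variable no longer appears, so it contributes a full
    # don't-care factor to the count; dividing by the whole space yields the
    # proportion over completions of the remaining features
    k <- model_count(odd_condition(odd, partial))
    p_pos <- k / prod(mgr$nvals)
  } else {
    if (is.null(data)) stop("empirical weighting requires data")
    part <- mgr$partition
    nm <- if (!is.null(part$features)) part$features$name else colnames(data)
    x <- as.matrix(data[, nm, drop = FALSE])
    cells <- discretize(part, x)
    sel <- cells[, feature] == interval_index
    if (!any(sel))
      stop("undefined proportion: no dataset rows fall in interval ",
           interval_index, " of feature ", feature)
    preds <- vapply(which(sel), function(r) odd_evaluate(odd, cells[r, ]),
                    character(1))
    p_pos <- mean(preds == "positive")
  }
  c(p_positive = p_pos, p_negative = 1 - p_pos)
}

#' Tabulate both baseline metrics for every feature
#'
#' @param odd a `primo_odd`.
#' @param ... passed to [monotonicity()].
#' @return A list with `monotonicity` (data frame: feature, percent, vacuous)
#'   and `best_worst` (data frame: feature, interval, low, high, p_positive,
#'   p_negative), serializable to JSON.
#' @export
baseline_metrics <- function(odd, ...) {
  mgr <- odd$mgr
  part <- mgr$partition
  nm <- if (!is.null(part$features)) part$features$name
        else paste0("feature_", seq_along(mgr$nvals))
  mono <- do.call(rbind, lapply(seq_along(mgr$nvals), function(f) {
    m <- monotonicity(odd, f, ...)
    data.frame(feature = nm[f], percent = as.numeric(m),
               vacuous = isTRUE(attr(m, "vacuous")))
  }))
  bw <- do.call(rbind, lapply(seq_along(mgr$nvals), function(f) {
    do.call(rbind, lapply(seq_len(mgr$nvals[f]), function(j) {
      b <- interval_bounds(part, f, j)
      p <- best_worst(odd, f, j)
      data.frame(feature = nm[f], interval = j, low = b[1], high = b[2],
                 p_positive = p[["p_positive"]], p_negative = p[["p_negative"]])
    }))
  }))
  list(monotonicity = mono, best_worst = bw)
}
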