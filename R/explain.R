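# Prime-implicant (sufficient) explanations.
#
# An implicant is a partial assignment of features to interval indices such
# that every completion of it receives the same class label (sufficiency);
# it is prime when dropping any assigned feature breaks sufficiency. The
# explanation shown for an instance is the shortest prime implicant
# compatible with the instance's cell — the smallest subinstance that by
# itself fixes the classifier's decision — subsequently widened, per feature,
# to the maximal contiguous run of intervals that preserves sufficiency, and
# rendered as natural-unit ranges.

#' Test sufficiency of a partial assignment
#'
#' A partial assignment is sufficient for a label iff conditioning the
#' diagram on it yields the constant diagram of that label, i.e. every
#' completion over the unassigned features receives `label`.
#'
#' @param odd a `primo_odd`.
#' @param partial integer vector with `NA` for unassigned features (or a
#'   named list, see [odd_condition()]).
#' @param label `"positive"` or `"negative"`.
#' @return Logical.
#' @export
is_sufficient <- function(odd, partial, label) {
  res <- odd_condition(odd, partial)
  res$root == if (label == "positive") TRUE_ID else FALSE_ID
}

# Sufficiency for a set-valued partial assignment: sets[[f]] is NULL
# (unconstrained) or a vector of allowed interval indices. True iff every
# cell consistent with the sets receives `label`.
is_sufficient_sets <- function(odd, sets, label) {
  mgr <- odd$mgr
  target <- if (label == "positive") TRUE_ID else FALSE_ID
  memo <- new.env(parent = emptyenv())
  rec <- function(id) {
    if (id <= 2L) return(id == target)
    key <- as.character(id)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    v <- mgr$var[id]
    kids <- mgr$kids[[id]]
    if (!is.null(sets[[v]])) kids <- kids[sets[[v]]]
    res <- all(vapply(unique(kids), rec, logical(1)))
    memo[[key]] <- res
    res
  }
  rec(odd$root)
}

#' Shortest prime implicant compatible with a cell
#'
#' Searches feature subsets in increasing cardinality (and, within a
#' cardinality, in lexicographic order of the feature-index sets, which makes
#' ties reproducible) for the smallest subset S such that fixing the cell's
#' intervals on S alone already forces the cell's label. Minimum cardinality
#' implies primality: dropping a feature gives a smaller sufficient subset,
#' which would have been found first.
#'
#' @param odd a `primo_odd`.
#' @param cell integer vector of interval indices.
#' @return A list of class `primo_implicant`: `features` (integer indices),
#'   `intervals` (their interval indices), `label`, `partial` (full-length
#'   vector with `NA`s).
#' @export
shortest_prime_implicant <- function(odd, cell) {
  mgr <- odd$mgr
  p <- length(mgr$nvals)
  label <- odd_evaluate(odd, cell)
  for (size in 0:p) {
    subsets <- if (size == 0) matrix(integer(0), nrow = 0, ncol = 1)
               else utils::combn(p, size)
    for (j in seq_len(ncol(subsets))) {
      s <- subsets[, j]
      partial <- rep(NA_integer_, p)
      partial[s] <- cell[s]
      if (is_sufficient(odd, partial, label))
        return(structure(list(features = s, intervals = cell[s],
                              label = label, partial = partial),
                         class = "primo_implicant"))
    }
  }
  stop("unreachable: the full cell is always sufficient for its own label")
}

#' @export
print.primo_implicant <- function(x, ...) {
  cat("Prime implicant (", x$label, "), cardinality ", length(x$features),
      "\n", sep = "")
  if (length(x$features))
    cat(paste0("  feature ", x$features, " = interval ", x$intervals,
               collapse = "\n"), "\n")
  invisible(x)
}

#' Enumerate all prime implicants of a label
#'
#' For the small feature spaces at hand this filters all partial assignments:
#' a partial assignment is kept iff it is sufficient for `label` and no
#' single assigned feature can be dropped without losing sufficiency. The
#' disjunction of the returned implicants is the label's prime cover.
#'
#' @param odd a `primo_odd`.
#' @param label `"positive"` or `"negative"`.
#' @param cap maximum number of implicants to return.
#' @return A list of `primo_implicant` objects with attribute `truncated`
#'   (logical) — never silently truncated.
#' @export
enumerate_prime_implicants <- function(odd, label, cap = 10000L) {
  mgr <- odd$mgr
  p <- length(mgr$nvals)
  if (p > 12) stop("exhaustive enumeration is limited to <= 12 features")
  out <- list()
  truncated <- FALSE
  for (size in 0:p) {
    subsets <- if (size == 0) matrix(integer(0), nrow = 0, ncol = 1)
               else utils::combn(p, size)
    for (j in seq_len(ncol(subsets))) {
      s <- subsets[, j]
      grid <- if (size == 0) matrix(integer(0), nrow = 1, ncol = 0)
              else as.matrix(expand.grid(lapply(mgr$nvals[s], seq_len)))
      for (r in seq_len(nrow(grid))) {
        partial <- rep(NA_integer_, p)
        partial[s] <- as.integer(grid[r, ])
        if (!is_sufficient(odd, partial, label)) next
        prime <- TRUE
        for (d in s) {
          sub <- partial; sub[d] <- NA_integer_
          if (is_sufficient(odd, sub, label)) { prime <- FALSE; break }
        }
        if (!prime) next
        if (length(out) >= cap) { truncated <- TRUE; break }
        out[[length(out) + 1L]] <- structure(
          list(features = s, intervals = partial[s], label = label,
               partial = partial), class = "primo_implicant")
      }
      if (truncated) break
    }
    if (truncated) break
  }
  attr(out, "truncated") <- truncated
  out
}

#' Widen an implicant to maximal invariance ranges
#'
#' Starting from the implicant's single-interval assignments, each assigned
#' feature (in variable order) is greedily extended to the maximal contiguous
#' run of intervals containing the instance's interval — left first, then
#' right — such that the set-valued assignment remains sufficient. Within the
#' resulting per-feature ranges any tweak of the input values leaves the
#' model's prediction unchanged; unassigned features carry no range (no
#' constraint at all).
#'
#' @param odd a `primo_odd` whose manager holds the feature partition.
#' @param implicant a `primo_implicant` compatible with `cell`.
#' @param cell the instance's cell.
#' @param instance optional original instance (natural units) echoed into the
#'   result.
#' @return An object of class `primo_explanation`: the implicant, the
#'   prediction, `interval_sets` (per assigned feature, the widened
#'   contiguous interval indices), and `ranges`, a data frame with one row
#'   per assigned feature (`feature`, `name`, `low`, `high`, `low_open`,
#'   `high_open` in natural units, plus `z_low`, `z_high` when feature
#'   scaling is available).
#' @export
widen_ranges <- function(odd, implicant, cell, instance = NULL) {
  mgr <- odd$mgr
  if (!all(cell[implicant$features] == implicant$intervals))
    stop("implicant is not compatible with the cell")
  label <- implicant$label
  sets <- vector("list", length(mgr$nvals))
  for (i in seq_along(implicant$features))
    sets[[implicant$features[i]]] <- implicant$intervals[i]
  for (f in mgr$order) {
    if (is.null(sets[[f]])) next
    repeat {                       # extend left
      lo <- sets[[f]][1]
      if (lo == 1L) break
      trial <- sets; trial[[f]] <- c(lo - 1L, sets[[f]])
      if (!is_sufficient_sets(odd, trial, label)) break
      sets <- trial
    }
    repeat {                       # then right
      hi <- sets[[f]][length(sets[[f]])]
      if (hi == mgr$nvals[f]) break
      trial <- sets; trial[[f]] <- c(sets[[f]], hi + 1L)
      if (!is_sufficient_sets(odd, trial, label)) break
      sets <- trial
    }
  }
  part <- mgr$partition
  feats <- part$features
  rows <- lapply(implicant$features, function(f) {
    idx <- sets[[f]]
    lo <- interval_bounds(part, f, idx[1])[1]
    hi <- interval_bounds(part, f, idx[length(idx)])[2]
    data.frame(feature = f,
               name = if (!is.null(feats)) feats$name[f] else paste0("feature_", f),
               low = lo, high = hi,
               low_open = is.infinite(lo), high_open = TRUE,
               z_low = if (!is.null(feats)) (lo - feats$z_mean[f]) / feats$z_sd[f] else NA_real_,
               z_high = if (!is.null(feats)) (hi - feats$z_mean[f]) / feats$z_sd[f] else NA_real_)
  })
  ranges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = integer(0), name = character(0), low = numeric(0),
               high = numeric(0), low_open = logical(0), high_open = logical(0),
               z_low = numeric(0), z_high = numeric(0))
  structure(list(implicant = implicant, prediction = label, cell = cell,
                 instance = instance, interval_sets = sets, ranges = ranges,
                 partition = part),
            class = "primo_explanation")
}

#' Explain a prediction for an instance
#'
#' The full pipeline: discretize the instance into its cell, find the
#' shortest compatible prime implicant, widen it to maximal invariance
#' ranges, and render the ranges in natural units (and z-units when feature
#' scaling is available). The headline guarantee: tweaking the instance's
#' values anywhere within the displayed ranges cannot change the model's
#' prediction.
#'
#' @param x a `primo_forest` or a compiled `primo_odd`.
#' @param instance numeric vector in natural units (use
#'   [z_to_natural()] first for z-score entry).
#' @param ... unused.
#' @return A `primo_explanation` (see [widen_ranges()]).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 419, seed = 1))
#' f <- train_forest(cohort, weight_loss_features(), seed = 1)
#' explain_instance(f, archetypes()$natural["basic_weight_loss", ])
explain_instance <- function(x, instance, ...) {
  odd <- if (inherits(x, "primo_forest")) compile_forest(x)
         else if (inherits(x, "primo_odd")) x
         else stop("x must be a primo_forest or a primo_odd")
  instance <- as.numeric(instance)
  if (any(!is.finite(instance))) stop("instance values must be finite")
  cell <- discretize(odd$mgr$partition, instance)
  imp <- shortest_prime_implicant(odd, cell)
  widen_ranges(odd, imp, cell, instance = instance)
}

#' @export
print.primo_explanation <- function(x, ...) {
  cat("Prediction:", x$prediction, "\n")
  if (nrow(x$ranges) == 0) {
    cat("No feature constraints: the prediction holds everywhere.\n")
    return(invisible(x))
  }
  cat("Invariance ranges (prediction cannot change inside these):\n")
  for (i in seq_len(nrow(x$ranges))) {
    r <- x$ranges[i, ]
    lo <- if (is.infinite(r$low)) "-Inf" else format(signif(r$low, 4))
    hi <- if (is.infinite(r$high)) "Inf" else format(signif(r$high, 4))
    cat(sprintf("  %s in [%s, %s)\n", r$name, lo, hi))
  }
  un <- setdiff(seq_along(x$cell), x$ranges$feature)
  if (length(un)) {
    nm <- if (!is.null(x$partition$features)) x$partition$features$name[un]
          else paste0("feature_", un)
    cat("Unconstrained:", paste(nm, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize an explanation as JSON
#'
#' @param explanation a `primo_explanation`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
explanation_json <- function(explanation, path = NULL) {
  e <- explanation
  feats <- e$partition$features
  obj <- list(
    prediction = e$prediction,
    instance = if (!is.null(e$instance)) list(
      natural = as.numeric(e$instance),
      z = if (!is.null(feats)) as.numeric((e$instance - feats$z_mean) / feats$z_sd)
          else NULL) else NULL,
    ranges = lapply(seq_len(nrow(e$ranges)), function(i) as.list(e$ranges[i, ])),
    implicant = lapply(seq_along(e$implicant$features), function(i)
      list(feature = e$implicant$features[i],
           interval_index = e$implicant$intervals[i])),
    partition = lapply(e$partition$thresholds, as.numeric))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17), null = "null",
                         pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(as.character(js))) }
  as.character(js)
}
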