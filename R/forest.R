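#' Decision-tree and random-forest structures
#'
#' Trees are plain nested lists. An internal node is
#' `list(feature = <1-based index>, threshold = <natural units>, low = <node>,
#' high = <node>)` and routes an instance to `high` iff
#' `value >= threshold` (the propositions are of the form `x_i >= t` /
#' `x_i < t`). A leaf is `list(leaf = "positive")` or `list(leaf = "negative")`,
#' where `"positive"` denotes at least 7% weight loss at six months.
#'
#' @param trees list of tree root nodes.
#' @param features a `primo_features` table (see [feature_spec()]).
#' @param max_depth the depth cap the trees were grown under.
#' @return An object of class `primo_forest`.
#' @export
forest <- function(trees, features, max_depth) {
  stopifnot(inherits(features, "primo_features"), length(trees) >= 1)
  for (tr in trees) validate_tree(tr, nrow(features), max_depth)
  structure(list(trees = trees, features = features,
                 n_trees = length(trees), max_depth = as.integer(max_depth)),
            class = "primo_forest")
}

is_leaf <- function(node) !is.null(node$leaf)

validate_tree <- function(node, n_features, max_depth, depth = 0L) {
  if (depth > max_depth) stop("tree exceeds max_depth ", max_depth)
  if (is_leaf(node)) {
    if (!node$leaf %in% c("positive", "negative"))
      stop("leaf label must be 'positive' or 'negative'")
    return(invisible(TRUE))
  }
  if (is.null(node$feature) || node$feature < 1 || node$feature > n_features)
    stop("internal node references feature index out of range: ", node$feature)
  if (!is.finite(node$threshold)) stop("threshold must be finite")
  validate_tree(node$low, n_features, max_depth, depth + 1L)
  validate_tree(node$high, n_features, max_depth, depth + 1L)
}

#' Predict with a single decision tree
#'
#' Routes the instance from the root: `low` iff `value < threshold`,
#' `high` iff `value >= threshold`.
#'
#' @param tree a tree root node.
#' @param instance numeric vector of feature values in natural units.
#' @return `"positive"` or `"negative"`.
#' @export
predict_tree <- function(tree, instance) {
  node <- tree
  while (!is_leaf(node)) {
    if (node$feature > length(instance))
      stop("feature index out of range: ", node$feature)
    node <- if (instance[[node$feature]] >= node$threshold) node$high else node$low
  }
  node$leaf
}

#' Predict with a forest by hard majority vote
#'
#' The forest votes `"positive"` iff at least `floor(n_trees / 2) + 1` trees
#' reach a positive leaf, i.e. a strict majority. With an even number of trees
#' a tie therefore returns `"negative"` (conservative for a success label).
#'
#' @param object a `primo_forest`.
#' @param instance numeric vector (one instance) or matrix / data frame with
#'   one row per instance, natural units.
#' @param ... unused.
#' @return Character vector of labels, one per instance.
#' @export
predict.primo_forest <- function(object, instance, ...) {
  if (is.data.frame(instance)) instance <- as.matrix(instance)
  if (!is.matrix(instance)) instance <- matrix(instance, nrow = 1)
  if (ncol(instance) != nrow(object$features))
    stop("instance has ", ncol(instance), " values; forest expects ",
         nrow(object$features))
  apply(instance, 1, function(x) {
    votes <- sum(vapply(object$trees, function(tr)
      predict_tree(tr, x) == "positive", logical(1)))
    if (votes >= floor(object$n_trees / 2) + 1) "positive" else "negative"
  })
}

#' @rdname predict.primo_forest
#' @param forest a `primo_forest`.
#' @export
predict_forest <- function(forest, instance) {
  if (forest$n_trees < 1) stop("empty forest")
  predict(forest, instance)
}

#' @export
print.primo_forest <- function(x, ...) {
  cat("Random forest:", x$n_trees, "trees, max depth", x$max_depth, "\n")
  cat("Features:", paste(x$features$name, collapse = ", "), "\n")
  invisible(x)
}

tree_depth <- function(node) {
  if (is_leaf(node)) 0L else 1L + max(tree_depth(node$low), tree_depth(node$high))
}

#' Train a depth-limited random forest
#'
#' Fits a classification forest by bootstrap resampling with random feature
#' subsetting and a hard depth cap (the study configuration is 13 trees of
#' maximum depth 3 over the 5 features), then imports each tree into the
#' package's own structures: every leaf carries the majority class of the
#' training rows it received, and the forest predicts by hard majority vote
#' over these leaf labels. Training is delegated to \pkg{ranger} and is
#' deterministic given `seed`.
#'
#' @param data data frame with the feature columns named in `features` plus a
#'   binary `outcome` column in \{0, 1\} (1 = positive class).
#' @param features a `primo_features` table naming the feature columns.
#' @param n_trees,max_depth forest size and depth cap.
#' @param mtry features tried per split (default `floor(sqrt(p))`).
#' @param seed integer seed; identical (data, config, seed) give identical
#'   forests.
#' @return A `primo_forest`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 419, seed = 1))
#' f <- train_forest(cohort, weight_loss_features(), n_trees = 13,
#'                   max_depth = 3, seed = 1)
train_forest <- function(data, features, n_trees = 13, max_depth = 3,
                         mtry = NULL, seed = 1) {
  stopifnot(n_trees >= 1, max_depth >= 1)
  miss <- setdiff(c(features$name, "outcome"), names(data))
  if (length(miss)) stop("data is missing columns: ", paste(miss, collapse = ", "))
  y <- data$outcome
  if (!all(y %in% c(0, 1))) stop("outcome must be binary in {0, 1}")
  if (!any(y == 1)) stop("training data contain no positive-class rows (outcome = 1)")
  if (!any(y == 0)) stop("training data contain no negative-class rows (outcome = 0)")
  df <- data[, features$name, drop = FALSE]
  df$.outcome <- factor(ifelse(y == 1, "positive", "negative"),
                        levels = c("negative", "positive"))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(nrow(features))))
  fit <- ranger::ranger(.outcome ~ ., data = df, num.trees = n_trees,
                        max.depth = max_depth, mtry = mtry, seed = seed,
                        num.threads = 1, respect.unordered.factors = FALSE)
  trees <- lapply(seq_len(n_trees), function(k)
    import_ranger_tree(ranger::treeInfo(fit, k)))
  forest(trees, features, max_depth)
}

# treeInfo rows: nodeID (0-based), leftChild/rightChild, splitvarID (0-based),
# splitval, terminal, prediction. ranger routes x <= splitval left; we store
# the same split value with the package convention "x >= t goes high", which
# coincides except on the measure-zero set {x == t} and is canonical from
# here on.
import_ranger_tree <- function(info) {
  build <- function(id0) {
    row <- info[info$nodeID == id0, ]
    if (row$terminal) {
      lab <- as.character(row$prediction)
      if (lab %in% c("0", "1")) lab <- c("0" = "negative", "1" = "positive")[lab]
      return(list(leaf = lab))
    }
    list(feature = row$splitvarID + 1L, threshold = row$splitval,
         low = build(row$leftChild), high = build(row$rightChild))
  }
  build(0L)
}
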