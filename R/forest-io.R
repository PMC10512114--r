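# Forest JSON serialization.
#
# Schema:
#   {"features":[{"name","units","z_mean","z_sd"}, ...],
#    "n_trees": int, "max_depth": int,
#    "trees":[ {"feature": int (1-based), "threshold": num,
#               "low": <node>, "high": <node>} | {"leaf": "positive"|"negative"} ]}
# Thresholds are written with 17 significant digits so a write/read round
# trip reproduces every IEEE double bit-exactly.

#' Read or write a forest as JSON
#'
#' @param forest a `primo_forest`.
#' @param path file path.
#' @return `read_forest` returns a `primo_forest`; `write_forest` invisibly
#'   returns `path`.
#' @export
write_forest <- function(forest, path) {
  stopifnot(inherits(forest, "primo_forest"))
  obj <- list(
    features = lapply(seq_len(nrow(forest$features)), function(i)
      list(name = forest$features$name[i], units = forest$features$units[i],
           z_mean = forest$features$z_mean[i], z_sd = forest$features$z_sd[i])),
    n_trees = forest$n_trees, max_depth = forest$max_depth,
    trees = lapply(forest$trees, tree_to_json))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

tree_to_json <- function(node) {
  if (is_leaf(node)) list(leaf = node$leaf)
  else list(feature = node$feature, threshold = node$threshold,
            low = tree_to_json(node$low), high = tree_to_json(node$high))
}

#' @rdname write_forest
#' @export
read_forest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (key in c("features", "n_trees", "max_depth", "trees"))
    if (is.null(obj[[key]]))
      stop("forest JSON: missing required key at /", key)
  feats <- obj$features
  for (i in seq_along(feats))
    for (key in c("name", "units", "z_mean", "z_sd"))
      if (is.null(feats[[i]][[key]]))
        stop("forest JSON: missing key at /features/", i - 1, "/", key)
  features <- feature_spec(
    vapply(feats, `[[`, "", "name"), vapply(feats, `[[`, "", "units"),
    vapply(feats, function(f) as.numeric(f$z_mean), 0),
    vapply(feats, function(f) as.numeric(f$z_sd), 0))
  if (length(obj$trees) != obj$n_trees)
    stop("forest JSON: /n_trees (", obj$n_trees, ") does not match number of ",
         "trees (", length(obj$trees), ")")
  trees <- lapply(seq_along(obj$trees), function(k)
    tree_from_json(obj$trees[[k]], sprintf("/trees/%d", k - 1)))
  forest(trees, features, as.integer(obj$max_depth))
}

tree_from_json <- function(node, ptr) {
  if (!is.null(node$leaf)) {
    if (!node$leaf %in% c("positive", "negative"))
      stop("forest JSON: invalid leaf label at ", ptr, "/leaf")
    return(list(leaf = node$leaf))
  }
  for (key in c("feature", "threshold", "low", "high"))
    if (is.null(node[[key]]))
      stop("forest JSON: node at ", ptr, " is neither a leaf nor a complete ",
           "internal node (missing ", key, ")")
  list(feature = as.integer(node$feature), threshold = as.numeric(node$threshold),
       low = tree_from_json(node$low, paste0(ptr, "/low")),
       high = tree_from_json(node$high, paste0(ptr, "/high")))
}
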