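#' Feature specification with z-score/natural-unit duality
#'
#' The five self-monitoring features are measured in natural units (percent
#' weekly weight change, food-diary item counts, grams of fat) but are often
#' communicated on the cohort z-scale. A `primo_features` table stores the
#' affine map `natural = z_mean + z * z_sd` for each feature so instances can
#' be entered and displayed on either scale.
#'
#' @param name character vector of unique feature names.
#' @param units character vector of natural-unit labels.
#' @param z_mean numeric, natural-unit value at z = 0 (the cohort mean).
#' @param z_sd positive numeric, natural units per z-unit (the cohort SD).
#'
#' @return A data frame of class `primo_features` with one row per feature.
#' @export
#' @examples
#' feature_spec("weekly_weight_change", "%", z_mean = -1.3, z_sd = 2.39)
feature_spec <- function(name, units, z_mean, z_sd) {
  stopifnot(length(name) == length(units),
            length(name) == length(z_mean),
            length(name) == length(z_sd))
  if (anyDuplicated(name)) stop("feature names must be unique")
  if (any(!is.finite(z_sd)) || any(z_sd <= 0)) stop("z_sd must be positive and finite")
  out <- data.frame(name = as.character(name), units = as.character(units),
                    z_mean = as.numeric(z_mean), z_sd = as.numeric(z_sd),
                    stringsAsFactors = FALSE)
  class(out) <- c("primo_features", "data.frame")
  out
}

#' Convert between z-scores and natural units
#'
#' @param features a `primo_features` table.
#' @param z,natural numeric vector or matrix with one column per feature.
#' @return The values on the other scale, same shape as the input.
#' @export
z_to_natural <- function(features, z) {
  scale_shift(z, features$z_sd, features$z_mean)
}

#' @rdname z_to_natural
#' @export
natural_to_z <- function(features, natural) {
  scale_shift(natural, 1 / features$z_sd, -features$z_mean / features$z_sd)
}

scale_shift <- function(x, mult, add) {
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    stopifnot(ncol(x) == length(mult))
    sweep(sweep(x, 2, mult, `*`), 2, add, `+`)
  } else {
    stopifnot(length(x) == length(mult))
    x * mult + add
  }
}

#' The four hypothetical patient archetypes
#'
#' Returns the four archetype instances used in the expert evaluation study
#' (a basic and a complex case of each outcome), with each feature given both
#' as a cohort z-score and in natural units. These twenty (z, natural) pairs
#' are also what [scaling_from_archetypes()] uses to recover the per-feature
#' affine z-to-natural maps.
#'
#' @return A list of class `primo_archetypes` with elements `z` and `natural`
#'   (4 x 5 numeric matrices, archetypes in rows), `expected_outcome`
#'   (named character vector, `"positive"` = at least 7% weight loss at six
#'   months), and `feature_names`.
#' @export
#' @examples
#' a <- archetypes()
#' a$natural["basic_weight_loss", ]
archetypes <- function() {
  feats <- c("weekly_weight_change", "daily_food_entry", "daily_fat",
             "daily_custom_food_entry", "daily_saturated_fat")
  arcs <- c("basic_weight_loss", "basic_failed_weight_loss",
            "complex_weight_loss", "complex_failed_weight_loss")
  z <- rbind(
    c(-2.51, 0.00, -2.07,  0.00, -1.67),
    c( 0.50, 0.00,  0.76,  0.00,  1.79),
    c(-0.10, 1.44, -0.75,  1.78,  0.40),
    c(-2.05, -1.97, -0.11, -0.12,  1.20))
  natural <- rbind(
    c(-7.30,  8.19, 17.10, 2.00,  1.291),
    c(-0.11,  8.19, 45.70, 2.00, 15.500),
    c(-1.54, 12.00, 30.45, 5.00,  9.790),
    c(-6.20,  3.00, 36.90, 1.80, 13.070))
  dimnames(z) <- dimnames(natural) <- list(arcs, feats)
  out <- list(z = z, natural = natural,
              expected_outcome = stats::setNames(
                c("positive", "negative", "positive", "negative"), arcs),
              feature_names = feats)
  class(out) <- "primo_archetypes"
  out
}

#' Recover z-score scaling from (z, natural) value pairs
#'
#' Fits, per feature, the affine map `natural = z_mean + z * z_sd` by least
#' squares from at least two (z, natural) pairs, as printed for the archetype
#' instances. With more than two pairs the extra pairs serve as a
#' cross-validation of the fit and the worst residual is reported in z-units.
#'
#' @param pairs a list, one element per feature, each a two-column matrix or
#'   data frame with columns `z` and `natural`; or a `primo_archetypes`
#'   object, in which case all four instances are used.
#' @param units optional character vector of unit labels (defaults to `""`).
#' @return A `primo_features` table with an extra numeric column
#'   `max_residual_z`: the largest absolute leave-in residual expressed in
#'   z-units (`|natural - fit| / z_sd`).
#' @export
#' @examples
#' scaling_from_archetypes(archetypes())
scaling_from_archetypes <- function(pairs, units = NULL) {
  if (inherits(pairs, "primo_archetypes")) {
    a <- pairs
    pairs <- lapply(seq_along(a$feature_names), function(j)
      cbind(z = a$z[, j], natural = a$natural[, j]))
    names(pairs) <- a$feature_names
    if (is.null(units))
      units <- c("%", "items", "g", "items", "g")
  }
  if (is.null(units)) units <- rep("", length(pairs))
  nm <- names(pairs)
  if (is.null(nm)) nm <- paste0("feature_", seq_along(pairs))
  fits <- lapply(pairs, function(p) {
    p <- as.data.frame(p)
    if (nrow(p) < 2) stop("need at least two (z, natural) pairs per feature")
    if (max(p$z) - min(p$z) < 1e-12)
      stop("degenerate pairs: all z values equal, affine map not identifiable")
    fit <- stats::lm(natural ~ z, data = p)
    sd <- unname(stats::coef(fit)[2])
    if (sd <= 0) stop("fitted z_sd is not positive")
    resid_z <- abs(stats::resid(fit)) / sd
    c(mean = unname(stats::coef(fit)[1]), sd = sd, res = max(resid_z))
  })
  out <- feature_spec(nm, units,
                      z_mean = vapply(fits, `[[`, 0, "mean"),
                      z_sd = vapply(fits, `[[`, 0, "sd"))
  out$max_residual_z <- vapply(fits, `[[`, 0, "res")
  out
}

#' Feature scaling for the weight-loss cohort
#'
#' Convenience wrapper: the `primo_features` table fitted from the four
#' archetype instances. This is the default feature specification used by the
#' synthetic cohort generator.
#'
#' @return A `primo_features` table for the five features.
#' @export
weight_loss_features <- function() {
  f <- scaling_from_archetypes(archetypes())
  f$max_residual_z <- NULL
  f
}
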