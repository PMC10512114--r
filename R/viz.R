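# Static rendering of an explanation: one horizontal bar per feature on a
# clipped z-axis, the invariance range highlighted, and a marker dot at the
# instance — plus an aligned ASCII version for terminals.

#' Render an explanation as SVG and text
#'
#' Each feature gets a horizontal bar spanning z in `[-z_span, z_span]`
#' (clipped); the widened invariance range is drawn as a highlighted band
#' with dual z / natural-unit labels, an arrow glyph marking range ends that
#' extend beyond the clip, and a dot marking the instance. Features without a
#' range are annotated "no constraint" — the prediction does not depend on
#' them at all for this instance.
#'
#' @param explanation a `primo_explanation` carrying an instance and feature
#'   scaling.
#' @param path optional file path for the SVG.
#' @param z_span half-width of the displayed z-axis (default 3).
#' @return A list of class `primo_render`: `svg` (character), `text`
#'   (character vector of lines), and `geometry` (data frame with the band
#'   and marker x-coordinates per feature, for geometric checks).
#' @export
render_explanation <- function(explanation, path = NULL, z_span = 3) {
  e <- explanation
  feats <- e$partition$features
  if (is.null(feats) || is.null(e$instance))
    stop("rendering requires feature scaling and an instance in the explanation")
  p <- nrow(feats)
  zi <- (e$instance - feats$z_mean) / feats$z_sd
  x0 <- 60; x1 <- 580; row_h <- 56; top <- 50
  width <- 640; height <- top + p * row_h + 20
  zx <- function(z) x0 + (pmin(pmax(z, -z_span), z_span) + z_span) / (2 * z_span) * (x1 - x0)

  svg <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                   width, height),
           sprintf('<text x="%d" y="24" font-size="15" font-family="sans-serif">Prediction: %s</text>',
                   x0, e$prediction))
  geom <- data.frame(feature = seq_len(p), band_x0 = NA_real_,
                     band_x1 = NA_real_, marker_x = NA_real_,
                     constrained = FALSE)
  text_lines <- c(sprintf("Prediction: %s", e$prediction))
  bar_w <- 48
  for (f in seq_len(p)) {
    y <- top + (f - 1) * row_h + 20
    r <- e$ranges[e$ranges$feature == f, ]
    svg <- c(svg,
             sprintf('<text x="%d" y="%d" font-size="12" font-family="sans-serif">%s (%s)</text>',
                     x0, y - 6, feats$name[f], feats$units[f]),
             sprintf('<line x1="%g" y1="%d" x2="%g" y2="%d" stroke="#999" stroke-width="2"/>',
                     x0, y + 10, x1, y + 10))
    mx <- zx(zi[f])
    if (nrow(r) == 1) {
      bx0 <- zx(r$z_low); bx1 <- zx(r$z_high)
      svg <- c(svg,
               sprintf('<rect x="%g" y="%d" width="%g" height="14" fill="#7fb3d5" fill-opacity="0.7"/>',
                       bx0, y + 3, bx1 - bx0),
               if (r$z_low < -z_span)
                 sprintf('<text x="%g" y="%d" font-size="12">&#8592;</text>', x0 - 14, y + 14),
               if (r$z_high > z_span)
                 sprintf('<text x="%g" y="%d" font-size="12">&#8594;</text>', x1 + 4, y + 14),
               sprintf('<text x="%g" y="%d" font-size="10" font-family="sans-serif">z %s | %s</text>',
                       bx0, y + 30, fmt_range(r$z_low, r$z_high, "z"),
                       fmt_range(r$low, r$high, feats$units[f])))
      geom$band_x0[f] <- bx0; geom$band_x1[f] <- bx1; geom$constrained[f] <- TRUE
      band <- ascii_band(zi[f], r$z_low, r$z_high, z_span, bar_w)
    } else {
      svg <- c(svg, sprintf('<text x="%g" y="%d" font-size="10" font-family="sans-serif" fill="#666">no constraint</text>',
                            x0, y + 30))
      band <- ascii_band(zi[f], NA, NA, z_span, bar_w)
    }
    svg <- c(svg, sprintf('<circle cx="%g" cy="%d" r="5" fill="#c0392b"/>', mx, y + 10))
    geom$marker_x[f] <- mx
    text_lines <- c(text_lines, sprintf("%-24s |%s| %s", substr(feats$name[f], 1, 24),
                                        band,
                                        if (nrow(r) == 1)
                                          fmt_range(r$low, r$high, feats$units[f])
                                        else "no constraint"))
  }
  svg <- c(svg, "</svg>")
  svg <- paste(svg[!vapply(svg, is.null, logical(1))], collapse = "\n")
  if (!is.null(path)) writeLines(svg, path)
  structure(list(svg = svg, text = text_lines, geometry = geom),
            class = "primo_render")
}

fmt_range <- function(lo, hi, unit) {
  f <- function(v) if (is.infinite(v)) (if (v < 0) "-open" else "open+")
                   else format(signif(v, 3))
  sprintf("[%s, %s) %s", f(lo), f(hi), unit)
}

ascii_band <- function(z, zlo, zhi, span, w) {
  pos <- function(v) pmin(pmax(round((pmin(pmax(v, -span), span) + span) /
                                       (2 * span) * (w - 1)) + 1, 1), w)
  chars <- rep(".", w)
  if (!is.na(zlo)) {
    lo <- pos(zlo); hi <- pos(zhi)
    chars[lo:hi] <- "="
  }
  chars[pos(z)] <- "O"
  paste(chars, collapse = "")
}

#' @export
print.primo_render <- function(x, ...) {
  cat(paste(x$text, collapse = "\n"), "\n")
  invisible(x)
}
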