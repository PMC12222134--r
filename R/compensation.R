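# Adaptive color compensation: underwater absorption attenuates red first,
# so the weakly transmitted channels are boosted toward the dominant one.
# The compensation coefficients are ratios of the ordered channel means:
#   m = (Imax - Imin) / (Imax + Imin),  n = (Imax - Imid) / (Imax + Imid)
# and the attenuated channels are lifted per pixel by m (resp. n) times the
# dominant channel.

#' Rank the color channels by mean intensity
#'
#' Computes the per-channel arithmetic means, orders them (ties broken by the
#' fixed channel priority R < G < B: the lower index takes the higher rank
#' slot) and derives the two compensation coefficients from the ordered
#' scalar means.
#'
#' @param img Image array (see [as_image()]).
#' @return An object of class `channel_ranking`: list with `means` (named R,
#'   G, B), `max_channel`, `mid_channel`, `min_channel` (one of `"R"`, `"G"`,
#'   `"B"`), coefficients `m`, `n`, and `degenerate` (`TRUE` for an all-black
#'   image, where both coefficients are defined as 0).
#' @export
rank_channels <- function(img) {
  img <- as_image(img)
  means <- c(R = mean(img[, , 1L]), G = mean(img[, , 2L]),
             B = mean(img[, , 3L]))
  ord <- order(-means, seq_along(means))  # stable: R < G < B on ties
  labs <- names(means)[ord]
  mx <- means[ord[1L]]; md <- means[ord[2L]]; mn <- means[ord[3L]]
  degenerate <- (mx + mn) == 0  # all-black image
  m <- if (degenerate) 0 else (mx - mn) / (mx + mn)
  n <- if ((mx + md) == 0) 0 else (mx - md) / (mx + md)
  structure(list(means = means,
                 max_channel = labs[1L], mid_channel = labs[2L],
                 min_channel = labs[3L],
                 m = unname(m), n = unname(n), degenerate = degenerate),
            class = "channel_ranking")
}

#' @export
print.channel_ranking <- function(x, ...) {
  cat("channel ranking: ", x$max_channel, " >= ", x$mid_channel, " >= ",
      x$min_channel, "\n", sep = "")
  cat(sprintf("  means  R=%.4f G=%.4f B=%.4f\n",
              x$means["R"], x$means["G"], x$means["B"]))
  cat(sprintf("  m=%.6f n=%.6f%s\n", x$m, x$n,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Adaptive color compensation
#'
#' Lifts the mid- and minimum-mean channels toward the dominant channel,
#' per pixel: `I_mid' = I_mid + n * I_max` and `I_min' = I_min + m * I_max`,
#' with the dominant channel left unchanged; the result is clipped to
#' \[0, 1\]. Achromatic images (equal channel means) pass through unchanged,
#' as does the degenerate all-black image.
#'
#' @param img Image array.
#' @param ranking Optional precomputed [rank_channels()] result.
#' @return The color-compensated image.
#' @export
compensate_colors <- function(img, ranking = rank_channels(img)) {
  img <- as_image(img)
  if (ranking$degenerate) return(img)
  idx <- c(R = 1L, G = 2L, B = 3L)
  out <- img
  mx <- img[, , idx[[ranking$max_channel]]]
  out[, , idx[[ranking$mid_channel]]] <-
    img[, , idx[[ranking$mid_channel]]] + ranking$n * mx
  out[, , idx[[ranking$min_channel]]] <-
    img[, , idx[[ranking$min_channel]]] + ranking$m * mx
  out[] <- pmin(pmax(out, 0), 1)
  out
}

#' Spread between the largest and smallest channel mean
#'
#' A scalar summary of the color cast: 0 for a perfectly balanced image.
#'
#' @param img Image array.
#' @return `max(channel means) - min(channel means)`.
#' @export
channel_mean_spread <- function(img) {
  img <- as_image(img)
  m <- c(mean(img[, , 1L]), mean(img[, , 2L]), mean(img[, , 3L]))
  max(m) - min(m)
}
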