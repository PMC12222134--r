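# Multi-weight pyramid fusion. Each input is scored per pixel by contrast
# (Laplacian response), colorfulness/brightness (RGB deviation from
# luminance) and saliency (distance of the smoothed luminance from the
# global mean); the normalized weights drive a multi-band Laplacian-pyramid
# blend, which avoids the seams a flat per-pixel blend would create.

laplacian_3x3 <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
binomial_5 <- c(1, 4, 6, 4, 1) / 16

#' Contrast weight map
#'
#' Absolute response of the 3x3 Laplacian applied to the luminance channel
#' (mirror borders): large on edges and fine detail, zero on flat regions.
#'
#' @param img Image array.
#' @return `H x W` nonnegative matrix.
#' @export
contrast_weight <- function(img) {
  abs(.conv2_reflect_cpp(luminance(img), laplacian_3x3))
}

#' Brightness (colorfulness) weight map
#'
#' Root-mean-square deviation of the R, G, B channels from the luminance
#' channel: `sqrt(((R-L)^2 + (G-L)^2 + (B-L)^2) / 3)`. Zero on achromatic
#' pixels, at most `sqrt(2/3)` on the RGB cube.
#'
#' @param img Image array.
#' @return `H x W` nonnegative matrix.
#' @export
brightness_weight <- function(img) {
  img <- as_image(img)
  L <- luminance(img)
  d <- (matrix(img[, , 1L], nrow(L)) - L)^2 +
       (matrix(img[, , 2L], nrow(L)) - L)^2 +
       (matrix(img[, , 3L], nrow(L)) - L)^2
  sqrt(d / 3)
}

#' Saliency weight map
#'
#' Absolute difference between the Gaussian-smoothed luminance (sigma in
#' pixels) and the global luminance mean; highlights regions that stand out
#' from the scene's average brightness. Invariant to adding a constant to
#' the luminance.
#'
#' @param img Image array.
#' @param sigma Smoothing scale in pixels.
#' @return `H x W` nonnegative matrix.
#' @export
saliency_weight <- function(img, sigma = 5) {
  L <- luminance(img)
  abs(.conv_sep_cpp(L, gaussian_kernel_1d(sigma)) - mean(L))
}

#' Per-input fusion weights, normalized across inputs
#'
#' For each input `k`: `W_k = W_C + W_L + W_S`; the normalized maps are
#' `(W_k + delta) / sum_j (W_j + delta)`, which sum to 1 at every pixel and
#' stay defined on flat (all-zero-weight) regions.
#'
#' @param inputs List of >= 2 image arrays with equal shapes (a single
#'   input is accepted and receives the constant weight 1).
#' @param delta Regularizer added to every combined map.
#' @param saliency_sigma Smoothing scale for [saliency_weight()].
#' @return Object of class `weight_stack`: list with `combined` and
#'   `normalized` (lists of `H x W` matrices), plus the per-cue maps.
#' @export
normalize_weight_stack <- function(inputs, delta = 1e-3, saliency_sigma = 5) {
  stopifnot(is.list(inputs), length(inputs) >= 1L)
  inputs <- lapply(inputs, as_image)
  d1 <- dim(inputs[[1L]])
  if (!all(vapply(inputs, function(x) identical(dim(x), d1), logical(1))))
    stop("all fusion inputs must have the same shape")
  wc <- lapply(inputs, contrast_weight)
  wl <- lapply(inputs, brightness_weight)
  ws <- lapply(inputs, saliency_weight, sigma = saliency_sigma)
  comb <- Map(function(a, b, c) a + b + c, wc, wl, ws)
  tot <- Reduce(`+`, comb) + length(comb) * delta
  norm <- lapply(comb, function(w) (w + delta) / tot)
  structure(list(contrast = wc, brightness = wl, saliency = ws,
                 combined = comb, normalized = norm, delta = delta),
            class = "weight_stack")
}

#' Gaussian pyramid
#'
#' Smooth with the separable 5-tap binomial kernel (1,4,6,4,1)/16 (mirror
#' borders), then decimate by 2 (keeping rows/cols 1, 3, 5, ... so level
#' sizes follow the ceiling-halving rule).
#'
#' @param x `H x W` matrix.
#' @param depth Number of levels (level 1 is the input resolution).
#' @return List of matrices, class `image_pyramid`.
#' @export
gaussian_pyramid <- function(x, depth = 5L) {
  stopifnot(is.matrix(x), depth >= 1)
  if (depth > floor(log2(min(dim(x)))) + 1)
    stop("image too small for depth ", depth, "; maximum feasible depth is ",
         floor(log2(min(dim(x)))) + 1)
  levels <- vector("list", depth)
  levels[[1L]] <- x
  for (l in seq_len(depth - 1L)) {
    sm <- .conv_sep_cpp(levels[[l]], binomial_5)
    levels[[l + 1L]] <- sm[seq(1L, nrow(sm), by = 2L),
                           seq(1L, ncol(sm), by = 2L), drop = FALSE]
  }
  structure(levels, class = "image_pyramid")
}

#' Laplacian pyramid
#'
#' Band-pass levels `L_l = G_l - upsample(G_{l+1})` with the last level the
#' Gaussian residual; [collapse_pyramid()] inverts it exactly (it uses the
#' same bilinear upsampling).
#'
#' @param x `H x W` matrix.
#' @param depth Number of levels.
#' @return List of matrices, class `image_pyramid`.
#' @export
laplacian_pyramid <- function(x, depth = 5L) {
  g <- gaussian_pyramid(x, depth)
  out <- vector("list", depth)
  for (l in seq_len(depth - 1L)) {
    up <- .resize_bilinear_cpp(g[[l + 1L]], nrow(g[[l]]), ncol(g[[l]]))
    out[[l]] <- g[[l]] - up
  }
  out[[depth]] <- g[[depth]]
  structure(out, class = "image_pyramid")
}

#' Collapse a Laplacian pyramid back to an image plane
#'
#' @param pyr An `image_pyramid` from [laplacian_pyramid()] (or a plain
#'   list of detail levels plus the coarse residual).
#' @return The reconstructed matrix.
#' @export
collapse_pyramid <- function(pyr) {
  depth <- length(pyr)
  acc <- pyr[[depth]]
  for (l in rev(seq_len(depth - 1L)))
    acc <- pyr[[l]] + .resize_bilinear_cpp(acc, nrow(pyr[[l]]), ncol(pyr[[l]]))
  acc
}

#' Multi-weight Laplacian-pyramid fusion
#'
#' Each input channel is decomposed into a Laplacian pyramid and each
#' normalized weight map into a Gaussian pyramid; fused level
#' `l = sum_k L_l(input_k) * G_l(weight_k)`, collapsed and clipped to
#' \[0, 1\]. With a single input the result is the input itself.
#'
#' @param inputs List of image arrays with equal shapes.
#' @param stack Optional [normalize_weight_stack()] result built from
#'   `inputs` (computed if omitted).
#' @param depth Pyramid depth.
#' @return Fused image array.
#' @export
pyramid_fuse <- function(inputs, stack = NULL, depth = 5L) {
  stopifnot(is.list(inputs), length(inputs) >= 1L)
  inputs <- lapply(inputs, as_image)
  if (is.null(stack)) stack <- normalize_weight_stack(inputs)
  stopifnot(inherits(stack, "weight_stack"),
            length(stack$normalized) == length(inputs))
  wpyr <- lapply(stack$normalized, gaussian_pyramid, depth = depth)
  d <- dim(inputs[[1L]])
  out <- array(0, dim = d)
  for (c in 1:3) {
    lpyr <- lapply(inputs, function(x) laplacian_pyramid(x[, , c], depth))
    fused <- vector("list", depth)
    for (l in seq_len(depth)) {
      acc <- 0
      for (k in seq_along(inputs))
        acc <- acc + lpyr[[k]][[l]] * wpyr[[k]][[l]]
      fused[[l]] <- acc
    }
    out[, , c] <- collapse_pyramid(fused)
  }
  as_image(out, clip = TRUE)
}
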