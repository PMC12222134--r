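# No-reference underwater image quality scores: entropy, average gradient,
# UCIQE and UIQM. The community-standard coefficient sets are used
# (UCIQE: 0.4680/0.2745/0.2576; UIQM: 0.0282/0.2953/3.5753); block metrics
# (EME / logAMEE) run on full 8x8 blocks with natural logs, and degenerate
# (zero-dynamic-range) blocks contribute 0.

quantize8 <- function(x) as.integer(floor(x * 255 + 0.5))

#' Shannon entropy of an image (bits)
#'
#' Entropy of the 256-bin histogram of the 8-bit-quantized luminance, with
#' `0 log 0 = 0`; ranges over \[0, 8\] bits.
#'
#' @param img Image array.
#' @return Entropy in bits.
#' @export
img_entropy <- function(img) {
  p <- tabulate(quantize8(luminance(as_image(img))) + 1L, nbins = 256L)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Average gradient (sharpness proxy)
#'
#' Per channel on the 0–255 scale: mean over the `(H-1) x (W-1)` interior of
#' `sqrt((Gx^2 + Gy^2) / 2)` with forward differences; channel results are
#' averaged. Higher means sharper edges and texture.
#'
#' @param img Image array with `H, W >= 2`.
#' @return Average gradient in intensity levels per pixel.
#' @export
average_gradient <- function(img) {
  img <- as_image(img)
  H <- dim(img)[1L]; W <- dim(img)[2L]
  if (H < 2L || W < 2L) stop("average gradient needs at least 2 x 2 pixels")
  per_ch <- vapply(1:3, function(c) {
    x <- img[, , c] * 255
    gx <- x[-H, -1L] - x[-H, -W]   # forward difference along columns
    gy <- x[-1L, -W] - x[-H, -W]   # forward difference along rows
    mean(sqrt((gx^2 + gy^2) / 2))
  }, numeric(1))
  mean(per_ch)
}

#' UCIQE underwater color image quality
#'
#' `0.4680 * sigma_chroma + 0.2745 * con_lum + 0.2576 * mu_sat` in CIELab:
#' chroma standard deviation, luminance contrast (99th minus 1st percentile
#' of L*, divided by 100) and mean saturation `chroma / sqrt(chroma^2 +
#' L*^2)` (0 where both vanish).
#'
#' @param img Image array.
#' @param detail If `TRUE`, return the components alongside the score.
#' @return The score, or a list with `uciqe`, `sigma_chroma`, `con_lum`,
#'   `mu_sat`.
#' @export
uciqe <- function(img, detail = FALSE) {
  lab <- rgb_to_lab(as_image(img))
  L <- as.vector(lab[, , 1L])
  chroma <- sqrt(as.vector(lab[, , 2L])^2 + as.vector(lab[, , 3L])^2)
  sig_c <- sqrt(mean((chroma - mean(chroma))^2))
  qs <- stats::quantile(L, c(0.01, 0.99), names = FALSE, type = 7)
  con_l <- (qs[2L] - qs[1L]) / 100
  denom <- sqrt(chroma^2 + L^2)
  sat <- ifelse(denom > 0, chroma / denom, 0)
  mu_s <- mean(sat)
  score <- 0.4680 * sig_c + 0.2745 * con_l + 0.2576 * mu_s
  if (detail) list(uciqe = score, sigma_chroma = sig_c, con_lum = con_l,
                   mu_sat = mu_s)
  else score
}

trimmed_mean <- function(x, alpha = 0.1) {
  n <- length(x)
  k <- floor(alpha * n)
  xs <- sort(x)
  if (2 * k >= n) return(mean(x))
  mean(xs[(k + 1L):(n - k)])
}

# Mean over full blocks of f(block); partial border blocks are ignored.
block_apply <- function(x, size, f) {
  H <- nrow(x) - nrow(x) %% size
  W <- ncol(x) - ncol(x) %% size
  if (H < size || W < size) return(0)
  x <- x[seq_len(H), seq_len(W), drop = FALSE]
  a <- array(x, dim = c(size, H / size, size, W / size))
  vals <- apply(a, c(2L, 4L), f)
  mean(vals)
}

sobel_x <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
sobel_y <- t(sobel_x)

# EME of a plane: mean over 8x8 blocks of log(max/min), doubled per the
# usual convention; blocks with min <= 0 contribute 0.
eme <- function(x, size = 8L) {
  2 * block_apply(x, size, function(b) {
    mx <- max(b); mn <- min(b)
    if (mn <= 0 || mx == mn) 0 else log(mx / mn)
  })
}

# PLIP-free logAMEE: minus the mean over blocks of w*log(w) with w the
# Michelson contrast (max-min)/(max+min); zero-range blocks contribute 0.
log_amee <- function(x, size = 8L) {
  -block_apply(x, size, function(b) {
    mx <- max(b); mn <- min(b)
    if (mx + mn == 0 || mx == mn) return(0)
    w <- (mx - mn) / (mx + mn)
    w * log(w)
  })
}

#' UIQM underwater image quality
#'
#' `0.0282 * UICM + 0.2953 * UISM + 3.5753 * UIConM` where UICM measures
#' colorfulness via alpha-trimmed (alpha = 0.1) means and variances of the
#' opponent channels `RG = R - G` and `YB = (R + G)/2 - B` (0–255 scale),
#' UISM is the luminance-weighted EME of the Sobel-edge-weighted channels
#' (8x8 blocks) and UIConM the simplified (PLIP-free) logAMEE of the
#' luminance.
#'
#' @param img Image array.
#' @param detail If `TRUE`, also return `uicm`, `uism`, `uiconm`.
#' @return The score, or a list with the three sub-scores.
#' @export
uiqm <- function(img, detail = FALSE) {
  img <- as_image(img)
  R <- img[, , 1L] * 255; G <- img[, , 2L] * 255; B <- img[, , 3L] * 255
  rg <- as.vector(R - G); yb <- as.vector((R + G) / 2 - B)
  mu_rg <- trimmed_mean(rg); mu_yb <- trimmed_mean(yb)
  s2_rg <- mean((rg - mu_rg)^2); s2_yb <- mean((yb - mu_yb)^2)
  uicm <- -0.0268 * sqrt(mu_rg^2 + mu_yb^2) + 0.1586 * sqrt(s2_rg + s2_yb)
  lambda <- c(0.299, 0.587, 0.114)
  uism <- 0
  for (c in 1:3) {
    x <- img[, , c]
    e <- sqrt(.conv2_reflect_cpp(x, sobel_x)^2 +
              .conv2_reflect_cpp(x, sobel_y)^2)
    uism <- uism + lambda[c] * eme(e * x)
  }
  uiconm <- log_amee(luminance(img))
  score <- 0.0282 * uicm + 0.2953 * uism + 3.5753 * uiconm
  if (detail) list(uiqm = score, uicm = uicm, uism = uism, uiconm = uiconm)
  else score
}

#' Score one image with all four quality metrics
#'
#' @param img Image array.
#' @return A one-row data frame with columns `uciqe`, `uiqm`, `uicm`,
#'   `uism`, `uiconm`, `ag`, `entropy`.
#' @export
quality_report <- function(img) {
  u <- uiqm(img, detail = TRUE)
  data.frame(uciqe = uciqe(img), uiqm = u$uiqm, uicm = u$uicm,
             uism = u$uism, uiconm = u$uiconm, ag = average_gradient(img),
             entropy = img_entropy(img))
}

#' Batch quality scoring
#'
#' Scores a set of image files and (optionally) writes a CSV with one row
#' per image: `file, uciqe, uiqm, uicm, uism, uiconm, ag, entropy`.
#'
#' @param paths Character vector of image file paths.
#' @param out Optional CSV output path.
#' @return The report data frame, invisibly when `out` is given.
#' @export
score_images <- function(paths, out = NULL) {
  rows <- lapply(paths, function(p) cbind(file = basename(p),
                                          quality_report(read_image(p))))
  rep <- do.call(rbind, rows)
  if (!is.null(out)) {
    utils::write.csv(rep, out, row.names = FALSE)
    return(invisible(rep))
  }
  rep
}
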