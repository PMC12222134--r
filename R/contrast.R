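# Contrast enhancement: tile-wise contrast-limited histogram equalization
# (CLAHE) on the value channel, followed by adaptive gamma correction whose
# per-level exponent 1 - cdf_w(l) comes from a weighted histogram
# distribution, so dark levels are lifted without crushing the highlights.

#' CLAHE parameters
#'
#' @param tiles_row,tiles_col Tile grid size (M rows x N cols of blocks).
#' @param clip_limit Histogram cap as a multiple of the uniform bin height
#'   (`Inf` disables clipping, plain adaptive HE).
#' @param bins Histogram bin count (>= 2).
#' @return An object of class `clahe_params`.
#' @export
clahe_params <- function(tiles_row = 8L, tiles_col = 8L, clip_limit = 2.0,
                         bins = 256L) {
  stopifnot(tiles_row >= 1, tiles_col >= 1, clip_limit > 0, bins >= 2)
  structure(list(tiles_row = as.integer(tiles_row),
                 tiles_col = as.integer(tiles_col),
                 clip_limit = clip_limit, bins = as.integer(bins)),
            class = "clahe_params")
}

#' Clip a histogram and redistribute the excess
#'
#' Bins are capped at `ceiling(clip_limit * total / nbins)`; the excised
#' mass is spread uniformly over all bins, and the cap-and-spread pass is
#' repeated until the residual excess falls below one count. Total mass is
#' conserved exactly. A cap too small to hold the mass (`cap * nbins <=
#' total`) returns the fully flattened (uniform) histogram.
#'
#' @param hist Nonnegative per-bin counts.
#' @param clip_limit Positive multiple of the uniform bin height.
#' @return Clipped histogram (possibly non-integer), same length and sum.
#' @export
clip_redistribute <- function(hist, clip_limit) {
  stopifnot(is.numeric(hist), all(hist >= 0), clip_limit > 0)
  total <- sum(hist)
  nb <- length(hist)
  if (total == 0 || !is.finite(clip_limit)) return(hist)
  cap <- ceiling(clip_limit * total / nb)
  if (cap * nb <= total) return(rep(total / nb, nb))
  h <- hist
  repeat {
    excess <- sum(pmax(h - cap, 0))
    if (excess < 1) break
    h <- pmin(h, cap) + excess / nb
  }
  h
}

# Tile index (1..m) for positions 1..n split into m near-equal runs.
tile_index <- function(n, m) floor((seq_len(n) - 1) * m / n) + 1L

#' Contrast-limited adaptive histogram equalization
#'
#' The channel is split into `tiles_row x tiles_col` non-overlapping blocks;
#' each block's histogram is clipped ([clip_redistribute()]) and equalized
#' (levels map to their cumulative distribution values), and every pixel is
#' remapped by bilinear interpolation between the four surrounding tile
#' mappings (clamped to the available tiles at the borders).
#'
#' @param channel `H x W` matrix in \[0, 1\].
#' @param params [clahe_params()].
#' @return Equalized channel in \[0, 1\].
#' @export
clahe <- function(channel, params = clahe_params()) {
  channel <- check_gray(channel)
  stopifnot(inherits(params, "clahe_params"))
  H <- nrow(channel); W <- ncol(channel)
  M <- params$tiles_row; N <- params$tiles_col; nb <- params$bins
  if (H %/% M < 2L || W %/% N < 2L)
    stop("tiles smaller than 2 x 2: reduce the tile grid")
  lev <- matrix(as.integer(floor(channel * (nb - 1L) + 0.5)), H, W)
  tr <- tile_index(H, M)          # tile row of each image row
  tc <- tile_index(W, N)          # tile col of each image col
  tile_of <- matrix(tr, H, W) + (matrix(tc, H, W, byrow = TRUE) - 1L) * M
  # per-tile clipped histogram -> cdf mapping (lut rows: tiles, cols: level)
  lut <- matrix(0, M * N, nb)
  for (t in seq_len(M * N)) {
    cnt <- tabulate(lev[tile_of == t] + 1L, nbins = nb)
    h <- clip_redistribute(cnt, params$clip_limit)
    lut[t, ] <- cumsum(h) / sum(h)
  }
  # tile centres (pixel coordinates) for the bilinear blend
  cy <- vapply(seq_len(M), function(m) mean(which(tr == m)), numeric(1))
  cx <- vapply(seq_len(N), function(n) mean(which(tc == n)), numeric(1))
  row_lo <- pmin(pmax(findInterval(seq_len(H), cy), 1L), M)
  col_lo <- pmin(pmax(findInterval(seq_len(W), cx), 1L), N)
  row_hi <- pmin(row_lo + 1L, M)
  col_hi <- pmin(col_lo + 1L, N)
  wy <- ifelse(row_hi > row_lo,
               (seq_len(H) - cy[row_lo]) / (cy[row_hi] - cy[row_lo]), 0)
  wy <- pmin(pmax(wy, 0), 1)
  wx <- ifelse(col_hi > col_lo,
               (seq_len(W) - cx[col_lo]) / (cx[col_hi] - cx[col_lo]), 0)
  wx <- pmin(pmax(wx, 0), 1)
  RL <- matrix(row_lo, H, W); RH <- matrix(row_hi, H, W)
  CL <- matrix(col_lo, H, W, byrow = TRUE); CH <- matrix(col_hi, H, W, byrow = TRUE)
  WY <- matrix(wy, H, W); WX <- matrix(wx, H, W, byrow = TRUE)
  look <- function(trow, tcol) lut[cbind(trow + (tcol - 1L) * M,
                                         as.vector(lev) + 1L)]
  v00 <- look(as.vector(RL), as.vector(CL))
  v01 <- look(as.vector(RL), as.vector(CH))
  v10 <- look(as.vector(RH), as.vector(CL))
  v11 <- look(as.vector(RH), as.vector(CH))
  out <- (1 - WY) * ((1 - WX) * v00 + WX * v01) +
         WY * ((1 - WX) * v10 + WX * v11)
  matrix(pmin(pmax(out, 0), 1), H, W)
}

#' Adaptive gamma correction curve
#'
#' From the channel's histogram pdf: the weighted density
#' `pdf_w(l) = pdf_max * ((pdf(l) - pdf_min) / (pdf_max - pdf_min))^alpha`
#' and its normalized cumulative sum `cdf_w`. A degenerate histogram
#' (`pdf_max == pdf_min`, i.e. uniform) falls back to `pdf_w = pdf`.
#'
#' @param channel `H x W` matrix in \[0, 1\].
#' @param alpha Adjustment exponent (> 0); 0.5 by default downstream.
#' @param bins Number of intensity levels (levels `0 .. bins - 1`).
#' @return Object of class `agc_curve`: list with `l_max`, `pdf`, `pdf_w`,
#'   `cdf_w`, `alpha`, `sum_pdf_w`.
#' @export
agc_curve <- function(channel, alpha = 0.5, bins = 256L) {
  channel <- check_gray(channel)
  stopifnot(alpha > 0, bins >= 2)
  l_max <- bins - 1L
  lev <- as.integer(floor(channel * l_max + 0.5))
  pdf <- tabulate(lev + 1L, nbins = bins) / length(lev)
  pmx <- max(pdf); pmn <- min(pdf)
  pdf_w <- if (pmx == pmn) pdf else pmx * ((pdf - pmn) / (pmx - pmn))^alpha
  s <- sum(pdf_w)
  cdf_w <- if (s > 0) cumsum(pdf_w) / s else cumsum(pdf)
  structure(list(l_max = l_max, pdf = pdf, pdf_w = pdf_w, cdf_w = cdf_w,
                 alpha = alpha, sum_pdf_w = s),
            class = "agc_curve")
}

#' Adaptive gamma transform of intensity levels
#'
#' `T(l) = l_max * (l / l_max)^(1 - cdf_w(l))`, with `T(0) = 0` (including
#' when the exponent is 0). The exponent never exceeds 1, so the transform
#' brightens or preserves every level and fixes the endpoint
#' `T(l_max) = l_max`.
#'
#' @param curve An [agc_curve()] object.
#' @return Numeric vector `T` of length `l_max + 1` on the level scale
#'   (entry `l + 1` is `T(l)`).
#' @export
agc_transform <- function(curve) {
  stopifnot(inherits(curve, "agc_curve"))
  l <- 0:curve$l_max
  expo <- 1 - curve$cdf_w
  out <- curve$l_max * (l / curve$l_max)^expo
  out[1L] <- 0  # 0^e := 0, also when e == 0
  out
}

#' CLAHE plus adaptive gamma correction on the value channel
#'
#' The image is converted to HSV; V is equalized with [clahe()], then
#' remapped through the adaptive gamma LUT fitted to the equalized V
#' ([agc_curve()] / [agc_transform()]). H and S are untouched.
#'
#' @param img Image array (normally the normalized Retinex output).
#' @param clahe_p [clahe_params()].
#' @param alpha AGC adjustment exponent.
#' @param bins Level count for the AGC histogram.
#' @return Contrast-enhanced image.
#' @export
enhance_contrast <- function(img, clahe_p = clahe_params(), alpha = 0.5,
                             bins = 256L) {
  img <- as_image(img)
  hsv <- rgb_to_hsv(img)
  v <- clahe(hsv[, , 3L], clahe_p)
  curve <- agc_curve(v, alpha = alpha, bins = bins)
  tl <- agc_transform(curve)
  lev <- as.integer(floor(v * curve$l_max + 0.5))
  hsv[, , 3L] <- matrix(tl[lev + 1L] / curve$l_max, nrow(v), ncol(v))
  out <- hsv_to_rgb(hsv)
  as_image(out, clip = TRUE)
}
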