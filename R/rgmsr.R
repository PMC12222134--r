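# Retinex color recovery with a rolling-guidance illumination estimate.
#
# Classical SSR/MSR estimates illumination by Gaussian blurring, which also
# blurs large-scale edges and causes halos. The rolling guidance filter
# first erases small-scale texture with a Gaussian, then runs a few joint
# bilateral iterations whose guide is the previous iterate (input always the
# original channel), recovering the large-scale edges of the illumination
# field. Reflectance is log(I + eps) - log(illumination + eps), combined
# over several spatial scales with convex weights.

gaussian_kernel_1d <- function(sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Rolling guidance filter parameters
#'
#' @param sigma_s Spatial standard deviation in pixels (> 0). Controls which
#'   structure scale is treated as "texture" and smoothed away.
#' @param sigma_r Range standard deviation, relative to the channel's peak
#'   intensity (> 0). Smaller values preserve edges more strongly.
#' @param iterations Number of joint bilateral iterations `t` (>= 1).
#' @param coarse_sigma Scales larger than this are evaluated on a
#'   proportionally downsampled copy of the channel (the illumination field
#'   at scale `sigma_s` carries no detail below that scale, so a coarse grid
#'   represents it exactly enough); set to `Inf` to force full-resolution
#'   evaluation everywhere.
#' @return An object of class `rgf_params`.
#' @export
rgf_params <- function(sigma_s = 15, sigma_r = 0.1, iterations = 4L,
                       coarse_sigma = 5) {
  stopifnot(is.numeric(sigma_s), length(sigma_s) == 1L, sigma_s > 0,
            is.numeric(sigma_r), length(sigma_r) == 1L, sigma_r > 0,
            coarse_sigma > 0)
  if (!is.numeric(iterations) || length(iterations) != 1L ||
      iterations < 1 || iterations != floor(iterations))
    stop("iterations must be a positive integer (t >= 1)")
  structure(list(sigma_s = sigma_s, sigma_r = sigma_r,
                 iterations = as.integer(iterations),
                 coarse_sigma = coarse_sigma),
            class = "rgf_params")
}

#' Multi-scale Retinex parameters
#'
#' Defaults follow the classic MSR triple of surround scales with equal
#' weights; `epsilon` guards the logarithms.
#'
#' @param scales Spatial scales (pixels), one per Retinex component.
#' @param weights Convex combination weights, same length as `scales`;
#'   must sum to 1 (renormalized silently if off by < 1e-6).
#' @param epsilon Positive log-domain guard added to image and illumination.
#' @return An object of class `msr_params`.
#' @export
msr_params <- function(scales = c(15, 80, 250),
                       weights = rep(1 / length(scales), length(scales)),
                       epsilon = 1 / 255) {
  stopifnot(length(scales) >= 1L, all(scales > 0),
            length(weights) == length(scales), all(weights >= 0),
            epsilon > 0)
  s <- sum(weights)
  if (abs(s - 1) >= 1e-6) stop("MSR weights must sum to 1")
  structure(list(scales = as.numeric(scales), weights = weights / s,
                 epsilon = epsilon),
            class = "msr_params")
}

#' Gaussian illumination estimate
#'
#' Normalized Gaussian-weighted mean over a window truncated at radius
#' `ceiling(3 * sigma_s)`, mirror borders — the first (texture-erasing)
#' step of the rolling guidance filter.
#'
#' @param channel `H x W` numeric matrix.
#' @param sigma_s Spatial standard deviation in pixels.
#' @return Filtered matrix, same shape.
#' @export
gaussian_estimate <- function(channel, sigma_s) {
  stopifnot(is.matrix(channel), sigma_s > 0)
  .conv_sep_cpp(channel, gaussian_kernel_1d(sigma_s))
}

#' One joint bilateral iteration
#'
#' `J'(p) = (1/K_p) * sum_q exp(-|p-q|^2 / 2 sigma_s^2
#'          - (G(p)-G(q))^2 / 2 sigma_r^2) * I(q)` with the range kernel
#' evaluated on the guide `G`, window truncated at `ceiling(3 * sigma_s)`,
#' mirror borders. Exact windowed double sum (no approximation).
#'
#' @param input `H x W` matrix filtered toward the guide's structure.
#' @param guide `H x W` matrix supplying the range kernel (same shape).
#' @param params [rgf_params()].
#' @return Filtered matrix.
#' @export
joint_bilateral_step <- function(input, guide, params) {
  stopifnot(inherits(params, "rgf_params"), is.matrix(input),
            is.matrix(guide))
  if (!identical(dim(input), dim(guide)))
    stop("input and guide must have the same shape")
  .joint_bilateral_cpp(input, guide, params$sigma_s, params$sigma_r,
                       as.integer(ceiling(3 * params$sigma_s)))
}

rgf_core <- function(channel, params) {
  J <- gaussian_estimate(channel, params$sigma_s)
  for (t in seq_len(params$iterations))
    J <- joint_bilateral_step(channel, J, params)
  J
}

#' Rolling guidance filter
#'
#' Gaussian estimate followed by `iterations` joint bilateral steps whose
#' guide is the previous iterate and whose input is the original channel.
#' The channel is peak-normalized before filtering and rescaled after, so
#' the operator is positively homogeneous (`RGF(k x) = k RGF(x)`) and
#' `sigma_r` acts relative to the channel's dynamic range. Scales above
#' `params$coarse_sigma` are evaluated on a downsampled grid (see
#' [rgf_params()]).
#'
#' @param channel `H x W` numeric matrix (any nonnegative scale).
#' @param params [rgf_params()].
#' @return The estimated illumination channel, same shape.
#' @export
rolling_guidance_filter <- function(channel, params) {
  stopifnot(inherits(params, "rgf_params"), is.matrix(channel))
  peak <- max(abs(channel))
  if (peak == 0) return(channel)
  x <- channel / peak
  if (params$sigma_s > params$coarse_sigma) {
    f <- params$sigma_s / params$coarse_sigma
    H2 <- max(2L, as.integer(ceiling(nrow(x) / f)))
    W2 <- max(2L, as.integer(ceiling(ncol(x) / f)))
    fy <- nrow(x) / H2  # realized factor after the >= 2 clamp
    sig <- params$sigma_s / max(fy, ncol(x) / W2)
    p2 <- params; p2$sigma_s <- max(sig, 1)
    J <- rgf_core(.resize_bilinear_cpp(x, H2, W2), p2)
    J <- .resize_bilinear_cpp(J, nrow(x), ncol(x))
  } else {
    J <- rgf_core(x, params)
  }
  J * peak
}

#' Improved multi-scale Retinex reflectance
#'
#' Per channel `c` and scale `s_n`:
#' `R_n = log(I_c + eps) - log(RGF(I_c; sigma_s = s_n) + eps)`, combined as
#' `R = sum_n W_n R_n`. The output lives in the unbounded log domain; use
#' [normalize_reflectance()] for display.
#'
#' @param img Image array (normally the color-compensated image).
#' @param params [msr_params()].
#' @param rgf [rgf_params()]; its `sigma_s` is overridden by each scale.
#' @return `H x W x 3` numeric array of log-domain reflectance, finite
#'   everywhere.
#' @export
improved_msr <- function(img, params = msr_params(), rgf = rgf_params()) {
  img <- as_image(img)
  stopifnot(inherits(params, "msr_params"), inherits(rgf, "rgf_params"))
  out <- array(0, dim = dim(img))
  for (c in 1:3) {
    ch <- img[, , c]
    acc <- 0
    for (n in seq_along(params$scales)) {
      p <- rgf; p$sigma_s <- params$scales[n]
      illum <- rolling_guidance_filter(ch, p)
      acc <- acc + params$weights[n] *
        (log(ch + params$epsilon) - log(pmax(illum, 0) + params$epsilon))
    }
    out[, , c] <- acc
  }
  out
}

#' Map a log-domain reflectance to a displayable image
#'
#' Per-channel gain/offset mapping in the style of the classic MSR display
#' step: `mu - k sigma` maps to 0 and `mu + k sigma` to 1 (clipped), so the
#' channel mean lands at 0.5 regardless of the distribution's skew and the
#' mapping introduces no color cast of its own. A channel with
#' (numerically) zero spread maps to the constant 0.5.
#'
#' @param r `H x W x 3` finite numeric array (reflectance).
#' @param k Half-width of the displayed range in standard deviations.
#' @return Image array in \[0, 1\].
#' @export
normalize_reflectance <- function(r, k = 2.5) {
  if (!is.array(r) || length(dim(r)) != 3L || dim(r)[3L] != 3L ||
      any(!is.finite(r)))
    stop("reflectance must be a finite H x W x 3 array")
  stopifnot(k > 0)
  out <- array(0, dim = dim(r))
  for (c in 1:3) {
    ch <- r[, , c]
    mu <- mean(ch)
    sig <- sqrt(mean((ch - mu)^2))
    if (sig < 1e-12) out[, , c] <- 0.5
    else out[, , c] <- pmin(pmax((ch - mu) / (2 * k * sig) + 0.5, 0), 1)
  }
  out
}
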