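# Seeded synthetic scenes and a physically motivated underwater degradation
# model (wavelength-dependent attenuation + backscatter + noise + optional
# motion blur), so every pipeline stage is testable without external data.

#' Underwater degradation parameters
#'
#' Attenuation–backscatter image formation: per channel
#' `t_c = exp(-beta_c * d)`, `out = img * t_c + B_c * (1 - t_c)`, followed
#' by optional linear motion blur and clipped additive Gaussian noise.
#' Red light is absorbed fastest in water, hence the default
#' `beta_R > beta_G >= beta_B` and the blue-green background light.
#'
#' @param beta Per-channel attenuation coefficients (1/depth-unit).
#' @param d Scene distance in depth units (>= 0).
#' @param background Veiling light RGB triple in \[0, 1\].
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @param blur_len Motion blur length in pixels (0 disables).
#' @param blur_angle Motion blur angle in degrees.
#' @param seed RNG seed for the noise.
#' @return Object of class `degradation_params`.
#' @export
degradation_params <- function(beta = c(0.8, 0.3, 0.1), d = 1,
                               background = c(0.08, 0.42, 0.52),
                               noise_sigma = 0, blur_len = 0,
                               blur_angle = 0, seed = 1L) {
  stopifnot(length(beta) == 3L, all(beta >= 0), d >= 0,
            length(background) == 3L, all(background >= 0 & background <= 1),
            noise_sigma >= 0, blur_len >= 0)
  structure(list(beta = beta, d = d, background = background,
                 noise_sigma = noise_sigma, blur_len = blur_len,
                 blur_angle = blur_angle, seed = as.integer(seed)),
            class = "degradation_params")
}

# Normalized line kernel for linear motion blur.
motion_kernel <- function(len, angle_deg) {
  r <- ceiling(len / 2)
  n <- 2L * r + 1L
  k <- matrix(0, n, n)
  th <- angle_deg * pi / 180
  steps <- seq(-len / 2, len / 2, length.out = max(2L * ceiling(len) + 1L, 3L))
  for (s in steps) {
    i <- round(r + 1 + s * sin(th))
    j <- round(r + 1 + s * cos(th))
    if (i >= 1 && i <= n && j >= 1 && j <= n) k[i, j] <- k[i, j] + 1
  }
  k / sum(k)
}

#' Generate a procedural clean scene
#'
#' Deterministic for a fixed seed. Scenes combine a smooth color gradient,
#' high-chroma discs and star shapes (urchin/starfish-like), and a smoothed
#' texture field, so contrast, saliency and chroma statistics are all
#' exercised.
#'
#' @param seed RNG seed.
#' @param H,W Image size (>= 32 each).
#' @return Image array in \[0, 1\].
#' @export
generate_scene <- function(seed, H = 300L, W = 400L) {
  stopifnot(H >= 32L, W >= 32L)
  with_seed(seed, {
    yy <- matrix(seq(0, 1, length.out = H), H, W)
    xx <- matrix(seq(0, 1, length.out = W), H, W, byrow = TRUE)
    c1 <- runif(3, 0.15, 0.7); c2 <- runif(3, 0.3, 0.95)
    img <- array(0, dim = c(H, W, 3L))
    g <- (yy + xx) / 2
    for (c in 1:3) img[, , c] <- c1[c] + (c2[c] - c1[c]) * g
    # texture field: smoothed noise modulating mid-tones
    tex <- .conv_sep_cpp(matrix(runif(H * W, -1, 1), H, W),
                         gaussian_kernel_1d(2))
    for (c in 1:3) img[, , c] <- img[, , c] + 0.15 * tex
    # high-chroma discs
    for (b in seq_len(6L)) {
      ctr <- c(runif(1, 0.1, 0.9) * H, runif(1, 0.1, 0.9) * W)
      rad <- runif(1, 0.04, 0.12) * min(H, W)
      col <- runif(3)
      col[sample(3L, 1L)] <- runif(1, 0.85, 1)  # force one strong primary
      d2 <- (row(img[, , 1L]) - ctr[1L])^2 + (col(img[, , 1L]) - ctr[2L])^2
      mask <- pmax(1 - d2 / rad^2, 0)           # soft-edged disc
      for (c in 1:3) img[, , c] <- img[, , c] * (1 - mask) + col[c] * mask
    }
    # star shapes: radius modulated by cos(5 theta)
    for (s in seq_len(3L)) {
      ctr <- c(runif(1, 0.15, 0.85) * H, runif(1, 0.15, 0.85) * W)
      r0 <- runif(1, 0.05, 0.1) * min(H, W)
      ph <- runif(1, 0, 2 * pi)
      col <- c(runif(1, 0.75, 1), runif(1, 0.2, 0.6), runif(1, 0, 0.35))
      dy <- row(img[, , 1L]) - ctr[1L]; dx <- col(img[, , 1L]) - ctr[2L]
      rr <- sqrt(dy^2 + dx^2)
      th <- atan2(dy, dx)
      edge <- r0 * (0.55 + 0.45 * cos(5 * (th - ph)))
      mask <- rr <= edge
      for (c in 1:3) img[, , c][mask] <- col[c]
    }
    img[] <- pmin(pmax(img, 0), 1)
    # gray-world balance: a clean reference scene carries local chroma but
    # no global cast (casts are the degradation model's job)
    m <- c(mean(img[, , 1]), mean(img[, , 2]), mean(img[, , 3]))
    for (c in 1:3) img[, , c] <- img[, , c] * (mean(m) / m[c])
    as_image(img, clip = TRUE)
  })
}

#' Apply the underwater degradation model
#'
#' @param img Clean image array.
#' @param params [degradation_params()].
#' @return Degraded image array in \[0, 1\].
#' @export
degrade <- function(img, params = degradation_params()) {
  img <- as_image(img)
  out <- img
  tr <- exp(-params$beta * params$d)
  for (c in 1:3)
    out[, , c] <- img[, , c] * tr[c] + params$background[c] * (1 - tr[c])
  if (params$blur_len > 0) {
    k <- motion_kernel(params$blur_len, params$blur_angle)
    for (c in 1:3) out[, , c] <- .conv2_reflect_cpp(out[, , c], k)
  }
  if (params$noise_sigma > 0) {
    noise <- with_seed(params$seed,
                       array(rnorm(length(out), 0, params$noise_sigma),
                             dim = dim(out)))
    out <- out + noise
  }
  as_image(out, clip = TRUE)
}

#' Seeded fixture set spanning a degradation grid
#'
#' `n` clean/degraded pairs over a fixed grid of mild/strong color cast,
#' haze depth, sensor noise and motion blur. Deterministic for a fixed
#' seed; the manifest records every parameter.
#'
#' @param n Number of pairs (>= 1).
#' @param seed Base RNG seed.
#' @param H,W Image size.
#' @return List of records `list(clean, degraded, params, strong_cast)`
#'   with a `manifest` data frame attribute.
#' @export
make_fixture_set <- function(n = 20L, seed = 7L, H = 300L, W = 400L) {
  stopifnot(n >= 1L)
  beta_grid <- list(mild = c(0.35, 0.12, 0.06), strong = c(0.9, 0.3, 0.08))
  d_grid <- c(1.2, 2.5)
  noise_grid <- c(0, 0.01)
  blur_grid <- c(0, 5)
  combos <- expand.grid(cast = c("mild", "strong"), d = d_grid,
                        noise = noise_grid, blur = blur_grid,
                        stringsAsFactors = FALSE)
  out <- vector("list", n)
  man <- vector("list", n)
  for (i in seq_len(n)) {
    cmb <- combos[(i - 1L) %% nrow(combos) + 1L, ]
    sc_seed <- seed + 1000L * i
    clean <- generate_scene(sc_seed, H, W)
    p <- degradation_params(beta = beta_grid[[cmb$cast]], d = cmb$d,
                            noise_sigma = cmb$noise, blur_len = cmb$blur,
                            blur_angle = 30 * (i %% 6),
                            seed = sc_seed + 1L)
    out[[i]] <- list(clean = clean, degraded = degrade(clean, p), params = p,
                     strong_cast = cmb$cast == "strong")
    man[[i]] <- data.frame(id = i, cast = cmb$cast, d = cmb$d,
                           noise_sigma = cmb$noise, blur_len = cmb$blur,
                           blur_angle = 30 * (i %% 6), scene_seed = sc_seed)
  }
  attr(out, "manifest") <- do.call(rbind, man)
  out
}
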