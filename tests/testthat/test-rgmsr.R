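test_that("gaussian_estimate is exact against the direct-summation oracle", {
  set.seed(101)
  x <- matrix(runif(25), 5, 5)
  x[3, 3] <- 1  # impulse-dominated patch
  for (sigma in c(0.8, 1.5)) {
    expect_lt(max(abs(gaussian_estimate(x, sigma) -
                      gaussian_brute(x, sigma))), 1e-10)
  }
  imp <- matrix(0, 5, 5); imp[3, 3] <- 1
  expect_lt(max(abs(gaussian_estimate(imp, 0.9) -
                    gaussian_brute(imp, 0.9))), 1e-10)
})

test_that("gaussian_estimate preserves constants and contracts variance", {
  expect_lt(max(abs(gaussian_estimate(matrix(0.42, 6, 7), 2) - 0.42)), 1e-12)
  set.seed(7)
  noise <- matrix(runif(900), 30, 30)
  expect_lt(var(as.vector(gaussian_estimate(noise, 3))),
            var(as.vector(noise)))
})

test_that("joint bilateral step reduces to the Gaussian when the range kernel is flat", {
  set.seed(21)
  x <- matrix(runif(64), 8, 8)
  p <- rgf_params(sigma_s = 1.5, sigma_r = 0.1)
  # constant guide: range kernel identically 1
  expect_lt(max(abs(joint_bilateral_step(x, matrix(0.5, 8, 8), p) -
                    gaussian_estimate(x, 1.5))), 1e-12)
  # sigma_r -> infinity limit
  p_inf <- rgf_params(sigma_s = 1.5, sigma_r = 1e6)
  expect_lt(max(abs(joint_bilateral_step(x, x, p_inf) -
                    gaussian_estimate(x, 1.5))), 1e-8)
})

test_that("joint bilateral step is exact against the direct-summation oracle", {
  set.seed(33)
  input <- matrix(runif(49), 7, 7)
  guide <- matrix(runif(49), 7, 7)
  p <- rgf_params(sigma_s = 1.2, sigma_r = 0.15)
  expect_lt(max(abs(joint_bilateral_step(input, guide, p) -
                    jb_brute(input, guide, 1.2, 0.15))), 1e-10)
  expect_error(joint_bilateral_step(input, guide[1:6, ], p), "shape")
})

test_that("rolling guidance filtering recovers a step edge from texture", {
  set.seed(5)
  H <- 24; W <- 24
  step <- matrix(0.25, H, W); step[, (W / 2 + 1):W] <- 0.75
  textured <- pmin(pmax(step + 0.08 * sin(outer(1:H, 1:W, "+")), 0), 1)
  rms_after <- function(t) {
    p <- rgf_params(sigma_s = 2, sigma_r = 0.2, iterations = t)
    sqrt(mean((rolling_guidance_filter(textured, p) - step)^2))
  }
  expect_lt(rms_after(4), rms_after(1))
  # constants are fixed points for any iteration count
  p <- rgf_params(sigma_s = 3, sigma_r = 0.1, iterations = 3)
  expect_lt(max(abs(rolling_guidance_filter(matrix(0.6, 10, 10), p) - 0.6)),
            1e-12)
  expect_error(rgf_params(sigma_s = 2, sigma_r = 0.1, iterations = 0),
               "positive integer")
})

test_that("the coarse-grid evaluation of large scales tracks the exact filter", {
  set.seed(55)
  ch <- gaussian_estimate(matrix(runif(48 * 40), 48, 40), 1)
  exact <- rolling_guidance_filter(ch, rgf_params(6, 0.1, 2, coarse_sigma = Inf))
  coarse <- rolling_guidance_filter(ch, rgf_params(6, 0.1, 2, coarse_sigma = 3))
  expect_lt(max(abs(exact - coarse)), 0.02)
})

test_that("improved MSR obeys its algebraic identities", {
  # constant image -> zero reflectance
  cimg <- const_img(c(0.3, 0.5, 0.7), 12, 12)
  r0 <- improved_msr(cimg, msr_params(scales = 2, weights = 1),
                     rgf_params(sigma_s = 2))
  expect_lt(max(abs(r0)), 1e-12)

  img <- rand_img(77, 16, 16)
  rgf <- rgf_params(sigma_s = 2, sigma_r = 0.2, iterations = 2)
  # equal-weight multi-scale equals the mean of single-scale runs
  scales <- c(1.5, 3, 5)
  multi <- improved_msr(img, msr_params(scales, rep(1 / 3, 3)), rgf)
  singles <- lapply(scales, function(s)
    improved_msr(img, msr_params(s, 1), rgf))
  expect_lt(max(abs(multi - (singles[[1]] + singles[[2]] + singles[[3]]) / 3)),
            1e-12)
})

test_that("single-scale MSR with a flat range kernel is classical SSR", {
  img <- rand_img(13, 12, 12)
  eps <- 1 / 255
  rgf <- rgf_params(sigma_s = 2, sigma_r = 1e6, iterations = 3)
  got <- improved_msr(img, msr_params(scales = 2, weights = 1, epsilon = eps),
                      rgf)
  for (c in 1:3) {
    ssr <- log(img[, , c] + eps) -
      log(gaussian_estimate(img[, , c], 2) + eps)
    expect_lt(max(abs(got[, , c] - ssr)), 1e-8)
  }
})

test_that("reflectance is invariant to global intensity scaling", {
  img <- rand_img(3, 10, 10) * 0.5
  img <- as_image(img)
  rgf <- rgf_params(sigma_s = 2, sigma_r = 0.15, iterations = 2)
  mp <- msr_params(scales = c(1.5, 3), weights = c(0.5, 0.5),
                   epsilon = 1e-12)
  r1 <- improved_msr(img, mp, rgf)
  r2 <- improved_msr(as_image(img * 1.8, clip = FALSE), mp, rgf)
  expect_lt(max(abs(r1 - r2)), 1e-6)
})

test_that("normalize_reflectance centers each channel and preserves interior order", {
  expect_equal(unique(as.vector(
    normalize_reflectance(array(0, dim = c(6, 6, 3))))), 0.5)
  set.seed(8)
  r <- array(rnorm(50 * 50 * 3), dim = c(50, 50, 3))
  out <- normalize_reflectance(r)
  expect_true(all(out >= 0 & out <= 1))
  for (c in 1:3) {
    # Gaussian tails reach past mu +/- 2.5 sigma, so the display range is used
    expect_lt(min(out[, , c]), 0.01)
    expect_gt(max(out[, , c]), 0.99)
    # interior ordering is preserved (clipping only touches the tails)
    mu <- mean(r[, , c]); sig <- sd(as.vector(r[, , c]))
    interior <- abs(r[, , c] - mu) < 2.4 * sig
    expect_equal(order(r[, , c][interior]), order(out[, , c][interior]))
  }
  # the channel mean maps to mid-gray even for a skewed distribution
  sk <- array(rexp(3000), dim = c(10, 100, 3))
  outs <- normalize_reflectance(sk)
  for (c in 1:3) {
    ch <- sk[, , c]
    at_mean <- which.min(abs(ch - mean(ch)))
    expect_equal(outs[, , c][at_mean], 0.5, tolerance = 0.02)
  }
})

test_that("the full rgmsr stage maps [0,1] images into [0,1]", {
  img <- rand_img(29, 20, 24)
  out <- normalize_reflectance(
    improved_msr(img, msr_params(scales = c(2, 4), weights = c(0.5, 0.5)),
                 rgf_params(sigma_s = 2, iterations = 2)))
  expect_true(all(out >= 0 & out <= 1))
})
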