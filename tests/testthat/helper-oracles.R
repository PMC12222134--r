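# Brute-force reference implementations, independent of the package's
# compiled filters: direct double-loop sums with the same mirror-border
# convention, exhaustive PR-curve integration, and dense attention.

reflect_idx <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# Direct evaluation of the normalized Gaussian windowed mean.
gaussian_brute <- function(x, sigma) {
  r <- ceiling(3 * sigma)
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    num <- 0; den <- 0
    for (di in -r:r) for (dj in -r:r) {
      w <- exp(-(di^2 + dj^2) / (2 * sigma^2))
      num <- num + w * x[reflect_idx(i + di, H), reflect_idx(j + dj, W)]
      den <- den + w
    }
    out[i, j] <- num / den
  }
  out
}

# Direct evaluation of one joint bilateral step (range kernel on the guide).
jb_brute <- function(input, guide, sigma_s, sigma_r) {
  r <- ceiling(3 * sigma_s)
  H <- nrow(input); W <- ncol(input)
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    num <- 0; den <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- reflect_idx(i + di, H); jj <- reflect_idx(j + dj, W)
      w <- exp(-(di^2 + dj^2) / (2 * sigma_s^2) -
               (guide[i, j] - guide[ii, jj])^2 / (2 * sigma_r^2))
      num <- num + w * input[ii, jj]
      den <- den + w
    }
    out[i, j] <- num / den
  }
  out
}

# Direct 2-D correlation with mirror borders.
conv2_brute <- function(x, k) {
  rh <- (nrow(k) - 1) / 2; rw <- (ncol(k) - 1) / 2
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    s <- 0
    for (di in -rh:rh) for (dj in -rw:rw)
      s <- s + k[di + rh + 1, dj + rw + 1] *
        x[reflect_idx(i + di, H), reflect_idx(j + dj, W)]
    out[i, j] <- s
  }
  out
}

# AP as an explicit rectangle sum over the interpolated PR staircase.
ap_brute <- function(scores, is_tp, n_gt) {
  o <- order(-scores)
  is_tp <- is_tp[o]
  tp <- 0; fp <- 0
  rec <- numeric(0); prec <- numeric(0)
  for (i in seq_along(is_tp)) {
    if (is_tp[i]) tp <- tp + 1 else fp <- fp + 1
    rec <- c(rec, tp / n_gt)
    prec <- c(prec, tp / (tp + fp))
  }
  area <- 0
  prev_r <- 0
  for (i in seq_along(rec)) {
    p_max <- max(prec[i:length(prec)])
    area <- area + (rec[i] - prev_r) * p_max
    prev_r <- rec[i]
  }
  area
}

# Independent greedy matcher written over plain loops.
match_brute <- function(pred, gt, thresh) {
  flags <- logical(nrow(pred))
  for (img in unique(pred$image)) for (cl in unique(pred$class)) {
    p <- which(pred$image == img & pred$class == cl)
    p <- p[order(-pred$score[p])]
    g <- which(gt$image == img & gt$class == cl)
    taken <- rep(FALSE, length(g))
    for (d in p) {
      ious <- vapply(seq_along(g), function(j) {
        if (taken[j]) return(-1)
        iou(unlist(pred[d, c("x_min", "y_min", "x_max", "y_max")]),
            unlist(gt[g[j], c("x_min", "y_min", "x_max", "y_max")]))
      }, numeric(1))
      if (length(ious) && max(ious) >= thresh) {
        flags[d] <- TRUE
        taken[which.max(ious)] <- TRUE
      }
    }
  }
  flags
}

# Dense (unrouted) attention over all tokens, plus the local-context term.
dense_attention_oracle <- function(x, w_q, w_k, w_v, lce_kernel) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  xm <- matrix(x, H * W, C)
  Q <- xm %*% w_q; K <- xm %*% w_k; V <- xm %*% w_v
  A <- Q %*% t(K) / sqrt(C)
  P <- exp(A - apply(A, 1, max))
  P <- P / rowSums(P)
  O <- P %*% V
  out <- array(O, dim = c(H, W, C))
  for (c in 1:C) {
    v <- matrix(V[, c], H, W)
    lce <- matrix(0, H, W)
    kk <- lce_kernel[, , c]
    for (i in 1:H) for (j in 1:W) {
      s <- 0
      for (di in -2:2) for (dj in -2:2) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
          s <- s + kk[di + 3, dj + 3] * v[ii, jj]
      }
      lce[i, j] <- s
    }
    out[, , c] <- out[, , c] + lce
  }
  out
}

rand_img <- function(seed, H = 16, W = 16) {
  set.seed(seed)
  array(runif(H * W * 3), dim = c(H, W, 3))
}

const_img <- function(v, H = 8, W = 8) {
  array(rep(v, each = H * W), dim = c(H, W, 3))
}
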