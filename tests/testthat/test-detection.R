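test_that("IoU matches hand-computed overlaps", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1.0)
  expect_equal(iou(c(0, 0, 1, 1), c(2, 2, 3, 3)), 0.0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  expect_error(bbox(1, 1, 1, 2), "degenerate")
})

test_that("ECIoU loss reproduces the worked example and its geometry", {
  expect_equal(eclou_loss(c(1, 1, 3, 3), c(1, 1, 3, 3))$loss, 0)
  ex <- eclou_loss(c(1, 1, 3, 3), c(0, 0, 2, 2))
  expect_equal(ex$terms$iou, 1 / 7)
  expect_equal(ex$terms$v, 0)
  expect_equal(ex$terms$rho2_center, 2)
  expect_equal(ex$terms$c2, 18)
  expect_equal(ex$loss, 1 - 1 / 7 + 2 / 18, tolerance = 1e-9)
  expect_equal(ex$loss, 0.968254, tolerance = 1e-6)
  # terms recompose the loss exactly
  t <- eclou_loss(c(0, 0, 1, 3), c(0.5, 0.2, 2, 2.5))$terms
  recomposed <- 1 - t$iou + t$alpha * t$v + t$rho2_center / t$c2 +
    t$rho2_h / t$c2_h + t$rho2_w / t$c2_w
  expect_equal(eclou_loss(c(0, 0, 1, 3), c(0.5, 0.2, 2, 2.5))$loss,
               recomposed, tolerance = 1e-12)
})

test_that("ECIoU is nonnegative, zero only at coincidence, and pose invariant", {
  set.seed(70)
  for (i in 1:1000) {
    a <- c(runif(2, 0, 10), 0, 0); a[3:4] <- a[1:2] + runif(2, 0.1, 5)
    b <- c(runif(2, 0, 10), 0, 0); b[3:4] <- b[1:2] + runif(2, 0.1, 5)
    l <- eclou_loss(a, b)
    expect_gte(l$loss, 0)
    expect_gte(l$terms$c2, l$terms$rho2_center)
    expect_true(l$terms$iou >= 0 && l$terms$iou <= 1)
    if (i <= 50) {  # pose invariances on a subsample
      sh <- runif(2, -5, 5)
      expect_equal(eclou_loss(a + sh[c(1, 2, 1, 2)], b + sh[c(1, 2, 1, 2)])$loss,
                   l$loss, tolerance = 1e-9)
      s <- runif(1, 0.5, 3)
      expect_equal(eclou_loss(a * s, b * s)$loss, l$loss, tolerance = 1e-9)
    }
  }
  expect_equal(eclou_loss(c(2, 3, 4, 5), c(2, 3, 4, 5))$loss, 0)
})

test_that("ECIoU decreases monotonically as the prediction approaches the target", {
  gt <- c(4, 4, 6, 6)
  offs <- seq(3, 0, by = -0.25)
  losses <- vapply(offs, function(o)
    eclou_loss(gt + c(o, o, o, o), gt)$loss, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("precision and recall follow their definitions with a 0/0 flag", {
  expect_equal(precision_recall(8, 2, 0)$precision, 0.8)
  expect_equal(precision_recall(8, 0, 8)$recall, 0.5)
  pr <- precision_recall(0, 0, 0)
  expect_equal(pr$precision, 0)
  expect_false(pr$precision_defined)
})

test_that("average precision matches the worked example and the brute oracle", {
  expect_equal(average_precision(c(0.9, 0.8, 0.7), c(TRUE, FALSE, TRUE), 2),
               0.5 * 1.0 + 0.5 * (2 / 3), tolerance = 1e-12)
  expect_equal(average_precision(c(0.9, 0.8, 0.7), c(TRUE, FALSE, TRUE), 2),
               0.8333, tolerance = 1e-4)
  expect_equal(average_precision(c(0.5, 0.4), c(TRUE, TRUE), 2), 1.0)
  expect_equal(mean_average_precision(c(1.0, 0.5)), 0.75)
  expect_error(average_precision(0.4, TRUE, 0), "n_gt")
  set.seed(71)
  for (i in 1:50) {
    n <- sample(1:10, 1)
    sc <- runif(n)
    tp <- runif(n) < 0.5
    ngt <- sample(max(1, sum(tp)):(sum(tp) + 3), 1)
    expect_equal(average_precision(sc, tp, ngt), ap_brute(sc, tp, ngt),
                 tolerance = 1e-12)
  }
})

test_that("greedy matching follows the single-match threshold rule", {
  gt <- data.frame(image = "a", class = "urchin",
                   x_min = 0, y_min = 0, x_max = 2, y_max = 2)
  pred <- data.frame(image = "a", class = "urchin",
                     x_min = c(0.1, 0.2), y_min = c(0.1, 0.2),
                     x_max = c(2.1, 2.2), y_max = c(2.1, 2.2),
                     score = c(0.9, 0.8))
  m <- match_detections(pred, gt, 0.5)
  expect_equal(m$is_tp, c(TRUE, FALSE))
  # IoU 0.49 at threshold 0.5 is a miss
  p49 <- data.frame(image = "a", class = "urchin", x_min = 0, y_min = 0,
                    x_max = 2 * 0.49 / (2 - 0.49) + 0, y_max = 2,
                    score = 0.9)
  # width chosen so that inter/union = 0.49 exactly: w*2 / (4 + 2w - 2w)
  p49$x_max <- 0.98
  expect_false(match_detections(p49, gt, 0.5)$is_tp)
  expect_true(match_detections(p49, gt, 0.49)$is_tp)
})

test_that("greedy matching agrees with the independent brute matcher", {
  set.seed(72)
  for (rep in 1:10) {
    gt <- data.frame(image = sample(c("a", "b"), 8, TRUE),
                     class = sample(c("u", "s"), 8, TRUE),
                     x_min = runif(8, 0, 10), y_min = runif(8, 0, 10))
    gt$x_max <- gt$x_min + runif(8, 1, 4)
    gt$y_max <- gt$y_min + runif(8, 1, 4)
    jit <- function(v, s) v + rnorm(length(v), 0, s)
    pred <- gt
    pred$x_min <- jit(gt$x_min, 0.7); pred$x_max <- jit(gt$x_max, 0.7)
    pred$y_min <- jit(gt$y_min, 0.7); pred$y_max <- jit(gt$y_max, 0.7)
    bad <- pred$x_max <= pred$x_min; pred$x_max[bad] <- pred$x_min[bad] + 0.5
    bad <- pred$y_max <= pred$y_min; pred$y_max[bad] <- pred$y_min[bad] + 0.5
    pred$score <- runif(8)
    got <- match_detections(pred, gt, 0.5)$is_tp
    expect_equal(got, match_brute(pred, gt, 0.5))
  }
})

test_that("end-to-end detection evaluation returns per-class AP and mAP", {
  gt <- data.frame(image = "a", class = c("u", "u", "s"),
                   x_min = c(0, 5, 0), y_min = c(0, 5, 5),
                   x_max = c(2, 7, 2), y_max = c(2, 7, 7))
  pred <- data.frame(image = "a", class = c("u", "u", "s"),
                     x_min = c(0, 9, 0), y_min = c(0, 9, 5),
                     x_max = c(2, 10, 2), y_max = c(2, 10, 7),
                     score = c(0.9, 0.8, 0.7))
  res <- evaluate_detections(pred, gt)
  expect_equal(res$per_class$ap[res$per_class$class == "s"], 1.0)
  expect_equal(res$per_class$ap[res$per_class$class == "u"], 0.5)
  expect_equal(res$map, 0.75)
})

test_that("BRA with k = S^2 equals dense attention plus local context", {
  set.seed(80)
  H <- 8; W <- 8; C <- 4
  x <- array(rnorm(H * W * C), dim = c(H, W, C))
  w_q <- matrix(rnorm(C * C), C, C)
  w_k <- matrix(rnorm(C * C), C, C)
  w_v <- matrix(rnorm(C * C), C, C)
  lce <- array(rnorm(5 * 5 * C, 0, 0.1), dim = c(5, 5, C))
  dense <- dense_attention_oracle(x, w_q, w_k, w_v, lce)
  for (S in c(1, 2, 4)) {
    got <- bra_forward(x, S, S^2, w_q, w_k, w_v, lce)
    expect_lt(max(abs(got - dense)), 1e-8)
  }
})

test_that("BRA validates its region and top-k contract", {
  x <- array(rnorm(6 * 6 * 2), dim = c(6, 6, 2))
  w <- diag(2); lce <- array(0, dim = c(5, 5, 2))
  expect_error(bra_forward(x, 4, 1, w, w, w, lce), "divide")
  expect_error(bra_forward(x, 2, 5, w, w, w, lce), "1..S")
  # routed attention is a proper softmax: rows of the attention map sum to 1,
  # so a constant-value projection returns that constant plus local context
  xc <- array(rnorm(8 * 8 * 2), dim = c(8, 8, 2))
  w_v0 <- matrix(0, 2, 2)
  out <- bra_forward(xc, 2, 1, w, w, w_v0, lce)
  expect_lt(max(abs(out)), 1e-12)  # V = 0 -> softmax rows * 0 + LCE(0)
})
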