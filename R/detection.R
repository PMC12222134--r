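# Pure-math detection-side components: the IoU family with the combined
# ECIoU regression loss, greedy IoU matching, precision / recall / AP /
# mAP, and a deterministic bi-level routing attention (BRA) forward pass.

#' Axis-aligned bounding box
#'
#' Corner format with continuous coordinates; width and height are
#' `x_max - x_min` and `y_max - y_min` (no +1 pixel convention).
#'
#' @param x_min,y_min,x_max,y_max Corner coordinates, `x_max > x_min`,
#'   `y_max > y_min`.
#' @return Object of class `bbox`.
#' @export
bbox <- function(x_min, y_min, x_max, y_max) {
  if (!all(is.finite(c(x_min, y_min, x_max, y_max))))
    stop("box coordinates must be finite")
  if (x_max <= x_min || y_max <= y_min)
    stop("degenerate box: need x_max > x_min and y_max > y_min")
  structure(list(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
                 w = x_max - x_min, h = y_max - y_min,
                 cx = (x_min + x_max) / 2, cy = (y_min + y_max) / 2),
            class = "bbox")
}

as_bbox <- function(b) {
  if (inherits(b, "bbox")) return(b)
  if (is.numeric(b) && length(b) == 4L) return(bbox(b[1], b[2], b[3], b[4]))
  stop("expected a bbox or a numeric (x_min, y_min, x_max, y_max)")
}

#' Intersection over union of two boxes
#'
#' @param a,b Boxes ([bbox()] or length-4 numeric `(x_min, y_min, x_max,
#'   y_max)`).
#' @return IoU in \[0, 1\]; 0 for disjoint boxes.
#' @export
iou <- function(a, b) {
  a <- as_bbox(a); b <- as_bbox(b)
  iw <- min(a$x_max, b$x_max) - max(a$x_min, b$x_min)
  ih <- min(a$y_max, b$y_max) - max(a$y_min, b$y_min)
  inter <- max(iw, 0) * max(ih, 0)
  inter / (a$w * a$h + b$w * b$h - inter)
}

#' ECIoU bounding-box regression loss
#'
#' Combines the aspect-ratio penalty of CIoU with the explicit width/height
#' distance penalties of EIoU:
#' `loss = 1 - IoU + alpha v + rho2(b, b_gt)/c2 + rho2(h, h_gt)/c_h2 +
#' rho2(w, w_gt)/c_w2`, where `v = (4/pi^2)(atan(w_gt/h_gt) - atan(w/h))^2`,
#' `alpha = v / ((1 - IoU) + v)` (0 when both vanish), and `c2`, `c_w2`,
#' `c_h2` are the squared diagonal, width and height of the smallest
#' enclosing box.
#'
#' @param pred,gt Predicted and ground-truth boxes.
#' @return List with `loss` and `terms` (class `eclou_terms`): `iou`, `v`,
#'   `alpha`, `rho2_center`, `rho2_w`, `rho2_h`, `c2`, `c2_w`, `c2_h`.
#' @export
eclou_loss <- function(pred, gt) {
  p <- as_bbox(pred); g <- as_bbox(gt)
  i <- iou(p, g)
  v <- (4 / pi^2) * (atan(g$w / g$h) - atan(p$w / p$h))^2
  alpha <- if ((1 - i) + v == 0) 0 else v / ((1 - i) + v)
  ex_min <- min(p$x_min, g$x_min); ex_max <- max(p$x_max, g$x_max)
  ey_min <- min(p$y_min, g$y_min); ey_max <- max(p$y_max, g$y_max)
  cw <- ex_max - ex_min; chh <- ey_max - ey_min
  c2 <- cw^2 + chh^2
  rho2_center <- (p$cx - g$cx)^2 + (p$cy - g$cy)^2
  rho2_w <- (p$w - g$w)^2
  rho2_h <- (p$h - g$h)^2
  loss <- 1 - i + alpha * v + rho2_center / c2 + rho2_h / chh^2 +
    rho2_w / cw^2
  terms <- structure(list(iou = i, v = v, alpha = alpha,
                          rho2_center = rho2_center, rho2_w = rho2_w,
                          rho2_h = rho2_h, c2 = c2, c2_w = cw^2,
                          c2_h = chh^2),
                     class = "eclou_terms")
  list(loss = loss, terms = terms)
}

#' Precision and recall from detection counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`; an undefined
#' 0/0 ratio is reported as 0 with the corresponding flag set.
#'
#' @param tp,fp,fn Nonnegative integer counts.
#' @return List with `precision`, `recall`, `precision_defined`,
#'   `recall_defined`.
#' @export
precision_recall <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  pd <- (tp + fp) > 0
  rd <- (tp + fn) > 0
  list(precision = if (pd) tp / (tp + fp) else 0,
       recall = if (rd) tp / (tp + fn) else 0,
       precision_defined = pd, recall_defined = rd)
}

#' Average precision (all-point interpolation)
#'
#' Detections are sorted by descending score (ties keep input order);
#' cumulative precision/recall points are integrated as
#' `AP = sum_i (r_i - r_{i-1}) * max_{j >= i} p_j`, the continuous-area
#' reading of the precision–recall integral.
#'
#' @param scores Numeric detection confidences.
#' @param is_tp Logical: whether each detection is a true positive.
#' @param n_gt Number of ground-truth instances (>= 1).
#' @return AP in \[0, 1\] (0 when there are no detections).
#' @export
average_precision <- function(scores, is_tp, n_gt) {
  stopifnot(length(scores) == length(is_tp))
  if (n_gt < 1) stop("n_gt must be >= 1")
  if (length(scores) == 0L) return(0)
  o <- order(-scores)  # stable: ties broken by input order
  tp <- cumsum(as.numeric(is_tp[o]))
  fp <- cumsum(as.numeric(!is_tp[o]))
  prec <- tp / (tp + fp)
  rec <- tp / n_gt
  p_int <- rev(cummax(rev(prec)))  # max precision at recall >= r_i
  sum(diff(c(0, rec)) * p_int)
}

#' Mean average precision over classes
#'
#' @param aps Numeric vector of per-class average precisions.
#' @return Their unweighted mean.
#' @export
mean_average_precision <- function(aps) {
  stopifnot(length(aps) >= 1L, all(aps >= 0 & aps <= 1))
  mean(aps)
}

#' Greedy IoU matching of detections to ground truth
#'
#' Within each image and class, detections are visited in order of
#' descending score; a detection is a true positive iff its best-IoU
#' unmatched ground-truth box reaches `iou_thresh`, and each ground-truth
#' box matches at most once.
#'
#' @param pred Data frame with columns `image`, `class`, `x_min`, `y_min`,
#'   `x_max`, `y_max`, `score`.
#' @param gt Data frame with columns `image`, `class`, `x_min`, `y_min`,
#'   `x_max`, `y_max`.
#' @param iou_thresh Match threshold (detections below it are FP).
#' @return `pred` with a logical `is_tp` column appended (original row
#'   order preserved).
#' @export
match_detections <- function(pred, gt, iou_thresh = 0.5) {
  need <- c("image", "class", "x_min", "y_min", "x_max", "y_max")
  stopifnot(all(c(need, "score") %in% names(pred)), all(need %in% names(gt)))
  is_tp <- logical(nrow(pred))
  for (img in unique(pred$image)) {
    for (cl in unique(pred$class[pred$image == img])) {
      pi <- which(pred$image == img & pred$class == cl)
      pi <- pi[order(-pred$score[pi])]
      gi <- which(gt$image == img & gt$class == cl)
      used <- logical(length(gi))
      for (d in pi) {
        db <- bbox(pred$x_min[d], pred$y_min[d], pred$x_max[d], pred$y_max[d])
        best <- 0; best_g <- 0L
        for (j in seq_along(gi)) {
          if (used[j]) next
          gb <- bbox(gt$x_min[gi[j]], gt$y_min[gi[j]],
                     gt$x_max[gi[j]], gt$y_max[gi[j]])
          ov <- iou(db, gb)
          if (ov > best) { best <- ov; best_g <- j }
        }
        if (best >= iou_thresh && best_g > 0L) {
          is_tp[d] <- TRUE
          used[best_g] <- TRUE
        }
      }
    }
  }
  pred$is_tp <- is_tp
  pred
}

#' Evaluate detections: per-class AP and mAP at a fixed IoU threshold
#'
#' @param pred,gt Data frames as in [match_detections()].
#' @param iou_thresh Match threshold (default 0.5, i.e. mAP@0.5).
#' @return List with `per_class` (data frame `class`, `ap`, `n_gt`) and
#'   `map`.
#' @export
evaluate_detections <- function(pred, gt, iou_thresh = 0.5) {
  matched <- match_detections(pred, gt, iou_thresh)
  classes <- sort(unique(gt$class))
  aps <- vapply(classes, function(cl) {
    sel <- matched$class == cl
    n_gt <- sum(gt$class == cl)
    average_precision(matched$score[sel], matched$is_tp[sel], n_gt)
  }, numeric(1))
  list(per_class = data.frame(class = classes, ap = unname(aps),
                              n_gt = as.vector(table(gt$class)[classes])),
       map = mean_average_precision(unname(aps)))
}

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

#' Bi-level routing attention forward pass
#'
#' Deterministic reference forward pass: the `H x W x C` feature map is
#' split into `S x S` regions; per-token queries/keys/values are linear
#' projections; region-level descriptors (token means of Q and K) give the
#' region affinity `A_r = Q_r K_r^T`, of which each row keeps its top-`k`
#' regions (ties to the lower region index). Token attention then runs over
#' the keys/values gathered from the routed regions,
#' `softmax(Q K_g^T / sqrt(C)) V_g`, and a local-context term — a depthwise
#' 5x5 convolution of V on the spatial grid, zero padded — is added.
#'
#' @param x `H x W x C` numeric array; `S` must divide `H` and `W`.
#' @param S Regions per side.
#' @param k Regions each query region attends to (`1 <= k <= S^2`).
#' @param w_q,w_k,w_v `C x C` projection matrices.
#' @param lce_kernel `5 x 5 x C` depthwise kernel for the local-context
#'   term.
#' @return `H x W x C` output array.
#' @export
bra_forward <- function(x, S, k, w_q, w_k, w_v, lce_kernel) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  H <- dim(x)[1L]; W <- dim(x)[2L]; C <- dim(x)[3L]
  if (H %% S != 0 || W %% S != 0) stop("S must divide both H and W")
  if (k < 1 || k > S^2) stop("k must be in 1..S^2")
  stopifnot(identical(dim(w_q), c(C, C)), identical(dim(w_k), c(C, C)),
            identical(dim(w_v), c(C, C)),
            identical(dim(lce_kernel), c(5L, 5L, C)),
            all(is.finite(x)), all(is.finite(w_q)), all(is.finite(w_k)),
            all(is.finite(w_v)), all(is.finite(lce_kernel)))
  xm <- matrix(x, H * W, C)              # token t = pixel (column-major)
  Q <- xm %*% w_q; K <- xm %*% w_k; V <- xm %*% w_v
  # region id of every pixel (column-major S x S grid of blocks)
  ri <- (seq_len(H) - 1L) %/% (H %/% S)
  ci <- (seq_len(W) - 1L) %/% (W %/% S)
  region <- as.vector(outer(ri, ci, function(a, b) a + b * S)) + 1L
  nreg <- S^2
  Qr <- rowsum(Q, region) / as.vector(table(region))
  Kr <- rowsum(K, region) / as.vector(table(region))
  Ar <- Qr %*% t(Kr)
  out_attn <- matrix(0, H * W, C)
  for (r in seq_len(nreg)) {
    routed <- order(-Ar[r, ], seq_len(nreg))[seq_len(k)]  # ties: lower index
    tok <- which(region == r)
    gathered <- which(region %in% routed)
    A <- Q[tok, , drop = FALSE] %*% t(K[gathered, , drop = FALSE]) / sqrt(C)
    out_attn[tok, ] <- softmax_rows(A) %*% V[gathered, , drop = FALSE]
  }
  out <- array(out_attn, dim = c(H, W, C))
  for (c in seq_len(C))
    out[, , c] <- out[, , c] +
      .conv2_zero_cpp(matrix(V[, c], H, W), lce_kernel[, , c])
  out
}
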