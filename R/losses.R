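# ---------------------------------------------------------------------------
# Boundary-weighted segmentation losses with deep supervision.
#
# Pixel weights follow the boundary-weighting convention of the salient-
# object / polyp decoder lineage: w = 1 + omega * |meanpool_k(G) - G|, so
# pixels whose k x k neighbourhood disagrees with them (boundary pixels)
# carry up to 1 + omega times the weight of interior pixels.
# ---------------------------------------------------------------------------

as_tensor4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected a matrix or array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(dim(x)) != 4L) stop("expected a (h,w) or (h,w,c,n) array")
  x
}

check_binary <- function(gt) {
  if (!all(gt %in% c(0, 1))) {
    stop("ground-truth mask must be strictly binary {0,1}")
  }
  invisible(gt)
}

#' Boundary pixel weights
#'
#' @param gt Binary mask, (h, w) matrix or (h, w, 1, n) array.
#' @param kernel Odd sliding-window size of the local mean (default 31).
#' @param omega Boundary weight amplitude; weights lie in `[1, 1 + omega]`.
#' @return Array of weights with the same shape as `gt` (promoted to 4-d).
#' @export
boundary_weights <- function(gt, kernel = 31L, omega = 5) {
  if (kernel %% 2L == 0L) stop("boundary weight kernel must be odd")
  gt <- as_tensor4(gt)
  check_binary(gt)
  d <- dim(gt)
  w <- gt
  for (n in seq_len(d[4])) {
    for (c in seq_len(d[3])) {
      mp <- cpp_box_mean_reflect(matrix(gt[, , c, n], d[1], d[2]), kernel)
      w[, , c, n] <- 1 + omega * abs(mp - gt[, , c, n])
    }
  }
  w
}

logits_value <- function(x) if (is_node(x)) x$v else as_tensor4(x)

#' Weighted binary cross-entropy from logits
#'
#' Computes `sum(w * bce(z, g)) / sum(w)` with the per-pixel cross-entropy
#' evaluated stably from logits.
#'
#' @param logits Node or array of unbounded logits.
#' @param gt Binary ground truth of the same shape.
#' @param w Pixel weights (same shape); defaults to uniform.
#' @return Scalar loss node.
#' @export
weighted_bce <- function(logits, gt, w = NULL) {
  z <- if (is_node(logits)) logits else ag_node(as_tensor4(logits))
  gt <- as_tensor4(gt)
  check_binary(gt)
  if (!identical(dim(z$v), dim(gt))) stop("logits/ground-truth shape mismatch")
  if (is.null(w)) w <- array(1, dim = dim(gt))
  sw <- sum(w)
  bce <- pmax(z$v, 0) - z$v * gt + log1p(exp(-abs(z$v)))
  ag_node(sum(w * bce) / sw, list(z), function(g) {
    p <- 1 / (1 + exp(-z$v))
    list(g * w * (p - gt) / sw)
  })
}

#' Weighted soft IoU loss from logits
#'
#' `1 - (sum(w p g) + 1) / (sum(w (p + g - p g)) + 1)` with `p = sigmoid(z)`;
#' the +1 smoothing keeps empty masks well-defined.
#'
#' @inheritParams weighted_bce
#' @return Scalar loss node in `[0, 1]`.
#' @export
weighted_iou <- function(logits, gt, w = NULL) {
  z <- if (is_node(logits)) logits else ag_node(as_tensor4(logits))
  gt <- as_tensor4(gt)
  check_binary(gt)
  if (!identical(dim(z$v), dim(gt))) stop("logits/ground-truth shape mismatch")
  if (is.null(w)) w <- array(1, dim = dim(gt))
  p <- 1 / (1 + exp(-z$v))
  I <- sum(w * p * gt) + 1
  U <- sum(w * (p + gt - p * gt)) + 1
  ag_node(1 - I / U, list(z), function(g) {
    dp <- -(w * gt * U - I * w * (1 - gt)) / U^2
    list(g * dp * p * (1 - p))
  })
}

#' Unweighted comparison losses
#'
#' The loss family used by the loss-comparison harness: plain soft IoU,
#' binary cross-entropy, soft Dice (`1 - (2 sum(pg) + 1)/(sum p + sum g + 1)`)
#' and the two additive combinations.
#'
#' @param logits Node or array of logits.
#' @param gt Binary ground truth.
#' @param name One of `"iou"`, `"bce"`, `"dice"`, `"dice+bce"`, `"iou+bce"`.
#' @return Scalar loss node.
#' @export
alt_losses <- function(logits, gt, name) {
  valid <- c("iou", "bce", "dice", "dice+bce", "iou+bce")
  if (!name %in% valid) {
    stop("unknown loss '", name, "'; available: ", paste(valid, collapse = ", "))
  }
  dice_loss <- function(z, gt) {
    z <- if (is_node(z)) z else ag_node(as_tensor4(z))
    gt <- as_tensor4(gt)
    check_binary(gt)
    p <- 1 / (1 + exp(-z$v))
    num <- 2 * sum(p * gt) + 1
    den <- sum(p) + sum(gt) + 1
    ag_node(1 - num / den, list(z), function(g) {
      dp <- -(2 * gt * den - num) / den^2
      list(g * dp * p * (1 - p))
    })
  }
  switch(name,
         iou = weighted_iou(logits, gt),
         bce = weighted_bce(logits, gt),
         dice = dice_loss(logits, gt),
         `dice+bce` = ag_add(dice_loss(logits, gt), weighted_bce(logits, gt)),
         `iou+bce` = ag_add(weighted_iou(logits, gt), weighted_bce(logits, gt)))
}

#' Combined deep-supervision training loss
#'
#' Sum of the boundary-weighted IoU + BCE combination over the main output
#' and, when present, the auxiliary decoder output, both against the same
#' full-resolution ground truth.
#'
#' @param outputs List from [model_forward()] (`main_logits`, `aux_logits`).
#' @param gt Binary ground truth at full resolution.
#' @param kernel,omega Boundary-weight parameters.
#' @param loss Loss name; `"iou+bce"` (default) is the boundary-weighted
#'   combination, other names fall back to [alt_losses()] per branch.
#' @return Scalar loss node.
#' @export
total_loss <- function(outputs, gt, kernel = 31L, omega = 5,
                       loss = "iou+bce") {
  gt <- as_tensor4(gt)
  check_binary(gt)
  main <- if (is_node(outputs$main_logits)) outputs$main_logits
          else ag_node(as_tensor4(outputs$main_logits))
  if (!identical(dim(main$v), dim(gt))) {
    stop("output resolution ", paste(dim(main$v), collapse = "x"),
         " does not match ground truth ", paste(dim(gt), collapse = "x"))
  }
  branch <- if (loss == "iou+bce") {
    w <- boundary_weights(gt, kernel, omega)
    function(z) ag_add(weighted_iou(z, gt, w), weighted_bce(z, gt, w))
  } else {
    function(z) alt_losses(z, gt, loss)
  }
  total <- branch(main)
  if (!is.null(outputs$aux_logits)) {
    total <- ag_add(total, branch(outputs$aux_logits))
  }
  total
}
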