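# ---------------------------------------------------------------------------
# Spatial Channel Attention Module on the low-level tap X1. The two
# attention operations are applied in parallel and their gated maps SUMMED
# (not chained as in CBAM): O2 = SAM(X1) + CAM(X1).
# ---------------------------------------------------------------------------

#' Construct the spatial attention operation
#'
#' Channel-wise mean and max maps are concatenated, passed through a single
#' 7x7 convolution (pad 3, no normalization) and a sigmoid; the resulting
#' (0,1) spatial gate multiplies the input.
#'
#' @return Module list for [sam_forward()].
#' @export
sam_new <- function() {
  l <- list(conv = conv_new(2L, 1L, 7L, pad = 3L, bias = TRUE, bn = FALSE,
                            act = "none"))
  class(l) <- c("nn_sam", "list")
  l
}

#' Spatial attention forward pass
#' @param l Module from [sam_new()].
#' @param x Input node or array (h, w, C, n).
#' @param train Logical training-mode flag.
#' @return Gated node of the same shape as `x`.
#' @export
sam_forward <- function(l, x, train = FALSE) {
  x <- as_node(x)
  pooled <- ag_concat_c(list(ag_channel_mean(x), ag_channel_max(x)))
  gate <- ag_sigmoid(fwd_conv(l$conv, pooled, train))
  ag_mul(gate, x)
}

#' Construct the channel attention operation
#'
#' Global average- and max-pooled descriptors pass through two separately
#' parameterized bottlenecks (1x1 conv C -> C/r, ReLU, 1x1 conv C/r -> C);
#' their sum is sigmoided into a per-channel gate.
#'
#' @param channels Input channel count; must be divisible by `reduction`.
#' @param reduction Bottleneck reduction ratio.
#' @return Module list for [cam_forward()].
#' @export
cam_new <- function(channels, reduction = 16L) {
  if (channels %% reduction != 0) {
    stop("channel attention requires channels divisible by ", reduction,
         ", got ", channels)
  }
  mid <- channels %/% reduction
  mlp <- function() list(
    fc1 = conv_new(channels, mid, 1L, bias = TRUE, bn = FALSE, act = "relu"),
    fc2 = conv_new(mid, channels, 1L, bias = TRUE, bn = FALSE, act = "none"))
  l <- list(h1 = mlp(), h2 = mlp(), channels = channels)
  class(l) <- c("nn_cam", "list")
  l
}

#' Channel attention forward pass
#' @param l Module from [cam_new()].
#' @param x Input node or array (h, w, C, n).
#' @param train Logical training-mode flag.
#' @return Gated node of the same shape as `x`.
#' @export
cam_forward <- function(l, x, train = FALSE) {
  x <- as_node(x)
  avg <- ag_global_avgpool(x)
  mx <- ag_global_maxpool(x)
  h1 <- fwd_conv(l$h1$fc2, fwd_conv(l$h1$fc1, avg, train), train)
  h2 <- fwd_conv(l$h2$fc2, fwd_conv(l$h2$fc1, mx, train), train)
  gate <- ag_sigmoid(ag_add(h1, h2))
  ag_mul(x, gate)
}

#' Construct the full spatial-channel attention module
#' @param channels Channels of the incoming low-level tap (128).
#' @param reduction Channel-attention reduction ratio.
#' @return Module list for [scam_forward()].
#' @export
scam_new <- function(channels = 128L, reduction = 16L) {
  l <- list(sam = sam_new(), cam = cam_new(channels, reduction))
  class(l) <- c("nn_scam", "list")
  l
}

#' SCAM forward pass: sum of the two gated branches
#' @param l Module from [scam_new()].
#' @param x1 The untouched low-level encoder tap.
#' @param train Logical training-mode flag.
#' @return Node `O2` of the same shape as `x1`.
#' @export
scam_forward <- function(l, x1, train = FALSE) {
  x1 <- as_node(x1)
  ag_add(sam_forward(l$sam, x1, train), cam_forward(l$cam, x1, train))
}
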