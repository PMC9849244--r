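# ---------------------------------------------------------------------------
# Cascaded Fusion Module: progressive two-stage fusion of the reduced taps
# into the stride-8 semantic map O1. Each branch runs a Feature Pyramid
# Module (FPM): 1x1 entry conv, split into four 8-channel chunks refined by a
# cascade of dilated-convolution branches (DDCM, dilations 1/3/5/7), 1x1 exit
# conv and a residual connection back to the FPM input.
# ---------------------------------------------------------------------------

#' Construct one DDCM branch
#'
#' A factorized dilated branch: 1xD convolution (pad (0,d)), Dx1 convolution
#' (pad (d,0)), then a 3x3 convolution with dilation D and pad D, all
#' size-preserving, with d = (D-1)/2.
#'
#' @param channels Channel count of the chunk the branch refines.
#' @param dilation Odd dilation rate D.
#' @return Module list for [ddcm_forward()].
#' @export
ddcm_new <- function(channels, dilation) {
  if (dilation %% 2 == 0) {
    stop("DDCM dilation must be odd, got ", dilation)
  }
  D <- as.integer(dilation)
  d <- (D - 1L) %/% 2L
  l <- list(c1 = conv_new(channels, channels, 1L, D, pad = c(0L, d)),
            c2 = conv_new(channels, channels, D, 1L, pad = c(d, 0L)),
            c3 = conv_new(channels, channels, 3L, pad = D, dil = D),
            dilation = D)
  class(l) <- c("nn_ddcm", "list")
  l
}

#' DDCM branch forward pass
#' @param l Branch from [ddcm_new()].
#' @param x Input node or array.
#' @param train Logical training-mode flag.
#' @return Node of the same shape as `x`.
#' @export
ddcm_forward <- function(l, x, train = FALSE) {
  fwd_conv(l$c3, fwd_conv(l$c2, fwd_conv(l$c1, x, train), train), train)
}

#' Construct a Feature Pyramid Module
#'
#' @param channels Input/output channel count (must be divisible by 4).
#' @param dilations Dilation rates of the four chunk branches.
#' @return Module list for [fpm_forward()].
#' @export
fpm_new <- function(channels = 32L, dilations = c(1L, 3L, 5L, 7L)) {
  if (channels %% 4 != 0) {
    stop("FPM channel count must be divisible by 4, got ", channels)
  }
  ck <- channels %/% 4L
  l <- list(entry = conv_new(channels, channels, 1L),
            branches = lapply(dilations, function(D) ddcm_new(ck, D)),
            exit = conv_new(channels, channels, 1L, bias = TRUE, bn = FALSE,
                            act = "none"),
            channels = as.integer(channels), chunk = ck)
  class(l) <- c("nn_fpm", "list")
  l
}

#' FPM forward pass
#'
#' Entry 1x1 convolution, split into four equal chunks, sequential DDCM
#' cascade (each later chunk is summed with the previous refined chunk before
#' its branch), concatenation, exit 1x1 convolution and residual addition of
#' the module input.
#'
#' @param l Module from [fpm_new()].
#' @param x Input node or array with `l$channels` channels.
#' @param train Logical training-mode flag.
#' @return Node of the same shape as `x`.
#' @export
fpm_forward <- function(l, x, train = FALSE) {
  x <- as_node(x)
  u <- fwd_conv(l$entry, x, train)
  ck <- l$chunk
  chunks <- lapply(0:3, function(i) ag_narrow_c(u, i * ck + 1L, ck))
  refined <- vector("list", 4L)
  refined[[1]] <- ddcm_forward(l$branches[[1]], chunks[[1]], train)
  for (j in 2:4) {
    refined[[j]] <- ddcm_forward(l$branches[[j]],
                                 ag_add(refined[[j - 1]], chunks[[j]]), train)
  }
  out <- fwd_conv(l$exit, ag_concat_c(refined), train)
  ag_add(out, x)
}

#' Construct the Cascaded Fusion Module
#'
#' Five independently-parameterized FPM instances (two on the upsampled
#' deepest tap in stage one, and one each for the X3'/X4'/fused-stage
#' branches in stage two) plus two 3x3 fusion convolutions.
#'
#' @param channels Working channel width (32).
#' @param dilations DDCM dilation ladder.
#' @return Module list for [cfm_forward()].
#' @export
cfm_new <- function(channels = 32L, dilations = c(1L, 3L, 5L, 7L)) {
  l <- list(fpm_a = fpm_new(channels, dilations),
            fpm_b = fpm_new(channels, dilations),
            fpm_x3 = fpm_new(channels, dilations),
            fpm_x4 = fpm_new(channels, dilations),
            fpm_x43 = fpm_new(channels, dilations),
            fuse1 = conv_new(2L * channels, channels, 3L, pad = 1L),
            fuse2 = conv_new(2L * channels, channels, 3L, pad = 1L))
  class(l) <- c("nn_cfm", "list")
  l
}

#' Cascaded Fusion Module forward pass
#'
#' Stage one fuses the (upsampled) deepest tap with X3' into X43 at stride
#' 16; stage two lifts everything to stride 8 and produces the semantic map
#' O1. All upsampling is bilinear.
#'
#' @param l Module from [cfm_new()].
#' @param x2p,x3p,x4p Reduced taps at strides 8/16/32, 32 channels each.
#' @param train Logical training-mode flag.
#' @return Node `O1` with 32 channels at the stride-8 resolution.
#' @export
cfm_forward <- function(l, x2p, x3p, x4p, train = FALSE) {
  x2p <- as_node(x2p); x3p <- as_node(x3p); x4p <- as_node(x4p)
  d3 <- dim(x3p$v); d2 <- dim(x2p$v)
  # stage one at stride 16
  x4u <- ag_upsample(x4p, d3[1], d3[2])
  x41 <- fpm_forward(l$fpm_a, x4u, train)
  x42 <- fpm_forward(l$fpm_b, x4u, train)
  stopifnot(identical(dim(x41$v)[1:2], d3[1:2]))
  x43 <- fwd_conv(l$fuse1, ag_concat_c(list(ag_mul(x41, x3p), x42)), train)
  # stage two at stride 8
  x3u <- fpm_forward(l$fpm_x3, ag_upsample(x3p, d2[1], d2[2]), train)
  x4u2 <- fpm_forward(l$fpm_x4, ag_upsample(x4p, d2[1], d2[2]), train)
  x43u <- fpm_forward(l$fpm_x43, ag_upsample(x43, d2[1], d2[2]), train)
  fused <- ag_mul(ag_mul(x3u, x4u2), x2p)
  stopifnot(identical(dim(fused$v)[1:2], d2[1:2]))
  fwd_conv(l$fuse2, ag_concat_c(list(fused, x43u)), train)
}
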