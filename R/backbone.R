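# ---------------------------------------------------------------------------
# HarDNet-68 encoder: five 8-layer harmonic dense blocks.
#
# Within a block, layer l (layer 0 being the block input) receives input from
# layers l - 2^i for every power 2^i dividing l, so the connection pattern is
# logarithmic rather than fully dense. The channel width of layer l is
# growth * mult^v2(l) rounded to the nearest even integer, where v2(l) is the
# number of times 2 divides l. The block output concatenates the odd-indexed
# layers plus the last layer and is compressed by a trailing 1x1 transition.
# ---------------------------------------------------------------------------

#' Harmonic connectivity of one dense-block layer
#'
#' Returns the indices of the layers feeding layer `layer` of a harmonic
#' dense block: `layer - 2^i` for every power of two `2^i` that divides
#' `layer`. Layer 0 denotes the block input.
#'
#' @param layer Positive integer layer index (1-based within the block).
#' @return Integer vector of source layer indices, in decreasing power order.
#' @export
hard_block_links <- function(layer) {
  stopifnot(layer >= 1)
  layer <- as.integer(layer)
  links <- integer()
  i <- 0L
  while (layer %% as.integer(2^i) == 0L) {
    links <- c(links, layer - as.integer(2^i))
    i <- i + 1L
  }
  links
}

hard_layer_width <- function(growth, mult, layer) {
  w <- growth
  i <- 1L
  while (layer %% 2L^i == 0L) {
    w <- w * mult
    i <- i + 1L
  }
  2L * as.integer(round(w / 2))
}

#' Construct one harmonic dense block
#'
#' @param cin Input channel count.
#' @param growth Base channel growth of the block's layers.
#' @param out_channels Channels after the trailing 1x1 transition.
#' @param n_layers Number of 3x3 layers in the block (8 throughout).
#' @param mult Width multiplier applied once per extra power of two dividing
#'   the layer index.
#' @param index Block position in the encoder, used in error messages.
#' @return A module list usable with [hard_block_forward()].
#' @export
hard_block_new <- function(cin, growth, out_channels, n_layers = 8L,
                           mult = 1.7, index = NA_integer_) {
  widths <- c(cin, vapply(seq_len(n_layers), function(l)
    hard_layer_width(growth, mult, l), numeric(1)))
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    links <- hard_block_links(l)
    layers[[l]] <- conv_new(sum(widths[links + 1L]), widths[l + 1L], 3L,
                            pad = 1L)
  }
  keep <- sort(unique(c(seq(1L, n_layers, by = 2L), n_layers)))
  blk <- list(layers = layers,
              transition = conv_new(sum(widths[keep + 1L]), out_channels, 1L),
              spec = list(cin = cin, growth = growth, mult = mult,
                          n_layers = n_layers, out_channels = out_channels,
                          widths = widths, keep = keep, index = index))
  class(blk) <- c("nn_hardblock", "list")
  blk
}

#' Forward pass of a harmonic dense block
#'
#' @param blk Block from [hard_block_new()].
#' @param x Input node or array of shape (h, w, cin, n).
#' @param train Logical; use batch statistics and record the tape.
#' @return Node with `spec$out_channels` channels at the input's spatial size.
#' @export
hard_block_forward <- function(blk, x, train = FALSE) {
  x <- as_node(x)
  if (dim(x$v)[3] != blk$spec$cin) {
    stop("hard block ", blk$spec$index, ": input has ", dim(x$v)[3],
         " channels but the block is configured for ", blk$spec$cin)
  }
  outs <- vector("list", blk$spec$n_layers + 1L)
  outs[[1L]] <- x
  for (l in seq_len(blk$spec$n_layers)) {
    links <- hard_block_links(l)
    src <- outs[links + 1L]
    inp <- if (length(src) == 1L) src[[1L]] else ag_concat_c(src)
    outs[[l + 1L]] <- fwd_conv(blk$layers[[l]], inp, train)
  }
  kept <- ag_concat_c(outs[blk$spec$keep + 1L])
  fwd_conv(blk$transition, kept, train)
}

#' Construct the HarDNet-68 encoder
#'
#' Stem (two 3x3 convolutions, the first at stride 2, then 2x2 max pooling)
#' followed by five 8-layer harmonic dense blocks with 2x2 max pooling after
#' blocks 1, 3 and 4, so blocks 2 and 3 share their spatial size. Feature
#' taps are taken after the transitions of blocks 1, 3, 4 and 5, giving
#' channel counts 128/320/640/1024 at strides 4/8/16/32.
#'
#' @param growth Per-block base growth rates.
#' @param channels Per-block transition output channels.
#' @param mult Harmonic width multiplier.
#' @return Encoder module for [encoder_forward()].
#' @export
encoder_new <- function(growth = c(14, 16, 20, 40, 160),
                        channels = c(128, 256, 320, 640, 1024),
                        mult = 1.7) {
  blocks <- vector("list", 5L)
  cin <- 64L
  for (b in 1:5) {
    blocks[[b]] <- hard_block_new(cin, growth[b], channels[b], 8L, mult,
                                  index = b)
    cin <- channels[b]
  }
  enc <- list(stem1 = conv_new(3L, 32L, 3L, stride = 2L, pad = 1L),
              stem2 = conv_new(32L, 64L, 3L, pad = 1L),
              blocks = blocks)
  class(enc) <- c("nn_encoder", "list")
  enc
}

#' Encoder forward pass: the four-scale feature pyramid
#'
#' @param enc Encoder from [encoder_new()].
#' @param x Input node or array (h, w, 3, n); `h` and `w` must be divisible
#'   by 32.
#' @param train Logical training-mode flag.
#' @return List with nodes `X1` (stride 4, 128 ch), `X2` (stride 8, 320 ch),
#'   `X3` (stride 16, 640 ch) and `X4` (stride 32, 1024 ch).
#' @export
encoder_forward <- function(enc, x, train = FALSE) {
  x <- as_node(x)
  d <- dim(x$v)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L) {
    stop("input spatial size ", d[1], "x", d[2], " is not divisible by 32; ",
         "pad or resize the image first")
  }
  h <- fwd_conv(enc$stem1, x, train)
  h <- fwd_conv(enc$stem2, h, train)
  h <- ag_maxpool2(h)                       # stride 4
  x1 <- hard_block_forward(enc$blocks[[1]], h, train)
  h <- ag_maxpool2(x1)                      # stride 8
  h <- hard_block_forward(enc$blocks[[2]], h, train)
  x2 <- hard_block_forward(enc$blocks[[3]], h, train)
  h <- ag_maxpool2(x2)                      # stride 16
  x3 <- hard_block_forward(enc$blocks[[4]], h, train)
  h <- ag_maxpool2(x3)                      # stride 32
  x4 <- hard_block_forward(enc$blocks[[5]], h, train)
  list(X1 = x1, X2 = x2, X3 = x3, X4 = x4)
}

#' Construct the tap reducers
#'
#' Three independent 1x1 convolutions squeezing taps X2/X3/X4 to 32 channels
#' each; X1 passes through untouched.
#'
#' @param channels Channel counts of X2, X3, X4.
#' @return Module list for [reduce_taps()].
#' @export
reducers_new <- function(channels = c(320, 640, 1024)) {
  r <- list(r2 = conv_new(channels[1], 32L, 1L, bias = TRUE, bn = FALSE,
                          act = "none"),
            r3 = conv_new(channels[2], 32L, 1L, bias = TRUE, bn = FALSE,
                          act = "none"),
            r4 = conv_new(channels[3], 32L, 1L, bias = TRUE, bn = FALSE,
                          act = "none"))
  class(r) <- c("nn_reducers", "list")
  r
}

#' Reduce the deep taps to 32 channels
#'
#' @param red Module from [reducers_new()].
#' @param pyr Feature pyramid from [encoder_forward()].
#' @param train Logical training-mode flag.
#' @return List of nodes `X2p`, `X3p`, `X4p`, 32 channels each.
#' @export
reduce_taps <- function(red, pyr, train = FALSE) {
  list(X2p = fwd_conv(red$r2, pyr$X2, train),
       X3p = fwd_conv(red$r3, pyr$X3, train),
       X4p = fwd_conv(red$r4, pyr$X4, train))
}
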