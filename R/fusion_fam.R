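# ---------------------------------------------------------------------------
# Feature Aggregation Module: fuses the semantic map O1 (stride 8, 32 ch)
# with the detail map O2 (stride 4, 128 ch) through (a) a projection of
# pixels onto a small set of anchor nodes, one graph-reasoning unit, and a
# reprojection back to pixels, and (b) a mutual embedding of global channel
# context into the detail branch and of spatial saliency into the semantic
# branch. The detail map is bilinearly aligned to stride 8 once at entry.
# ---------------------------------------------------------------------------

#' Construct the Feature Aggregation Module
#'
#' @param num_nodes Number of anchor nodes K (a perfect square; pooled as a
#'   sqrt(K) x sqrt(K) grid).
#' @param node_dim Feature dimension of each node (the Q/P embedding width).
#' @param o1_channels Channels of the semantic input (32).
#' @param o2_channels Channels of the detail input (128).
#' @param pool_grid Side of the pooled grid before center clipping; defaults
#'   to sqrt(K) so the clip is a no-op.
#' @return Module list for [fam_forward()].
#' @export
fam_new <- function(num_nodes = 16L, node_dim = 16L, o1_channels = 32L,
                    o2_channels = 128L, pool_grid = NULL) {
  side <- sqrt(num_nodes)
  if (side != round(side)) {
    stop("fam num_nodes must be a perfect square, got ", num_nodes)
  }
  side <- as.integer(side)
  pool_grid <- as.integer(pool_grid %||% side)
  if (pool_grid < side) stop("pool_grid must be at least sqrt(num_nodes)")
  plain <- function(cin, cout) conv_new(cin, cout, 1L, bias = TRUE,
                                        bn = FALSE, act = "none")
  l <- list(q_conv = plain(o1_channels, node_dim),
            p_conv = plain(o1_channels, node_dim),
            gate_conv = plain(o2_channels, 32L),
            gcn = list(
              adj = new_param(array(0, dim = c(num_nodes, num_nodes))),
              w = new_param(he_init(c(node_dim, node_dim), node_dim))),
            y_conv = plain(node_dim, o1_channels),
            mem = list(l_conv = plain(o2_channels, o1_channels),
                       lp_conv = plain(1L, 1L),
                       h_conv = plain(o1_channels, o1_channels),
                       hp_conv = plain(o1_channels, o1_channels)),
            num_nodes = as.integer(num_nodes), node_dim = as.integer(node_dim),
            side = side, pool_grid = pool_grid)
  class(l) <- c("nn_fam", "list")
  l
}

#' Pixel embeddings Q and P from the semantic map
#' @param l FAM module.
#' @param o1 Semantic input node (h, w, 32, n).
#' @param train Logical training-mode flag.
#' @return List of nodes `Q` and `P`, each (h, w, node_dim, n).
#' @export
pixel_embed <- function(l, o1, train = FALSE) {
  list(Q = fwd_conv(l$q_conv, o1, train), P = fwd_conv(l$p_conv, o1, train))
}

#' Detail-branch attention gate
#'
#' 1x1 convolution of the detail map to 32 channels, bilinear resize to the
#' target stride-8 grid, channel softmax, and selection of the second
#' channel as a single-channel attention map.
#'
#' @param l FAM module.
#' @param o2 Detail input node (any stride).
#' @param out_hw Target (h, w) of the stride-8 grid.
#' @param train Logical training-mode flag.
#' @return Node (h, w, 1, n) with values in (0, 1).
#' @export
detail_gate <- function(l, o2, out_hw, train = FALSE) {
  g <- fwd_conv(l$gate_conv, o2, train)
  g <- ag_upsample(g, out_hw[1], out_hw[2])
  s <- ag_softmax_c(g)
  ag_narrow_c(s, 2L, 1L)
}

#' Project gated pixels onto anchor nodes
#'
#' The embedding P is gated by the attention map, adaptively average-pooled
#' to a sqrt(K) x sqrt(K) grid (after optional center clipping from a larger
#' pooled grid) and flattened to K node vectors.
#'
#' @param l FAM module.
#' @param P Pixel embedding node (h, w, node_dim, n).
#' @param att Attention node (h, w, 1, n).
#' @param train Logical training-mode flag.
#' @return Node `V` of shape (K, node_dim, n).
#' @export
build_nodes <- function(l, P, att, train = FALSE) {
  gated <- ag_mul(P, att)
  pooled <- ag_adaptive_avgpool(gated, l$pool_grid, l$pool_grid)
  if (l$pool_grid > l$side) {
    off <- (l$pool_grid - l$side) %/% 2L
    pooled <- ag_crop_hw(pooled, off + 1L, off + 1L, l$side, l$side)
  }
  d <- dim(pooled$v)
  ag_reshape(pooled, c(l$side * l$side, d[3], d[4]))
}

# center crop helper on the spatial axes
ag_crop_hw <- function(a, h0, w0, hh, ww) {
  a <- as_node(a)
  dv <- dim(a$v)
  v <- a$v[h0:(h0 + hh - 1L), w0:(w0 + ww - 1L), , , drop = FALSE]
  ag_node(v, list(a), function(g) {
    gx <- array(0, dim = dv)
    gx[h0:(h0 + hh - 1L), w0:(w0 + ww - 1L), , ] <- g
    list(gx)
  })
}

#' Node-to-pixel assignment map
#'
#' S = softmax(V P^T) with P flattened to M x node_dim per sample and the
#' softmax taken over the pixel axis, so each node row is a distribution
#' over pixels.
#'
#' @param V Node features (K, node_dim, n).
#' @param P Pixel embedding node (h, w, node_dim, n).
#' @return Node `S` of shape (K, M, n) with rows summing to one.
#' @export
fam_assign <- function(V, P) {
  P <- as_node(P)
  d <- dim(P$v)
  pf <- ag_reshape(P, c(d[1] * d[2], d[3], d[4]))
  ag_softmax_ax2(ag_bmm(V, pf, tb = TRUE))
}

#' Graph reasoning over anchor nodes
#'
#' Pools Q onto the nodes through S, applies one graph-reasoning unit
#' (residual mixing (I - A) F followed by a channel linear map and ReLU) and
#' reprojects to pixels through S^T.
#'
#' @param l FAM module.
#' @param S Assignment node (K, M, n).
#' @param Q Pixel embedding node (h, w, node_dim, n).
#' @return Node `Y` of shape (h, w, node_dim, n).
#' @export
graph_reason <- function(l, S, Q) {
  Q <- as_node(Q)
  d <- dim(Q$v)
  qf <- ag_reshape(Q, c(d[1] * d[2], d[3], d[4]))
  fn <- ag_bmm(S, qf)                                   # (K, Cg, n)
  mixed <- ag_add(fn, ag_scale(ag_lmm(ag_leaf(l$gcn$adj), fn), -1))
  g <- ag_relu(ag_rmm(mixed, ag_leaf(l$gcn$w)))
  yf <- ag_bmm(S, g, ta = TRUE)                         # (M, Cg, n)
  ag_reshape(yf, c(d[1], d[2], l$node_dim, d[4]))
}

#' Mutual embedding of the two branches
#'
#' The detail branch contributes a 32-channel map L and a spatial saliency
#' map L'; the semantic branch contributes a 32-channel map Hf and a global
#' channel descriptor Hf'. The output is R = Hf' * L + Hf * L' with
#' broadcasting.
#'
#' @param l FAM module.
#' @param o1 Semantic node (h, w, 32, n).
#' @param o2_aligned Detail node already at stride 8.
#' @param train Logical training-mode flag.
#' @return Node `R` of shape (h, w, 32, n).
#' @export
mem_forward <- function(l, o1, o2_aligned, train = FALSE) {
  m <- l$mem
  L <- fwd_conv(m$l_conv, o2_aligned, train)
  Lp <- fwd_conv(m$lp_conv, ag_channel_mean(L), train)
  Hf <- fwd_conv(m$h_conv, o1, train)
  Hfp <- fwd_conv(m$hp_conv, ag_global_avgpool(Hf), train)
  ag_add(ag_mul(Hfp, L), ag_mul(Hf, Lp))
}

#' FAM forward pass
#'
#' @param l Module from [fam_new()].
#' @param o1 Semantic map from the cascaded decoder (stride 8, 32 ch).
#' @param o2 Detail map from the attention branch (stride 4, 128 ch);
#'   aligned internally.
#' @param train Logical training-mode flag.
#' @return Node `Z` of shape (h, w, 32, n).
#' @export
fam_forward <- function(l, o1, o2, train = FALSE) {
  o1 <- as_node(o1); o2 <- as_node(o2)
  d1 <- dim(o1$v)
  o2a <- ag_upsample(o2, d1[1], d1[2])
  att <- detail_gate(l, o2a, d1[1:2], train)
  qp <- pixel_embed(l, o1, train)
  V <- build_nodes(l, qp$P, att, train)
  S <- fam_assign(V, qp$P)
  Y <- graph_reason(l, S, qp$Q)
  R <- mem_forward(l, o1, o2a, train)
  ag_add(R, fwd_conv(l$y_conv, Y, train))
}
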