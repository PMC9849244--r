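# ---------------------------------------------------------------------------
# Full network assembly with deep supervision and ablation variants.
#
# Variant wiring:
#   baseline          encoder + reduced taps + naive top-down decoder
#   +CFM              cascaded decoder replaces the top-down path; auxiliary
#                     head on O1 added
#   +CFM+SCAM         attention branch on X1 projected to 32 channels,
#                     aligned to stride 8 and summed into the decoder output
#   full (+FAM)       graph-reasoned aggregation of O1 and O2 feeds the head
# ---------------------------------------------------------------------------

#' Ablation switches
#'
#' @param use_cfm,use_scam,use_fam Logical component switches. The
#'   aggregation stage consumes both other components, so `use_fam` requires
#'   `use_cfm` and `use_scam`; the attention branch is only wired into the
#'   cascaded decoder path, so `use_scam` requires `use_cfm`.
#' @return Validated list of the three flags.
#' @export
ablation_config <- function(use_cfm = TRUE, use_scam = TRUE, use_fam = TRUE) {
  if (use_fam && !(use_cfm && use_scam)) {
    stop("invalid ablation: the aggregation module requires both the ",
         "cascaded decoder and the attention branch")
  }
  if (use_scam && !use_cfm) {
    stop("invalid ablation: the attention branch is only wired together ",
         "with the cascaded decoder")
  }
  list(use_cfm = use_cfm, use_scam = use_scam, use_fam = use_fam)
}

#' Construct the segmentation network
#'
#' @param ablation List from [ablation_config()].
#' @param num_nodes,node_dim Anchor-node geometry of the aggregation module.
#' @param reduction Channel-attention reduction ratio.
#' @param head_fusion Either "add" (elementwise sum of the two 32-channel
#'   head features before the final 1x1 convolution) or "concat".
#' @return Model list for [model_forward()].
#' @export
model_new <- function(ablation = ablation_config(), num_nodes = 16L,
                      node_dim = 16L, reduction = 16L,
                      head_fusion = c("add", "concat")) {
  head_fusion <- match.arg(head_fusion)
  plain <- function(cin, cout) conv_new(cin, cout, 1L, bias = TRUE,
                                        bn = FALSE, act = "none")
  m <- list(encoder = encoder_new(), reducers = reducers_new(),
            ablation = ablation, head_fusion = head_fusion)
  if (ablation$use_cfm) {
    m$cfm <- cfm_new()
    m$aux_head <- plain(32L, 1L)
    m$op_conv <- plain(32L, 32L)
    m$o1p_conv <- plain(32L, 32L)
    m$t_conv <- plain(if (head_fusion == "add") 32L else 64L, 1L)
  } else {
    m$td1 <- conv_new(32L, 32L, 3L, pad = 1L)
    m$td2 <- conv_new(32L, 32L, 3L, pad = 1L)
    m$op_conv <- plain(32L, 32L)
    m$t_conv <- plain(32L, 1L)
  }
  if (ablation$use_scam) m$scam <- scam_new(128L, reduction)
  if (ablation$use_fam) {
    m$fam <- fam_new(num_nodes, node_dim)
  } else if (ablation$use_scam) {
    m$scam_proj <- plain(128L, 32L)
  }
  class(m) <- c("slhardnet_model", "list")
  m
}

#' Network forward pass
#'
#' @param m Model from [model_new()].
#' @param x Input node or array (h, w, 3, n), spatial size divisible by 32.
#' @param train Logical training-mode flag.
#' @return List with `main_logits` and (when the cascaded decoder is active)
#'   `aux_logits`, both 1-channel nodes at full input resolution; logits are
#'   unbounded, no sigmoid is applied.
#' @export
model_forward <- function(m, x, train = FALSE) {
  if (!is_node(x)) {
    x <- as_node(x)
    x$nograd <- TRUE
  }
  d <- dim(x$v)
  pyr <- encoder_forward(m$encoder, x, train)
  red <- reduce_taps(m$reducers, pyr, train)
  ab <- m$ablation
  aux <- NULL
  if (ab$use_cfm) {
    o1 <- cfm_forward(m$cfm, red$X2p, red$X3p, red$X4p, train)
    aux <- ag_upsample(fwd_conv(m$aux_head, o1, train), d[1], d[2])
    if (ab$use_fam) {
      o2 <- scam_forward(m$scam, pyr$X1, train)
      z <- fam_forward(m$fam, o1, o2, train)
    } else if (ab$use_scam) {
      o2 <- scam_forward(m$scam, pyr$X1, train)
      d1 <- dim(o1$v)
      proj <- ag_upsample(fwd_conv(m$scam_proj, o2, train), d1[1], d1[2])
      z <- ag_add(o1, proj)
    } else {
      z <- o1
    }
    op <- fwd_conv(m$op_conv, z, train)
    o1p <- fwd_conv(m$o1p_conv, o1, train)
    fused <- if (m$head_fusion == "add") ag_add(op, o1p)
             else ag_concat_c(list(op, o1p))
    logits8 <- fwd_conv(m$t_conv, fused, train)
  } else {
    d3 <- dim(red$X3p$v); d2 <- dim(red$X2p$v)
    f16 <- fwd_conv(m$td1,
                    ag_add(red$X3p, ag_upsample(red$X4p, d3[1], d3[2])), train)
    f8 <- fwd_conv(m$td2,
                   ag_add(red$X2p, ag_upsample(f16, d2[1], d2[2])), train)
    logits8 <- fwd_conv(m$t_conv, fwd_conv(m$op_conv, f8, train), train)
  }
  list(main_logits = ag_upsample(logits8, d[1], d[2]),
       aux_logits = aux)
}

#' Binarize a prediction
#'
#' @param m Model with loaded or trained weights.
#' @param image Array (h, w, 3) or (h, w, 3, 1) with values in `[0, 1]`.
#' @param threshold Sigmoid threshold in (0, 1).
#' @return Binary integer matrix (h, w).
#' @export
predict_mask <- function(m, image, threshold = 0.5) {
  if (length(dim(image)) == 3L) dim(image) <- c(dim(image), 1L)
  d <- dim(image)
  hw <- d[1:2]
  d32 <- 32L * pmax(1L, round(hw / 32))
  if (!all(hw %% 32L == 0L)) {
    image <- cpp_resize_bilinear_fw(image, d32[1], d32[2])
  }
  out <- model_forward(m, image, train = FALSE)
  p <- 1 / (1 + exp(-out$main_logits$v))
  mask <- (p >= threshold) * 1L
  if (!all(hw %% 32L == 0L)) {
    mask <- cpp_resize_nearest(mask + 0, hw[1], hw[2])
  }
  matrix(as.integer(mask >= 0.5), hw[1], hw[2])
}
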