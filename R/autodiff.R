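#' @useDynLib slhardnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Reverse-mode automatic differentiation on 4-d tensors.
#
# Values are plain numeric arrays with dim (H, W, C, N); a "node" is an
# environment holding the value, an accumulated gradient, its parents and a
# backward closure. Nodes created while a tape is active are recorded in
# creation order; ag_backward() walks the tape in reverse. Trainable
# parameters are separate environments ("ag_param") into which leaf gradients
# are accumulated, so the optimizer never touches the tape.
# ---------------------------------------------------------------------------

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL
.ag$n <- 0L
.ag$recording <- FALSE

ag_tape_start <- function() {
  .ag$tape <- vector("list", 1024L)
  .ag$n <- 0L
  .ag$recording <- TRUE
  invisible(NULL)
}

ag_tape_end <- function() {
  .ag$tape <- NULL
  .ag$n <- 0L
  .ag$recording <- FALSE
  invisible(NULL)
}

ag_node <- function(v, parents = list(), backfn = NULL, param = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- v
  nd$g <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$param <- param
  class(nd) <- "ag_node"
  if (.ag$recording) {
    n <- .ag$n + 1L
    if (n > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
    .ag$tape[[n]] <- nd
    .ag$n <- n
  }
  nd
}

is_node <- function(x) inherits(x, "ag_node")

# wrap raw arrays on the fly so ops accept both nodes and arrays
as_node <- function(x) if (is_node(x)) x else ag_node(x)

ag_accum <- function(nd, g) {
  if (is.null(nd$g)) nd$g <- g else nd$g <- nd$g + g
  invisible(NULL)
}

#' @keywords internal
ag_backward <- function(root) {
  if (!.ag$recording) stop("ag_backward() requires an active tape")
  root$g <- if (length(root$v) == 1L) 1 else array(1, dim = dim(root$v))
  for (i in seq(.ag$n, 1L)) {
    nd <- .ag$tape[[i]]
    if (is.null(nd$g)) next
    if (!is.null(nd$backfn)) {
      gs <- nd$backfn(nd$g)
      ps <- nd$parents
      for (j in seq_along(ps)) {
        if (!is.null(gs[[j]])) ag_accum(ps[[j]], gs[[j]])
      }
    }
    if (!is.null(nd$param)) {
      if (is.null(nd$param$grad)) nd$param$grad <- nd$g
      else nd$param$grad <- nd$param$grad + nd$g
    }
    # free interior activations; leaf nodes keep their gradient readable
    if (!is.null(nd$backfn) || !is.null(nd$param)) nd$g <- NULL
  }
  invisible(NULL)
}

# -- parameters -------------------------------------------------------------

new_param <- function(val, name = "", decay = TRUE) {
  p <- new.env(parent = emptyenv())
  p$val <- val
  p$grad <- NULL
  p$name <- name
  p$decay <- decay
  class(p) <- "ag_param"
  p
}

is_param <- function(x) inherits(x, "ag_param")

ag_leaf <- function(param) ag_node(param$val, param = param)

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- broadcasting helpers ---------------------------------------------------

bc_expand <- function(v, dd) {
  dv <- dim(v)
  if (identical(dv, dd)) return(v)
  idx <- lapply(1:4, function(k) {
    if (dv[k] == 1L && dd[k] > 1L) rep(1L, dd[k]) else seq_len(dv[k])
  })
  v[idx[[1]], idx[[2]], idx[[3]], idx[[4]], drop = FALSE]
}

sum_dim4 <- function(g, k) {
  d <- dim(g)
  perm <- c(setdiff(1:4, k), k)
  gp <- aperm(g, perm)
  s <- rowSums(matrix(gp, prod(d[perm[1:3]]), d[k]))
  kept <- perm[1:3]
  out <- aperm(array(s, d[kept]), order(kept))
  dm <- d
  dm[k] <- 1L
  dim(out) <- dm
  out
}

bc_reduce <- function(g, dv) {
  dg <- dim(g)
  if (identical(dg, dv)) return(g)
  for (k in 1:4) {
    if (dv[k] == 1L && dim(g)[k] > 1L) g <- sum_dim4(g, k)
  }
  g
}

# -- elementwise ops --------------------------------------------------------

is_scalar_v <- function(v) is.null(dim(v)) && length(v) == 1L

ag_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  if (is_scalar_v(a$v) || is_scalar_v(b$v)) {
    sa <- is_scalar_v(a$v); sb <- is_scalar_v(b$v)
    return(ag_node(a$v + b$v, list(a, b), function(g) {
      list(if (sa && !is.null(dim(g))) sum(g) else g,
           if (sb && !is.null(dim(g))) sum(g) else g)
    }))
  }
  da <- dim(a$v); db <- dim(b$v)
  dd <- pmax(da, db)
  v <- bc_expand(a$v, dd) + bc_expand(b$v, dd)
  ag_node(v, list(a, b), function(g) list(bc_reduce(g, da), bc_reduce(g, db)))
}

ag_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  if (is_scalar_v(a$v) || is_scalar_v(b$v)) {
    sa <- is_scalar_v(a$v); sb <- is_scalar_v(b$v)
    return(ag_node(a$v * b$v, list(a, b), function(g) {
      ga <- g * b$v; gb <- g * a$v
      list(if (sa && !is.null(dim(ga))) sum(ga) else ga,
           if (sb && !is.null(dim(gb))) sum(gb) else gb)
    }))
  }
  da <- dim(a$v); db <- dim(b$v)
  dd <- pmax(da, db)
  av <- bc_expand(a$v, dd); bv <- bc_expand(b$v, dd)
  ag_node(av * bv, list(a, b), function(g) {
    list(bc_reduce(g * bv, da), bc_reduce(g * av, db))
  })
}

ag_scale <- function(a, k) {
  a <- as_node(a)
  ag_node(a$v * k, list(a), function(g) list(g * k))
}

ag_relu <- function(a) {
  a <- as_node(a)
  m <- a$v > 0
  ag_node(a$v * m, list(a), function(g) list(g * m))
}

ag_sigmoid <- function(a) {
  a <- as_node(a)
  s <- 1 / (1 + exp(-a$v))
  ag_node(s, list(a), function(g) list(g * s * (1 - s)))
}

# -- structural ops ---------------------------------------------------------

ag_reshape <- function(a, dd) {
  a <- as_node(a)
  dv <- dim(a$v)
  v <- a$v
  dim(v) <- dd
  ag_node(v, list(a), function(g) { dim(g) <- dv; list(g) })
}

ag_concat_c <- function(xs) {
  xs <- lapply(xs, as_node)
  ds <- lapply(xs, function(x) dim(x$v))
  cs <- vapply(ds, function(d) d[3], numeric(1))
  d1 <- ds[[1]]
  tot <- sum(cs)
  d1[3] <- tot
  v <- array(0, dim = d1)
  off <- 0L
  for (i in seq_along(xs)) {
    v[, , off + seq_len(cs[i]), ] <- xs[[i]]$v
    off <- off + cs[i]
  }
  offs <- cumsum(c(0, cs))
  ag_node(v, xs, function(g) {
    lapply(seq_along(xs), function(i) {
      g[, , offs[i] + seq_len(cs[i]), , drop = FALSE]
    })
  })
}

ag_narrow_c <- function(a, from, len) {
  a <- as_node(a)
  dv <- dim(a$v)
  v <- a$v[, , from:(from + len - 1L), , drop = FALSE]
  ag_node(v, list(a), function(g) {
    gx <- array(0, dim = dv)
    gx[, , from:(from + len - 1L), ] <- g
    list(gx)
  })
}

ag_mean_all <- function(a) {
  a <- as_node(a)
  n <- length(a$v)
  ag_node(mean(a$v), list(a), function(g) list(array(g / n, dim = dim(a$v))))
}

ag_sum_all <- function(a) {
  a <- as_node(a)
  ag_node(sum(a$v), list(a), function(g) list(array(g, dim = dim(a$v))))
}

# mean over the channel axis -> (H,W,1,N)
ag_channel_mean <- function(a) {
  a <- as_node(a)
  d <- dim(a$v)
  C <- d[3]
  v <- sum_dim4(a$v, 3L) / C
  ag_node(v, list(a), function(g) {
    list(bc_expand(g / C, d))
  })
}

ag_channel_max <- function(a) {
  a <- as_node(a)
  r <- cpp_chanmax_fw(a$v)
  d <- dim(a$v)
  ag_node(r$y, list(a), function(g) {
    list(cpp_scatter_add(g, r$idx, length(a$v), d))
  })
}

ag_global_avgpool <- function(a) {
  a <- as_node(a)
  d <- dim(a$v)
  ag_node(cpp_adavg_fw(a$v, 1L, 1L), list(a),
          function(g) list(cpp_adavg_bw(g, d[1], d[2])))
}

ag_global_maxpool <- function(a) {
  a <- as_node(a)
  r <- cpp_globalmax_fw(a$v)
  d <- dim(a$v)
  ag_node(r$y, list(a), function(g) {
    list(cpp_scatter_add(g, r$idx, length(a$v), d))
  })
}

ag_adaptive_avgpool <- function(a, ho, wo) {
  a <- as_node(a)
  d <- dim(a$v)
  ag_node(cpp_adavg_fw(a$v, ho, wo), list(a),
          function(g) list(cpp_adavg_bw(g, d[1], d[2])))
}

ag_maxpool2 <- function(a) {
  a <- as_node(a)
  r <- cpp_maxpool2_fw(a$v)
  d <- dim(a$v)
  ag_node(r$y, list(a), function(g) {
    list(cpp_scatter_add(g, r$idx, length(a$v), d))
  })
}

ag_upsample <- function(a, ho, wo) {
  a <- as_node(a)
  d <- dim(a$v)
  if (d[1] == ho && d[2] == wo) return(a)
  ag_node(cpp_resize_bilinear_fw(a$v, ho, wo), list(a),
          function(g) list(cpp_resize_bilinear_bw(g, d[1], d[2])))
}

ag_conv2d <- function(x, w, b = NULL, stride = c(1L, 1L), pad = c(0L, 0L),
                      dil = c(1L, 1L)) {
  x <- as_node(x); w <- as_node(w)
  has_b <- !is.null(b)
  if (has_b) b <- as_node(b)
  bv <- if (has_b) b$v else NULL
  y <- cpp_conv2d_fw(x$v, w$v, bv, stride[1], stride[2], pad[1], pad[2],
                     dil[1], dil[2])
  parents <- if (has_b) list(x, w, b) else list(x, w)
  need_gx <- !isTRUE(x$nograd)
  ag_node(y, parents, function(g) {
    r <- cpp_conv2d_bw(x$v, w$v, g, has_b, need_gx, stride[1], stride[2],
                       pad[1], pad[2], dil[1], dil[2])
    if (has_b) list(if (need_gx) r$gx else NULL, r$gw, r$gb)
    else list(if (need_gx) r$gx else NULL, r$gw)
  })
}

# -- softmax ----------------------------------------------------------------

# softmax over the channel axis of a 4-d tensor
ag_softmax_c <- function(a) {
  a <- as_node(a)
  d <- dim(a$v)
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  xm <- a$v
  dim(xm) <- c(HW, C, N)
  mx <- xm[, 1, , drop = FALSE]
  if (C > 1) for (cc in 2:C) mx <- pmax(mx, xm[, cc, , drop = FALSE])
  e <- exp(xm - bc3(mx, c(HW, C, N)))
  ssum <- e[, 1, , drop = FALSE]
  if (C > 1) for (cc in 2:C) ssum <- ssum + e[, cc, , drop = FALSE]
  s <- e / bc3(ssum, c(HW, C, N))
  dim(s) <- d
  ag_node(s, list(a), function(g) {
    sm <- s; dim(sm) <- c(HW, C, N)
    gm <- g; dim(gm) <- c(HW, C, N)
    gs <- gm * sm
    tot <- gs[, 1, , drop = FALSE]
    if (C > 1) for (cc in 2:C) tot <- tot + gs[, cc, , drop = FALSE]
    gx <- gs - sm * bc3(tot, c(HW, C, N))
    dim(gx) <- d
    list(gx)
  })
}

# broadcast a (m,1,n) slice over (m,C,n)
bc3 <- function(v, dd) {
  v[, rep(1L, dd[2]), , drop = FALSE]
}

# softmax over the rows' second axis of a 3-d array (a, b, N): normalizes
# over axis 2 (used for the node-to-pixel assignment map)
ag_softmax_ax2 <- function(a) {
  a <- as_node(a)
  d <- dim(a$v)
  A <- d[1]; B <- d[2]; N <- d[3]
  x <- a$v
  # max over axis 2
  mx <- x[, 1, , drop = FALSE]
  if (B > 1) {
    if (B <= 64) {
      for (bb in 2:B) mx <- pmax(mx, x[, bb, , drop = FALSE])
    } else {
      mm <- apply(x, c(1, 3), max)
      mx <- array(mm, dim = c(A, 1, N))
    }
  }
  e <- exp(x - mx[, rep(1L, B), , drop = FALSE])
  ssum <- array(apply(e, c(1, 3), sum), dim = c(A, 1, N))
  s <- e / ssum[, rep(1L, B), , drop = FALSE]
  ag_node(s, list(a), function(g) {
    gs <- g * s
    tot <- array(apply(gs, c(1, 3), sum), dim = c(A, 1, N))
    list(gs - s * tot[, rep(1L, B), , drop = FALSE])
  })
}

# -- batched / parameterized matrix products --------------------------------

# batched matmul: A (p,q,N) x B (q,r,N) -> (p,r,N); transpose flags apply
# per sample
ag_bmm <- function(a, b, ta = FALSE, tb = FALSE) {
  a <- as_node(a); b <- as_node(b)
  da <- dim(a$v); db <- dim(b$v)
  N <- da[3]
  p <- if (ta) da[2] else da[1]
  r <- if (tb) db[1] else db[2]
  v <- array(0, dim = c(p, r, N))
  for (n in seq_len(N)) {
    A <- a$v[, , n]; B <- b$v[, , n]
    if (ta) A <- t(A)
    if (tb) B <- t(B)
    v[, , n] <- A %*% B
  }
  ag_node(v, list(a, b), function(g) {
    ga <- array(0, dim = da); gb <- array(0, dim = db)
    for (n in seq_len(N)) {
      G <- g[, , n]
      A <- a$v[, , n]; B <- b$v[, , n]
      if (ta) A <- t(A)
      if (tb) B <- t(B)
      gA <- G %*% t(B)
      gB <- t(A) %*% G
      ga[, , n] <- if (ta) t(gA) else gA
      gb[, , n] <- if (tb) t(gB) else gB
    }
    list(ga, gb)
  })
}

# left-multiply every sample of X (q,r,N) by a 2-d parameter matrix W (p,q)
ag_lmm <- function(w, x) {
  w <- as_node(w); x <- as_node(x)
  dx <- dim(x$v)
  N <- dx[3]
  W <- w$v
  v <- array(0, dim = c(nrow(W), dx[2], N))
  for (n in seq_len(N)) v[, , n] <- W %*% x$v[, , n]
  ag_node(v, list(w, x), function(g) {
    gw <- matrix(0, nrow(W), ncol(W))
    gx <- array(0, dim = dx)
    for (n in seq_len(N)) {
      gw <- gw + g[, , n] %*% t(x$v[, , n])
      gx[, , n] <- t(W) %*% g[, , n]
    }
    list(gw, gx)
  })
}

# right-multiply every sample of X (p,q,N) by a 2-d parameter matrix W (q,r)
ag_rmm <- function(x, w) {
  x <- as_node(x); w <- as_node(w)
  dx <- dim(x$v)
  N <- dx[3]
  W <- w$v
  v <- array(0, dim = c(dx[1], ncol(W), N))
  for (n in seq_len(N)) v[, , n] <- x$v[, , n] %*% W
  ag_node(v, list(x, w), function(g) {
    gw <- matrix(0, nrow(W), ncol(W))
    gx <- array(0, dim = dx)
    for (n in seq_len(N)) {
      gw <- gw + t(x$v[, , n]) %*% g[, , n]
      gx[, , n] <- g[, , n] %*% t(W)
    }
    list(gx, gw)
  })
}
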