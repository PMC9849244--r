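# ---------------------------------------------------------------------------
# Layer constructors and parameter bookkeeping.
#
# A "module" is a nested named list; leaves are ag_param environments
# (trainable) or nn_stats environments (batch-norm running statistics).
# Forward passes are explicit fwd_* functions, so the whole network is a
# tree of plain R lists that can be walked for optimization, counting and
# (de)serialization.
# ---------------------------------------------------------------------------

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

new_stats <- function(C) {
  s <- new.env(parent = emptyenv())
  s$rmu <- rep(0, C)
  s$rvar <- rep(1, C)
  class(s) <- "nn_stats"
  s
}

bn_new <- function(C) {
  list(gamma = new_param(array(1, dim = c(C)), decay = FALSE),
       beta = new_param(array(0, dim = c(C)), decay = FALSE),
       stats = new_stats(C))
}

# per-channel reductions for layout (H,W,C,N)
ch_sum <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  cs <- colSums(m)
  rowSums(matrix(cs, d[3], d[4]))
}

bc_ch <- function(vec, d) {
  array(rep(vec, each = d[1] * d[2]), dim = d)
}

bn_momentum <- 0.1
bn_eps <- 1e-5

ag_bn <- function(x, bn, train) {
  x <- as_node(x)
  gamma <- ag_leaf(bn$gamma)
  beta <- ag_leaf(bn$beta)
  d <- dim(x$v)
  C <- d[3]
  m <- d[1] * d[2] * d[4]
  if (train) {
    mu <- ch_sum(x$v) / m
    xc <- x$v - bc_ch(mu, d)
    va <- ch_sum(xc * xc) / m
    ivar <- 1 / sqrt(va + bn_eps)
    xhat <- xc * bc_ch(ivar, d)
    bn$stats$rmu <- (1 - bn_momentum) * bn$stats$rmu + bn_momentum * mu
    bn$stats$rvar <- (1 - bn_momentum) * bn$stats$rvar + bn_momentum * va
    v <- xhat * bc_ch(gamma$v, d) + bc_ch(beta$v, d)
    ag_node(v, list(x, gamma, beta), function(g) {
      dgamma <- ch_sum(g * xhat)
      dbeta <- ch_sum(g)
      dxhat <- g * bc_ch(gamma$v, d)
      t1 <- ch_sum(dxhat)
      t2 <- ch_sum(dxhat * xhat)
      gx <- bc_ch(ivar / m, d) * (m * dxhat - bc_ch(t1, d) - xhat * bc_ch(t2, d))
      list(gx, array(dgamma, dim = C), array(dbeta, dim = C))
    })
  } else {
    ivar <- 1 / sqrt(bn$stats$rvar + bn_eps)
    xhat <- (x$v - bc_ch(bn$stats$rmu, d)) * bc_ch(ivar, d)
    v <- xhat * bc_ch(gamma$v, d) + bc_ch(beta$v, d)
    ag_node(v, list(x, gamma, beta), function(g) {
      list(g * bc_ch(gamma$v * ivar, d),
           array(ch_sum(g * xhat), dim = C),
           array(ch_sum(g), dim = C))
    })
  }
}

#' @keywords internal
conv_new <- function(cin, cout, kh, kw = kh, stride = 1L, pad = 0L,
                     dil = 1L, bias = !bn, bn = TRUE, act = c("relu", "none")) {
  act <- match.arg(act)
  if (length(stride) == 1L) stride <- c(stride, stride)
  if (length(pad) == 1L) pad <- c(pad, pad)
  if (length(dil) == 1L) dil <- c(dil, dil)
  l <- list(w = new_param(he_init(c(kh, kw, cin, cout), kh * kw * cin)),
            b = if (bias) new_param(array(0, dim = c(cout)), decay = FALSE) else NULL,
            bn = if (bn) bn_new(cout) else NULL,
            stride = as.integer(stride), pad = as.integer(pad),
            dil = as.integer(dil), act = act, cin = cin, cout = cout)
  class(l) <- c("nn_conv", "list")
  l
}

fwd_conv <- function(l, x, train = FALSE) {
  y <- ag_conv2d(x, ag_leaf(l$w),
                 b = if (!is.null(l$b)) ag_leaf(l$b) else NULL,
                 stride = l$stride, pad = l$pad, dil = l$dil)
  if (!is.null(l$bn)) y <- ag_bn(y, l$bn, train)
  if (l$act == "relu") y <- ag_relu(y)
  y
}

# -- walking the module tree ------------------------------------------------

collect_params <- function(mod) {
  out <- list()
  walk <- function(x) {
    if (is_param(x)) {
      out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) {
      for (el in x) if (!is.null(el)) walk(el)
    }
  }
  walk(mod)
  out
}

n_params <- function(mod) {
  sum(vapply(collect_params(mod), function(p) length(p$val), numeric(1)))
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# flat named state for checkpointing (parameters + running statistics)
state_dict <- function(mod) {
  out <- list()
  walk <- function(x, path) {
    if (is_param(x)) {
      out[[path]] <<- x$val + 0 # copy: optimizer updates are in place
    } else if (inherits(x, "nn_stats")) {
      out[[paste0(path, ".rmu")]] <<- x$rmu
      out[[paste0(path, ".rvar")]] <<- x$rvar
    } else if (is.list(x)) {
      nm <- names(x) %||% as.character(seq_along(x))
      for (i in seq_along(x)) {
        if (!is.null(x[[i]]))
          walk(x[[i]], paste0(path, ".", if (nzchar(nm[i])) nm[i] else i))
      }
    }
  }
  walk(mod, "net")
  out
}

load_state_dict <- function(mod, state) {
  seen <- character()
  walk <- function(x, path) {
    if (is_param(x)) {
      v <- state[[path]]
      if (is.null(v) || !identical(dim(v) %||% length(v), dim(x$val) %||% length(x$val)))
        stop("checkpoint/config mismatch at parameter '", path, "'")
      x$val <- v + 0
      seen <<- c(seen, path)
    } else if (inherits(x, "nn_stats")) {
      x$rmu <- state[[paste0(path, ".rmu")]]
      x$rvar <- state[[paste0(path, ".rvar")]]
    } else if (is.list(x)) {
      nm <- names(x) %||% as.character(seq_along(x))
      for (i in seq_along(x)) {
        if (!is.null(x[[i]]))
          walk(x[[i]], paste0(path, ".", if (nzchar(nm[i])) nm[i] else i))
      }
    }
  }
  walk(mod, "net")
  invisible(mod)
}

# -- AdamW ------------------------------------------------------------------

adamw_new <- function(params, lr = 1e-4, weight_decay = 1e-2,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr
  st$wd <- weight_decay
  st$b1 <- beta1
  st$b2 <- beta2
  st$eps <- eps
  st$t <- 0L
  for (p in params) {
    p$m <- array(0, dim = dim(p$val) %||% length(p$val))
    p$vv <- array(0, dim = dim(p$val) %||% length(p$val))
  }
  st
}

adamw_step <- function(opt, lr = opt$lr) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (p in opt$params) {
    if (is.null(p$grad)) next
    cpp_adamw_step(p$val, p$grad, p$m, p$vv, lr, opt$b1, opt$b2, opt$eps,
                   if (p$decay) opt$wd else 0, bc1, bc2)
    p$grad <- NULL
  }
  invisible(NULL)
}

# cosine-annealed learning rate, period = total steps, no restarts
cosine_lr <- function(lr0, step, total, lr_min = 0) {
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * pmin(step, total) / total))
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}
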