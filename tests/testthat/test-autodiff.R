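# The autodiff core is checked against finite differences and straight-line
# oracles; everything downstream rests on these kernels.

fd_grad <- function(f, x, k, eps = 1e-6) (f(x + eps * k) - f(x)) / eps

test_that("conv2d forward matches a nested-loop oracle with dilation", {
  set.seed(3)
  H <- 7; W <- 6; Ci <- 2; Co <- 3
  x <- rand4(H, W, Ci, 2)
  w <- array(rnorm(3 * 3 * Ci * Co), c(3, 3, Ci, Co))
  b <- rnorm(Co)
  y <- ns$cpp_conv2d_fw(x, w, b, 1L, 1L, 2L, 2L, 2L, 2L)
  yo <- array(0, dim(y))
  for (n in 1:2) for (co in 1:Co) for (wo in seq_len(dim(y)[2]))
    for (ho in seq_len(dim(y)[1])) {
      s <- b[co]
      for (ci in 1:Ci) for (j in 1:3) for (i in 1:3) {
        hin <- ho - 2 + (i - 1) * 2
        win <- wo - 2 + (j - 1) * 2
        if (hin >= 1 && hin <= H && win >= 1 && win <= W)
          s <- s + x[hin, win, ci, n] * w[i, j, ci, co]
      }
      yo[ho, wo, co, n] <- s
    }
  expect_lt(max(abs(y - yo)), 1e-12)
})

test_that("elementwise, pooling and resize gradients agree with finite differences", {
  set.seed(4)
  x <- rand4(6, 6, 4, 2)
  cases <- list(
    relu = function(nd) ns$ag_relu(nd),
    sigmoid = function(nd) ns$ag_sigmoid(nd),
    maxpool = function(nd) ns$ag_maxpool2(nd),
    upsample = function(nd) ns$ag_upsample(nd, 9L, 11L),
    adavg = function(nd) ns$ag_adaptive_avgpool(nd, 2L, 2L),
    gmax = function(nd) ns$ag_global_maxpool(nd),
    chmean = function(nd) ns$ag_channel_mean(nd),
    chmax = function(nd) ns$ag_channel_max(nd),
    softc = function(nd) ns$ag_softmax_c(nd))
  for (nm in names(cases)) {
    op <- cases[[nm]]
    seedmask <- array(rnorm(length(x)), dim(x)) # random but fixed direction
    gref <- NULL
    f <- function(xv) {
      ns$ag_tape_start()
      on.exit(ns$ag_tape_end())
      nd <- ns$ag_node(xv)
      out <- op(nd)
      # weight the output so the scalar functional is generic
      s <- ns$ag_sum_all(ns$ag_mul(out, array(1 + 0.1 * seq_along(out$v),
                                              dim(out$v))))
      ns$ag_backward(s)
      gref <<- nd$g
      s$v
    }
    base <- f(x)
    for (rep in 1:4) {
      k <- array(0, dim(x))
      k[sample(length(k), 1)] <- 1
      num <- fd_grad(function(xx) {
        ns$ag_tape_start(); on.exit(ns$ag_tape_end())
        nd <- ns$ag_node(xx)
        out <- op(nd)
        sum(out$v * array(1 + 0.1 * seq_along(out$v), dim(out$v)))
      }, x, k)
      expect_lt(abs(num - sum(gref * k)), 1e-4, label = paste("op", nm))
    }
  }
})

test_that("broadcast add/mul reduce gradients over the broadcast axes", {
  set.seed(5)
  a <- rand4(4, 4, 3, 2)
  b <- rand4(1, 1, 3, 2)  # channel vector
  s <- rand4(4, 4, 1, 2)  # spatial map
  ns$ag_tape_start()
  na <- ns$ag_node(a); nb <- ns$ag_node(b); nsp <- ns$ag_node(s)
  out <- ns$ag_add(ns$ag_mul(na, nb), ns$ag_mul(na, nsp))
  root <- ns$ag_sum_all(out)
  ns$ag_backward(root)
  ns$ag_tape_end()
  # oracle gradients
  ga <- array(0, dim(a)); gb <- array(0, dim(b)); gs <- array(0, dim(s))
  for (n in 1:2) for (c in 1:3) for (w in 1:4) for (h in 1:4) {
    ga[h, w, c, n] <- b[1, 1, c, n] + s[h, w, 1, n]
    gb[1, 1, c, n] <- gb[1, 1, c, n] + a[h, w, c, n]
    gs[h, w, 1, n] <- gs[h, w, 1, n] + a[h, w, c, n]
  }
  expect_lt(max(abs(na$g - ga)), 1e-10)
  expect_lt(max(abs(nb$g - gb)), 1e-10)
  expect_lt(max(abs(nsp$g - gs)), 1e-10)
})

test_that("batched and parameterized matrix products match dense algebra", {
  set.seed(6)
  A <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  B <- array(rnorm(4 * 5 * 2), c(4, 5, 2))
  ns$ag_tape_start()
  na <- ns$ag_node(A); nb <- ns$ag_node(B)
  out <- ns$ag_bmm(na, nb)
  for (n in 1:2) expect_lt(max(abs(out$v[, , n] - A[, , n] %*% B[, , n])), 1e-12)
  G <- array(rnorm(length(out$v)), dim(out$v))
  root <- ns$ag_sum_all(ns$ag_mul(out, G))
  ns$ag_backward(root)
  ns$ag_tape_end()
  for (n in 1:2) {
    expect_lt(max(abs(na$g[, , n] - G[, , n] %*% t(B[, , n]))), 1e-10)
    expect_lt(max(abs(nb$g[, , n] - t(A[, , n]) %*% G[, , n])), 1e-10)
  }
})

test_that("batch normalization gradient matches finite differences", {
  set.seed(7)
  bn <- ns$bn_new(3L)
  x <- rand4(5, 5, 3, 2)
  G <- array(rnorm(length(x)), dim(x))
  run <- function(xv, backward = FALSE) {
    # fresh stats so the running-mean update never leaks between calls
    bn2 <- ns$bn_new(3L)
    bn2$gamma$val <- bn$gamma$val; bn2$beta$val <- bn$beta$val
    ns$ag_tape_start()
    on.exit(ns$ag_tape_end())
    nd <- ns$ag_node(xv)
    out <- ns$ag_bn(nd, bn2, train = TRUE)
    s <- ns$ag_sum_all(ns$ag_mul(out, G))
    if (backward) {
      ns$ag_backward(s)
      return(nd$g)
    }
    s$v
  }
  bn$gamma$val[] <- c(0.7, 1.3, 1.0)
  bn$beta$val[] <- c(0.1, -0.2, 0)
  g <- run(x, backward = TRUE)
  for (rep in 1:5) {
    k <- array(0, dim(x)); k[sample(length(k), 1)] <- 1
    num <- (run(x + 1e-5 * k) - run(x)) / 1e-5
    expect_lt(abs(num - sum(g * k)), 1e-4)
  }
})
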