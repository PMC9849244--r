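test_that("pixel embeddings are independent 16-channel projections of O1", {
  set.seed(40)
  l <- fam_new()
  o1 <- rand4(8, 8, 32, 1)
  qp <- pixel_embed(l, o1)
  expect_identical(dim(qp$Q$v), c(8L, 8L, 16L, 1L))
  expect_identical(dim(qp$P$v), c(8L, 8L, 16L, 1L))
  expect_gt(max(abs(qp$Q$v - qp$P$v)), 0)
  zero_module(l$q_conv); zero_module(l$p_conv)
  qp0 <- pixel_embed(l, o1)
  expect_true(all(qp0$Q$v == 0) && all(qp0$P$v == 0))
})

test_that("detail gate is a channel softmax slice matching an oracle", {
  set.seed(41)
  l <- fam_new()
  o2 <- rand4(16, 16, 128, 1)
  att <- detail_gate(l, o2, c(8L, 8L))
  expect_identical(dim(att$v), c(8L, 8L, 1L, 1L))
  expect_true(all(att$v > 0 & att$v < 1))
  # straight-line oracle: 1x1 conv, bilinear resize, softmax, channel 2
  wmat <- matrix(l$gate_conv$w$val, 128, 32)
  g <- array(0, c(16, 16, 32, 1))
  for (h in 1:16) for (w in 1:16) {
    g[h, w, , 1] <- as.vector(o2[h, w, , 1] %*% wmat) + l$gate_conv$b$val
  }
  g <- ns$cpp_resize_bilinear_fw(g, 8L, 8L)
  for (h in 1:8) for (w in 1:8) {
    e <- exp(g[h, w, , 1] - max(g[h, w, , 1]))
    sm <- e / sum(e)
    expect_lt(abs(sum(sm) - 1), 1e-12)
    expect_lt(abs(att$v[h, w, 1, 1] - sm[2]), 1e-6)
  }
})

test_that("anchor nodes pool the gated embedding; degenerate gates behave", {
  set.seed(42)
  l <- fam_new()
  P <- rand4(8, 8, 16, 1)
  attv <- array(runif(64), c(8, 8, 1, 1))
  V <- build_nodes(l, ns$ag_node(P), ns$ag_node(attv))
  expect_identical(dim(V$v), c(16L, 16L, 1L))
  # zero gate annihilates every node
  V0 <- build_nodes(l, ns$ag_node(P), ns$ag_node(array(0, c(8, 8, 1, 1))))
  expect_true(all(V0$v == 0))
  # constant P with unit gate: every node carries P's constant
  Pc <- array(rep(seq_len(16), each = 64), c(8, 8, 16, 1))
  V1 <- build_nodes(l, ns$ag_node(Pc), ns$ag_node(array(1, c(8, 8, 1, 1))))
  for (k in 1:16) expect_equal(as.vector(V1$v[k, , 1]), as.numeric(1:16))
  expect_error(fam_new(num_nodes = 15L), "perfect square")
})

test_that("assignment rows are pixel distributions matching a double-loop oracle", {
  set.seed(43)
  V <- array(rnorm(16 * 16), c(16, 16, 1))
  P <- rand4(8, 8, 16, 1)
  S <- fam_assign(ns$ag_node(V), ns$ag_node(P))
  expect_identical(dim(S$v), c(16L, 64L, 1L))
  expect_lt(max(abs(apply(S$v[, , 1], 1, sum) - 1)), 1e-5)
  Pf <- matrix(P, 64, 16) # pixels x dims, h-fastest flattening
  for (k in 1:16) {
    logits <- vapply(1:64, function(m) sum(V[k, , 1] * Pf[m, ]), numeric(1))
    e <- exp(logits - max(logits))
    expect_lt(max(abs(S$v[k, , 1] - e / sum(e))), 1e-6)
  }
  # zero nodes give the uniform assignment 1/M
  S0 <- fam_assign(ns$ag_node(array(0, dim(V))), ns$ag_node(P))
  expect_lt(max(abs(S0$v - 1 / 64)), 1e-12)
})

test_that("the project-reason-reproject chain matches dense linear algebra on a toy", {
  set.seed(44)
  l <- fam_new(num_nodes = 4L, node_dim = 16L)
  o1 <- rand4(4, 4, 32, 1) # 16 pixels
  o2 <- rand4(8, 8, 128, 1)
  d1 <- dim(o1)
  o2a <- ns$cpp_resize_bilinear_fw(o2, 4L, 4L)
  att <- detail_gate(l, ns$ag_node(o2a), c(4L, 4L))
  qp <- pixel_embed(l, o1)
  V <- build_nodes(l, qp$P, att)
  S <- fam_assign(V, qp$P)
  Y <- graph_reason(l, S, qp$Q)
  # dense oracle
  Pf <- matrix(qp$P$v, 16, 16)
  Qf <- matrix(qp$Q$v, 16, 16)
  gated <- Pf * as.vector(att$v)
  # adaptive 2x2 pooling of the 4x4 grid, h-fastest cells
  Vo <- matrix(0, 4, 16)
  cell <- list(c(1, 2, 5, 6), c(3, 4, 7, 8), c(9, 10, 13, 14), c(11, 12, 15, 16))
  for (k in 1:4) Vo[k, ] <- colMeans(gated[cell[[k]], ])
  expect_lt(max(abs(V$v[, , 1] - Vo)), 1e-10)
  L <- Vo %*% t(Pf)
  So <- t(apply(L, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
  expect_lt(max(abs(S$v[, , 1] - So)), 1e-10)
  Fn <- So %*% Qf
  G <- (Fn - l$gcn$adj$val %*% Fn) %*% l$gcn$w$val
  G[G < 0] <- 0
  Yo <- t(So) %*% G
  expect_lt(max(abs(matrix(Y$v, 16, 16) - Yo)), 1e-6)
})

test_that("mutual embedding matches its broadcast oracle", {
  set.seed(45)
  l <- fam_new()
  o1 <- rand4(8, 8, 32, 1)
  o2a <- rand4(8, 8, 128, 1)
  R <- mem_forward(l, ns$ag_node(o1), ns$ag_node(o2a))
  expect_identical(dim(R$v), c(8L, 8L, 32L, 1L))
  conv1 <- function(layer, x) node_value(ns$fwd_conv(layer, ns$ag_node(x)))
  L <- conv1(l$mem$l_conv, o2a)
  Lmean <- array(apply(L, c(1, 2), mean), c(8, 8, 1, 1))
  Lp <- conv1(l$mem$lp_conv, Lmean)
  Hf <- conv1(l$mem$h_conv, o1)
  Hgap <- array(apply(Hf, 3, mean), c(1, 1, 32, 1))
  Hfp <- conv1(l$mem$hp_conv, Hgap)
  # explicit per-pixel loops for the broadcast products
  Ro <- array(0, c(8, 8, 32, 1))
  for (c in 1:32) for (w in 1:8) for (h in 1:8) {
    Ro[h, w, c, 1] <- Hfp[1, 1, c, 1] * L[h, w, c, 1] + Hf[h, w, c, 1] * Lp[h, w, 1, 1]
  }
  expect_lt(max(abs(R$v - Ro)), 1e-10)
  # zero detail input: L collapses to its bias plane, so the first term of R
  # becomes a constant per channel and R reduces to bias terms plus Hf * L'
  R0 <- mem_forward(l, ns$ag_node(o1), ns$ag_node(array(0, dim(o2a))))
  L0 <- conv1(l$mem$l_conv, array(0, dim(o2a)))
  Lp0 <- conv1(l$mem$lp_conv, array(apply(L0, c(1, 2), mean), c(8, 8, 1, 1)))
  Ro0 <- array(0, dim(R$v))
  for (c in 1:32) {
    Ro0[, , c, 1] <- Hfp[1, 1, c, 1] * L0[, , c, 1] + Hf[, , c, 1] * Lp0[, , 1, 1]
  }
  expect_lt(max(abs(R0$v - Ro0)), 1e-10)
})

test_that("aggregation output adds the graph branch onto the mutual embedding", {
  set.seed(46)
  l <- fam_new()
  o1 <- rand4(8, 8, 32, 1)
  o2 <- rand4(16, 16, 128, 1)
  z <- fam_forward(l, o1, o2)
  expect_identical(dim(z$v), c(8L, 8L, 32L, 1L))
  # zero graph-branch lift: Z reduces exactly to R
  zero_module(l$y_conv)
  z0 <- fam_forward(l, o1, o2)
  o2a <- ns$cpp_resize_bilinear_fw(o2, 8L, 8L)
  R <- mem_forward(l, ns$ag_node(o1), ns$ag_node(o2a))
  expect_lt(max(abs(z0$v - R$v)), 1e-10)
})

test_that("gradients flow from Z to both inputs", {
  set.seed(47)
  l <- fam_new()
  ns$ag_tape_start()
  n1 <- ns$ag_node(rand4(8, 8, 32, 1))
  n2 <- ns$ag_node(rand4(16, 16, 128, 1))
  z <- fam_forward(l, n1, n2, train = TRUE)
  root <- ns$ag_sum_all(ns$ag_mul(z, array(rnorm(length(z$v)), dim(z$v))))
  ns$ag_backward(root)
  ns$ag_tape_end()
  expect_true(any(n1$g != 0))
  expect_true(any(n2$g != 0))
})
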