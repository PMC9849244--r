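test_that("DDCM branches preserve spatial size for every dilation", {
  set.seed(20)
  for (D in c(1L, 3L, 5L, 7L)) {
    br <- ddcm_new(8L, D)
    x <- rand4(16, 16, 8, 1)
    y <- ddcm_forward(br, x)
    expect_identical(dim(y$v), dim(x))
  }
  expect_error(ddcm_new(8L, 4L), "odd")
})

test_that("FPM is the identity map when all internal weights are zero", {
  set.seed(21)
  l <- fpm_new(32L)
  zero_module(l)
  x <- rand4(8, 8, 32, 2)
  y <- fpm_forward(l, x)
  expect_identical(y$v, x)          # residual carries the input exactly
  expect_error(fpm_new(30L), "divisible by 4")
})

test_that("FPM forward equals a straight-line re-implementation and the chunk cascade is ordered", {
  set.seed(22)
  l <- fpm_new(32L)
  x <- rand4(8, 8, 32, 1)
  # straight-line oracle built from the module's own sub-layers
  u <- ns$fwd_conv(l$entry, ns$ag_node(x))
  chunks <- lapply(0:3, function(i) u$v[, , i * 8 + 1:8, , drop = FALSE])
  refined <- vector("list", 4)
  refined[[1]] <- node_value(ddcm_forward(l$branches[[1]], chunks[[1]]))
  for (j in 2:4) {
    refined[[j]] <- node_value(
      ddcm_forward(l$branches[[j]], refined[[j - 1]] + chunks[[j]]))
  }
  cat4 <- array(0, c(8, 8, 32, 1))
  for (j in 1:4) cat4[, , (j - 1) * 8 + 1:8, ] <- refined[[j]]
  oracle <- node_value(ns$fwd_conv(l$exit, ns$ag_node(cat4))) + x
  expect_lt(max(abs(fpm_forward(l, x)$v - oracle)), 1e-10)
  # cascade order: perturbing the last chunk leaves earlier refined chunks
  # unchanged, perturbing the first changes all later ones
  chunks4b <- chunks; chunks4b[[4]] <- chunks[[4]] + 1
  r13 <- refined
  rb <- refined[[1]]
  expect_identical(node_value(ddcm_forward(l$branches[[1]], chunks4b[[1]])), rb)
  chunks1b <- chunks; chunks1b[[1]] <- chunks[[1]] + 1
  r1b <- node_value(ddcm_forward(l$branches[[1]], chunks1b[[1]]))
  r2b <- node_value(ddcm_forward(l$branches[[2]], r1b + chunks[[2]]))
  expect_gt(max(abs(r1b - refined[[1]])), 0)
  expect_gt(max(abs(r2b - refined[[2]])), 0)
})

test_that("CFM fuses the three taps into a stride-8 map of 32 channels", {
  set.seed(23)
  l <- cfm_new()
  x2p <- rand4(16, 16, 32, 1)
  x3p <- rand4(8, 8, 32, 1)
  x4p <- rand4(4, 4, 32, 1)
  o1 <- cfm_forward(l, x2p, x3p, x4p)
  expect_identical(dim(o1$v), c(16L, 16L, 32L, 1L))
})

test_that("zero X3' annihilates the X41 product branch", {
  set.seed(24)
  l <- cfm_new()
  x2p <- rand4(16, 16, 32, 1)
  x4p <- rand4(4, 4, 32, 1)
  z3 <- array(0, c(8, 8, 32, 1))
  o1 <- cfm_forward(l, x2p, z3, x4p)
  # X41 (fpm_a) only enters X43 through the Hadamard with X3', so with
  # X3' = 0 its parameters cannot influence the output
  for (p in ns$collect_params(l$fpm_a)) p$val <- p$val + 0.5
  o1b <- cfm_forward(l, x2p, z3, x4p)
  expect_equal(o1b$v, o1$v, tolerance = 1e-12)
})

test_that("stage ordering: with the stage-one fusion zeroed, X41/X42 cannot reach O1", {
  set.seed(25)
  l <- cfm_new()
  zero_module(l$fuse1)
  x2p <- rand4(16, 16, 32, 1); x3p <- rand4(8, 8, 32, 1)
  x4p <- rand4(4, 4, 32, 1)
  o1 <- cfm_forward(l, x2p, x3p, x4p)
  for (p in c(ns$collect_params(l$fpm_a), ns$collect_params(l$fpm_b))) {
    p$val <- p$val + 0.3
  }
  o1b <- cfm_forward(l, x2p, x3p, x4p)
  expect_equal(o1b$v, o1$v, tolerance = 1e-12)
})

test_that("gradients from O1 reach all three reduced taps", {
  set.seed(26)
  l <- cfm_new()
  ns$ag_tape_start()
  n2 <- ns$ag_node(rand4(16, 16, 32, 1))
  n3 <- ns$ag_node(rand4(8, 8, 32, 1))
  n4 <- ns$ag_node(rand4(4, 4, 32, 1))
  o1 <- cfm_forward(l, n2, n3, n4, train = TRUE)
  root <- ns$ag_sum_all(ns$ag_mul(o1, array(rnorm(length(o1$v)), dim(o1$v))))
  ns$ag_backward(root)
  ns$ag_tape_end()
  expect_true(any(n2$g != 0))
  expect_true(any(n3$g != 0))
  expect_true(any(n4$g != 0))
})
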