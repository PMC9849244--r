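test_that("boundary weights match a sliding-window oracle and edge cases", {
  expect_true(all(boundary_weights(matrix(0, 8, 8)) == 1))
  expect_true(all(boundary_weights(matrix(1, 8, 8)) == 1))
  gt <- matrix(0, 8, 8)
  gt[3:6, 3:6] <- 1
  w <- boundary_weights(gt, kernel = 3L, omega = 5)
  # brute-force 3x3 mean with symmetric reflection
  refl <- function(i, n) { while (i < 1 || i > n) { if (i < 1) i <- 1 - i; if (i > n) i <- 2 * n + 1 - i }; i }
  wo <- array(0, c(8, 8))
  for (h in 1:8) for (w2 in 1:8) {
    s <- 0
    for (a in -1:1) for (b in -1:1) s <- s + gt[refl(h + a, 8), refl(w2 + b, 8)]
    wo[h, w2] <- 1 + 5 * abs(s / 9 - gt[h, w2])
  }
  expect_lt(max(abs(w[, , 1, 1] - wo)), 1e-12)
  expect_true(all(w >= 1 & w <= 6))
  expect_error(boundary_weights(gt, kernel = 4L), "odd")
})

test_that("weighted BCE hits its analytic anchors and oracle", {
  gt <- matrix(c(1, 0, 1, 0), 2, 2)
  sat <- matrix(c(40, -40, 40, -40), 2, 2)
  expect_lt(weighted_bce(sat, gt)$v, 1e-10)
  # zero logits: ln 2 regardless of the weights
  w <- array(runif(4, 1, 6), c(2, 2, 1, 1))
  expect_equal(weighted_bce(matrix(0, 2, 2), gt, w)$v, log(2), tolerance = 1e-12)
  # random 8x8 against a per-pixel double loop
  set.seed(50)
  z <- matrix(rnorm(64), 8, 8)
  g8 <- matrix(rbinom(64, 1, 0.4), 8, 8)
  wts <- boundary_weights(g8, 5L, 5)
  num <- 0
  for (h in 1:8) for (j in 1:8) {
    p <- sigmoid(z[h, j])
    num <- num + wts[h, j, 1, 1] * (-(g8[h, j] * log(p) + (1 - g8[h, j]) * log(1 - p)))
  }
  expect_lt(abs(weighted_bce(z, g8, wts)$v - num / sum(wts)), 1e-6)
  expect_error(weighted_bce(z, matrix(0.5, 8, 8)), "binary")
})

test_that("weighted IoU loss matches its explicit-sum oracle and limits", {
  gt <- matrix(c(1, 0, 0, 1), 2, 2)
  sat <- ifelse(gt == 1, 1e6, -1e6)
  expect_lt(weighted_iou(sat, gt)$v, 1e-10)        # perfect binary agreement
  z0 <- matrix(-1e6, 2, 2)
  expect_equal(weighted_iou(z0, matrix(0, 2, 2))$v, 0)  # empty/empty smoothing
  set.seed(51)
  z <- matrix(rnorm(64), 8, 8)
  g8 <- matrix(rbinom(64, 1, 0.3), 8, 8)
  wts <- boundary_weights(g8, 5L, 5)
  p <- sigmoid(z)
  I <- sum(wts[, , 1, 1] * p * g8) + 1
  U <- sum(wts[, , 1, 1] * (p + g8 - p * g8)) + 1
  loss <- weighted_iou(z, g8, wts)$v
  expect_lt(abs(loss - (1 - I / U)), 1e-6)
  expect_gte(loss, 0); expect_lte(loss, 1)
})

test_that("loss gradients agree with finite differences", {
  set.seed(52)
  z <- matrix(rnorm(36), 6, 6)
  g6 <- matrix(rbinom(36, 1, 0.5), 6, 6)
  w <- boundary_weights(g6, 3L, 5)
  for (lf in list(function(zz) weighted_bce(zz, g6, w),
                  function(zz) weighted_iou(zz, g6, w),
                  function(zz) alt_losses(zz, g6, "dice"))) {
    grad <- NULL
    ns$ag_tape_start()
    nd <- ns$ag_node(ns$as_tensor4(z))
    root <- lf(nd)
    ns$ag_backward(root)
    grad <- nd$g
    ns$ag_tape_end()
    for (rep in 1:4) {
      k <- sample(36, 1)
      zp <- z; zp[k] <- zp[k] + 1e-6
      num <- (lf(zp)$v - lf(z)$v) / 1e-6
      expect_lt(abs(num - grad[k]), 1e-5)
    }
  }
})

test_that("the comparison loss family reproduces its hand-computed anchors", {
  # soft Dice on the printed 2x2 toy: p = [[1,1],[0,0]], g = [[1,0],[0,0]]
  z <- matrix(c(1e6, -1e6, 1e6, -1e6), 2, 2) # column-major: p = 1,0,1,0
  p_target <- matrix(c(1, 0, 1, 0), 2, 2)
  g <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(sigmoid(z), p_target)
  expect_equal(alt_losses(z, g, "dice")$v, 1 - (2 * 1 + 1) / (2 + 1 + 1))
  # additivity of the combinations
  set.seed(53)
  z <- matrix(rnorm(16), 4, 4)
  g <- matrix(rbinom(16, 1, 0.5), 4, 4)
  expect_equal(alt_losses(z, g, "iou+bce")$v,
               alt_losses(z, g, "iou")$v + alt_losses(z, g, "bce")$v,
               tolerance = 1e-12)
  expect_equal(alt_losses(z, g, "dice+bce")$v,
               alt_losses(z, g, "dice")$v + alt_losses(z, g, "bce")$v,
               tolerance = 1e-12)
  expect_error(alt_losses(z, g, "focal"), "iou, bce, dice")
})

test_that("the deep-supervision total is compositional and well-behaved", {
  set.seed(54)
  z <- array(rnorm(64), c(8, 8, 1, 1))
  g <- array(rbinom(64, 1, 0.4), c(8, 8, 1, 1))
  za <- array(rnorm(64), c(8, 8, 1, 1))
  both <- total_loss(list(main_logits = ns$ag_node(z),
                          aux_logits = ns$ag_node(za)), g)
  w <- boundary_weights(g)
  parts <- weighted_iou(z, g, w)$v + weighted_bce(z, g, w)$v +
    weighted_iou(za, g, w)$v + weighted_bce(za, g, w)$v
  expect_equal(both$v, parts, tolerance = 1e-12)
  # aux == main doubles the single-branch loss
  twice <- total_loss(list(main_logits = ns$ag_node(z),
                           aux_logits = ns$ag_node(z)), g)
  single <- total_loss(list(main_logits = ns$ag_node(z), aux_logits = NULL), g)
  expect_equal(twice$v, 2 * single$v, tolerance = 1e-12)
  # perfect saturated prediction on both branches
  sat <- ifelse(g == 1, 50, -50)
  perfect <- total_loss(list(main_logits = ns$ag_node(sat),
                             aux_logits = ns$ag_node(sat)), g)
  expect_lt(perfect$v, 1e-9)
  # monotone line search toward the saturated-correct solution, aux fixed
  vals <- vapply(seq(0, 1, by = 0.2), function(t) {
    total_loss(list(main_logits = ns$ag_node(z * (1 - t) + sat * t),
                    aux_logits = ns$ag_node(za)), g)$v
  }, numeric(1))
  # strictly decreasing until both terms saturate at machine precision
  expect_true(all(diff(vals) <= 1e-12))
  expect_lt(vals[6], vals[1])
  expect_error(total_loss(list(main_logits = ns$ag_node(z), aux_logits = NULL),
                          array(rbinom(16, 1, 0.5), c(4, 4, 1, 1))),
               "resolution")
})
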