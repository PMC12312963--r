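test_that("concat residual selects blocks under designed projections", {
  set.seed(21)
  f <- 4L
  p <- layerParams(f)
  hPrev <- matrix(rnorm(5 * f), 5, f)
  hNew <- matrix(rnorm(5 * f), 5, f)

  pSel <- p
  pSel$Wr <- rbind(diag(f), matrix(0, f, f)); pSel$br <- numeric(f)
  expect_equal(concatResidual(hPrev, hNew, pSel), hPrev)
  pSel$Wr <- rbind(matrix(0, f, f), diag(f))
  expect_equal(concatResidual(hPrev, hNew, pSel), hNew)

  # independent matrix-product recomputation
  want <- cbind(hPrev, hNew) %*% p$Wr +
    matrix(p$br, 5, f, byrow = TRUE)
  expect_equal(concatResidual(hPrev, hNew, p), want, tolerance = 1e-12)
  expect_error(concatResidual(hPrev, hNew[1:3, ], p), "equal shapes")
})

test_that("coordinate averaging is the equivariant midpoint", {
  set.seed(22)
  x <- matrix(rnorm(15), 5, 3)
  expect_equal(averageCoords(x, x), x)
  expect_equal(averageCoords(matrix(0, 1, 3), matrix(2, 1, 3)),
               matrix(1, 1, 3))
  y <- matrix(rnorm(15), 5, 3)
  motion <- randomRigidMotion()
  expect_lt(max(abs(averageCoords(applyRigidMotion(x, motion),
                                  applyRigidMotion(y, motion)) -
                    applyRigidMotion(averageCoords(x, y), motion))), 1e-12)
})

test_that("coordinate regularizer measures mean Euclidean displacement", {
  x <- matrix(rnorm(12), 4, 3)
  expect_equal(coordRegularizer(x, x), 0)
  expect_equal(coordRegularizer(rbind(c(3, 4, 0)), rbind(c(0, 0, 0))), 5)
  x0 <- rbind(c(0, 0, 0), c(1, 1, 1))
  xf <- rbind(c(1, 0, 0), c(1, 1, 1))
  expect_equal(coordRegularizer(xf, x0), 0.5)

  # invariant under a common rigid motion
  set.seed(23)
  xa <- matrix(rnorm(18), 6, 3); xb <- matrix(rnorm(18), 6, 3)
  motion <- randomRigidMotion()
  expect_lt(abs(coordRegularizer(applyRigidMotion(xa, motion),
                                 applyRigidMotion(xb, motion)) -
                coordRegularizer(xa, xb)), 1e-10)

  # mean of molecule means, not a pooled atom mean
  memb <- c(1L, 1L, 1L, 2L)
  xf2 <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 0, 0), c(0, 2, 0))
  x02 <- matrix(0, 4, 3)
  expect_equal(coordRegularizer(xf2, x02, memb), mean(c(1 / 3, 2)))
})

test_that("pairRegLayer modes route features and coordinates correctly", {
  set.seed(24)
  g <- randomGraph(5)
  f <- ncol(nodeFeatures(g))
  p <- layerParams(f, coordGain = 1)
  h <- nodeFeatures(g)
  x <- coords(g)
  e <- edgeIndex(g)

  frozen <- pairRegLayer(h, x, e, p, pairRegMode("node"))
  expect_identical(frozen$x, x)  # bit-exact

  noRes <- pairRegLayer(h, x, e, p, pairRegMode("coord"))
  raw <- egclForward(h, x, e, p)
  expect_equal(noRes$h, raw$h)
  expect_equal(noRes$x, averageCoords(x, raw$x))

  plain <- pairRegLayer(h, x, e, p, pairRegMode("plain"))
  expect_equal(plain$x, raw$x)
  expect_equal(plain$h, raw$h)

  full <- pairRegLayer(h, x, e, p, pairRegMode("full"))
  expect_equal(full$h, concatResidual(h, raw$h, p))
})

test_that("stacked layers keep invariance and equivariance in every mode", {
  set.seed(25)
  g <- randomGraph(6)
  f <- ncol(nodeFeatures(g))
  depth <- 8L
  ps <- lapply(1:depth, function(l) layerParams(f, coordGain = 1e-2))
  for (preset in c("full", "coord", "node", "plain")) {
    mode <- pairRegMode(preset)
    motion <- randomRigidMotion()
    h1 <- h2 <- nodeFeatures(g)
    x1 <- coords(g)
    x2 <- applyRigidMotion(x1, motion)
    for (l in 1:depth) {
      s1 <- pairRegLayer(h1, x1, edgeIndex(g), ps[[l]], mode)
      s2 <- pairRegLayer(h2, x2, edgeIndex(g), ps[[l]], mode)
      h1 <- s1$h; x1 <- s1$x
      h2 <- s2$h; x2 <- s2$x
    }
    expect_lt(max(abs(h2 - h1)), 1e-7)
    expect_lt(max(abs(x2 - applyRigidMotion(x1, motion))), 1e-7)
  }
})

test_that("the ablation presets map onto the mechanism switches", {
  expect_true(pairRegMode("full")$nodeResidual)
  expect_identical(pairRegMode("full")$coordMode, "average")
  expect_false(pairRegMode("coord")$nodeResidual)
  expect_identical(pairRegMode("coord")$coordMode, "average")
  expect_true(pairRegMode("node")$nodeResidual)
  expect_identical(pairRegMode("node")$coordMode, "frozen")
  expect_error(pairRegMode("full", lambda = -1), "non-negative")
})
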