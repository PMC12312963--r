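makeLayer <- function(f = 4L, m = f, seed = 11L, coordGain = 1e-3) {
  set.seed(seed)
  layerParams(f, m, coordGain)
}

test_that("edge messages depend on coordinates only through distance", {
  p <- makeLayer()
  set.seed(1)
  hi <- rnorm(4); hj <- rnorm(4)
  # same squared distance, any rigid motion: bit-identical message
  expect_identical(edgeMessage(hi, hj, 2.5, p), edgeMessage(hi, hj, 2.5, p))
  # distances differ -> messages differ
  expect_gt(max(abs(edgeMessage(hi, hj, 1, p) - edgeMessage(hi, hj, 4, p))),
            0)
  # zeroed final layer annihilates (SiLU(0) = 0)
  p0 <- p
  p0$We2[] <- 0; p0$be2[] <- 0
  expect_equal(edgeMessage(hi, hj, 1, p0), matrix(0, 1, 4))
  expect_error(edgeMessage(c(hi[1:3], NA), hj, 1, p), "non-finite")
})

test_that("edge gate is a sigmoid of a linear map", {
  p <- makeLayer()
  set.seed(2)
  msg <- rnorm(4)
  # zero weights -> sigmoid(0) = 1/2
  p0 <- p; p0$winf[] <- 0; p0$binf <- 0
  expect_equal(edgeWeight(msg, p0), 0.5)
  # saturation toward 1
  pInf <- p; pInf$binf <- 1e3
  expect_equal(edgeWeight(msg, pInf), 1)
  # matches scalar recomputation
  expect_equal(edgeWeight(msg, p), refEdgeWeight(msg, p), tolerance = 1e-14)
  expect_true(edgeWeight(msg, p) > 0 && edgeWeight(msg, p) < 1)
})

test_that("aggregation equals the naive double loop", {
  p <- makeLayer()
  g <- randomGraph(2, seed = 3)
  e <- edgeIndex(g)
  msgs <- matrix(rnorm(nrow(e) * 4), nrow(e), 4)

  expect_equal(aggregateMessages(msgs, rep(0, nrow(e)), e, 2),
               matrix(0, 2, 4))
  one <- aggregateMessages(msgs, rep(1, nrow(e)), e, 2)
  expect_equal(one[1, ], msgs[e[, 1] == 1, ])
  expect_equal(one[2, ], msgs[e[, 1] == 2, ])

  g6 <- randomGraph(6, seed = 4)
  e6 <- edgeIndex(g6)
  m6 <- matrix(rnorm(nrow(e6) * 4), ncol = 4)
  w6 <- runif(nrow(e6))
  expect_equal(aggregateMessages(m6, w6, e6, 6),
               refAggregate(m6, w6, e6, 6), tolerance = 1e-12)
  expect_error(aggregateMessages(m6, w6, e6, 3), "out of range")
})

test_that("coordinate update is equivariant and honours the zero gate", {
  p <- makeLayer()
  g <- randomGraph(5, seed = 5)
  e <- edgeIndex(g)
  x <- coords(g)
  msgs <- matrix(rnorm(nrow(e) * 4), ncol = 4)

  p0 <- p; p0$wx2[] <- 0
  expect_equal(coordUpdate(x, msgs, e, p0), x)

  x1 <- matrix(rnorm(3), 1, 3)
  expect_equal(coordUpdate(x1, msgs[0, , drop = FALSE],
                           matrix(integer(0), 0, 2), p), x1)

  # group action: moving inputs moves outputs identically (messages fixed,
  # since they are functions of invariant distances)
  pBig <- p; pBig$wx2 <- pBig$wx2 * 1000
  set.seed(6)
  motion <- randomRigidMotion()
  moved <- coordUpdate(applyRigidMotion(x, motion), msgs, e, pBig)
  expect_lt(max(abs(moved - applyRigidMotion(coordUpdate(x, msgs, e, pBig),
                                             motion))), 1e-10)
})

test_that("node update is row-local and matches the scalar oracle", {
  p <- makeLayer()
  set.seed(7)
  h <- matrix(rnorm(20), 5, 4)
  mA <- matrix(rnorm(20), 5, 4)
  out <- nodeUpdate(h, mA, p)
  perm <- sample(5)
  expect_equal(nodeUpdate(h[perm, ], mA[perm, ], p), out[perm, ])
  # zero weights -> constant bias rows
  p0 <- p; p0$Wh2[] <- 0; p0$bh2 <- rnorm(4)
  expect_equal(nodeUpdate(h, mA, p0),
               matrix(p0$bh2, 5, 4, byrow = TRUE))
  # single node vs direct two-layer perceptron evaluation
  expect_equal(drop(nodeUpdate(h[1, , drop = FALSE], mA[1, , drop = FALSE],
                               p)),
               refMLP2(c(h[1, ], mA[1, ]), p$Wh1, p$bh1, p$Wh2, p$bh2),
               tolerance = 1e-12)
  expect_error(nodeUpdate(h, mA[1:3, ], p), "node count")
})

test_that("egclForward matches an unvectorized per-edge reference", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(2:8, 1)
    g <- randomGraph(n)
    p <- makeLayer(f = 6, seed = 100 + seed, coordGain = 1)
    h <- matrix(rnorm(n * 6), n, 6)
    got <- egclForward(h, coords(g), edgeIndex(g), p)
    want <- refEgclForward(h, coords(g), edgeIndex(g), p)
    expect_lt(max(abs(got$h - want$h)), 1e-10)
    expect_lt(max(abs(got$x - want$x)), 1e-10)
  }
})

test_that("egclForward is invariant/equivariant under the group action", {
  p <- makeLayer(f = 6, seed = 12, coordGain = 1)
  g <- randomGraph(6, seed = 13)
  h <- matrix(rnorm(36), 6, 6)
  base <- egclForward(h, coords(g), edgeIndex(g), p)
  set.seed(14)
  for (k in 1:5) {
    motion <- randomRigidMotion()
    moved <- egclForward(h, applyRigidMotion(coords(g), motion),
                         edgeIndex(g), p)
    expect_lt(max(abs(moved$h - base$h)), 1e-8)
    expect_lt(max(abs(moved$x - applyRigidMotion(base$x, motion))), 1e-8)
  }
  # pure reflection: h unchanged, x reflected (update is odd in differences)
  refl <- list(R = -diag(3), t = c(0, 0, 0))
  mirrored <- egclForward(h, -coords(g), edgeIndex(g), p)
  expect_lt(max(abs(mirrored$h - base$h)), 1e-12)
  expect_lt(max(abs(mirrored$x + base$x)), 1e-12)
})

test_that("molecules in a batch do not interact", {
  gA <- randomGraph(4, seed = 15)
  gB <- randomGraph(3, seed = 16)
  b <- batchGraphs(list(gA, gB))
  p <- makeLayer(f = ncol(nodeFeatures(b)), seed = 17)
  h <- nodeFeatures(b)
  joint <- egclForward(h, coords(b), edgeIndex(b), p)
  solo <- Map(function(g) egclForward(nodeFeatures(g), coords(g),
                                      edgeIndex(g), p), list(gA, gB))
  expect_equal(joint$h, rbind(solo[[1]]$h, solo[[2]]$h), tolerance = 1e-12)
  expect_equal(joint$x, rbind(solo[[1]]$x, solo[[2]]$x), tolerance = 1e-12)
})
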