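test_that("the learning-rate schedule ramps, peaks and anneals", {
  expect_equal(lrSchedule(250, 1000), 1e-4)
  expect_equal(lrSchedule(999, 1000), 1e-8)
  expect_equal(lrSchedule(125, 1000), 5e-5)
  expect_equal(lrSchedule(0, 1000), 0)
  # continuous at the warmup/cosine junction
  expect_lt(abs(lrSchedule(251, 1000) - 1e-4), 1e-6)
  # monotone decay after the peak
  lrs <- lrSchedule(250:999, 1000)
  expect_true(all(diff(lrs) <= 0))
  expect_error(lrSchedule(10, 100, warmupEpochs = 25, peak = 1e-8,
                          floor = 1e-4), "peak < floor")
  expect_error(lrSchedule(100, 100, warmupEpochs = 25), "out of range")
})

test_that("total loss is MAE plus the weighted coordinate penalty", {
  expect_equal(totalLoss(c(1, 3), c(2, 2)), 1)
  expect_equal(totalLoss(c(2, 2), c(2, 2),
                         xFinal = matrix(0, 2, 3), x0 = matrix(0, 2, 3),
                         membership = c(1L, 2L), lambda = 5), 0)
  xf <- rbind(c(1, 0, 0)); x0 <- rbind(c(0, 0, 0))
  expect_equal(totalLoss(1, 1, xf, x0, 1L, lambda = 0.5), 0.5)
  # lambda = 0 reduces to plain MAE even with moved coordinates
  expect_equal(totalLoss(c(1, 3), c(2, 2), xf, x0, 1L, lambda = 0), 1)
  expect_error(totalLoss(1, 1, lambda = -0.1), "lambda")
  expect_error(totalLoss(c(1, 2), 1), "per molecule")
})

test_that("readout is permutation invariant and pooling behaves linearly", {
  set.seed(31)
  cfg <- tinyConfig(f = 6)
  p <- initModelParams(cfg)
  h <- matrix(rnorm(5 * 6), 5, 6)
  memb <- rep(1L, 5)
  base <- readoutForward(h, memb, p$readout)$pred
  perm <- sample(5)
  expect_equal(readoutForward(h[perm, ], memb, p$readout)$pred, base,
               tolerance = 1e-12)
  # duplicated molecule under sum pooling doubles the pooled vector
  h2 <- rbind(h, h)
  memb2 <- rep(1L, 10)
  pooledOnce <- readoutForward(h, memb, p$readout, cache = TRUE)$cache$pooled
  pooledTwice <- readoutForward(h2, memb2, p$readout,
                                cache = TRUE)$cache$pooled
  expect_equal(pooledTwice, 2 * pooledOnce, tolerance = 1e-12)
  # mean vs sum pooling differ by the atom count before the final map
  pooledMean <- readoutForward(h, memb, p$readout, pooling = "mean",
                               cache = TRUE)$cache$pooled
  expect_equal(pooledOnce, 5 * pooledMean, tolerance = 1e-12)
  expect_error(readoutForward(h, c(rep(1L, 4), 3L), p$readout), "empty")
})

test_that("model predictions are invariant; coordinates equivariant", {
  set.seed(32)
  cfg <- tinyConfig(nLayers = 3, f = 8)
  p <- initModelParams(cfg)
  g <- randomGraph(6)
  dev <- checkGroupEquivariance(g, p, cfg, nTrials = 10, seed = 33)
  expect_lt(dev[["invariance"]], 1e-7)
  expect_lt(dev[["equivariance"]], 1e-7)
  expect_lt(checkPermutationEquivariance(g, p, cfg, nTrials = 5, seed = 34),
            1e-10)
})

test_that("frozen coordinates pass through a deep stack bit-exactly", {
  set.seed(35)
  cfg <- tinyConfig(nLayers = 4, f = 6, preset = "node")
  p <- initModelParams(cfg)
  g <- randomGraph(5)
  fw <- modelForward(asBatch(g), p, cfg)
  expect_identical(fw$xFinal, coords(g))
})

test_that("zero-initialized coordinate gate leaves coordinates unchanged", {
  set.seed(36)
  cfg <- tinyConfig(nLayers = 3, f = 6, preset = "plain")
  p <- initModelParams(cfg)
  for (l in seq_along(p$layers)) p$layers[[l]]$wx2[] <- 0
  g <- randomGraph(5)
  fw <- modelForward(asBatch(g), p, cfg)
  expect_equal(fw$xFinal, coords(g))
})

test_that("analytic gradients match central finite differences", {
  # tiny models across modes; includes the coordinate-penalty path with
  # inflated coordinate gates so displacements are well away from zero
  for (preset in c("full", "node", "plain")) {
    cfg <- tinyConfig(nLayers = 1, f = 4, preset = preset, lambda = 0.3,
                      seed = 37)
    p <- initModelParams(cfg)
    if (preset != "node")
      for (l in seq_along(p$layers)) p$layers[[l]]$wx2 <-
          p$layers[[l]]$wx2 * 500
    g <- randomGraph(3, seed = 38, target = 0.4)
    b <- asBatch(g)
    lg <- lossAndGradient(b, p, cfg)
    ana <- unlist(lg$grads, use.names = FALSE)
    num <- numericGradient(b, p, cfg)
    nz <- abs(ana) > 1e-7
    expect_gt(sum(nz), 100)
    rel <- abs(num[nz] - ana[nz]) / pmax(abs(num[nz]), abs(ana[nz]))
    expect_lt(max(rel), 1e-4)
  }
})

test_that("parameter shapes are a deterministic function of the config", {
  cfg <- tinyConfig(nLayers = 2, f = 5, seed = 39)
  p1 <- initModelParams(cfg)
  p2 <- initModelParams(cfg)
  expect_identical(p1, p2)
  expect_equal(length(unlist(p1)),
               length(unlist(initModelParams(tinyConfig(nLayers = 2, f = 5,
                                                        seed = 40)))))
  # mismatched feature width is a configuration error
  g <- buildGraph(c("X1", "X2"), rbind(c(0, 0, 0), c(1, 0, 0)),
                  vocabulary = c("X1", "X2"))
  expect_error(modelForward(asBatch(g), p1, cfg), "configuration error")
})
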