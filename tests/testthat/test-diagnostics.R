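test_that("Dirichlet energy matches the formula and the brute-force loop", {
  # constant features have zero energy
  e <- fullEdges2 <- rbind(c(1L, 2L), c(2L, 1L))
  expect_equal(dirichletEnergy(matrix(1, 2, 3), e), 0)
  # N=2 scalar case: (1/4) * (4 + 4) = 2
  expect_equal(dirichletEnergy(matrix(c(0, 2)), e), 2)
  # brute force on random graphs
  for (seed in 1:4) {
    g <- randomGraph(sample(3:8, 1), seed = 50 + seed)
    h <- matrix(rnorm(nAtoms(g) * 5), ncol = 5)
    expect_equal(dirichletEnergy(h, edgeIndex(g)),
                 refDirichlet(h, edgeIndex(g)), tolerance = 1e-12)
    expect_equal(dirichletEnergy(h, edgeIndex(g), normalized = FALSE),
                 refDirichlet(h, edgeIndex(g), normalized = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(dirichletEnergy(matrix(1:4, 2, 2),
                               matrix(integer(0), 0, 2)),
               "contract violation")
})

test_that("Dirichlet energy is invariant to column and node permutations", {
  g <- randomGraph(6, seed = 55)
  h <- matrix(rnorm(36), 6, 6)
  e <- edgeIndex(g)
  base <- dirichletEnergy(h, e)
  expect_equal(dirichletEnergy(h[, sample(6)], e), base, tolerance = 1e-12)
  perm <- sample(6)
  relabeled <- cbind(match(e[, 1], perm), match(e[, 2], perm))
  expect_equal(dirichletEnergy(h[perm, ], relabeled), base,
               tolerance = 1e-12)
})

test_that("energy profiles walk the forward trace", {
  set.seed(56)
  cfg <- tinyConfig(nLayers = 1, f = 6)
  p <- initModelParams(cfg)
  g <- randomGraph(5)
  fw <- modelForward(asBatch(g), p, cfg, withTrace = TRUE)
  prof <- energyProfile(fw$hTrace, edgeIndex(g))
  expect_length(prof, 2L)
  expect_equal(prof[1], dirichletEnergy(fw$hTrace[[1]], edgeIndex(g)))
  # identical consecutive traces give equal energies
  expect_equal(energyProfile(list(fw$hTrace[[1]], fw$hTrace[[1]]),
                             edgeIndex(g))[1:2],
               rep(prof[1], 2))
  # profile of a deep model equals per-layer recomputation
  cfg9 <- tinyConfig(nLayers = 9, f = 6, preset = "plain", seed = 57)
  p9 <- initModelParams(cfg9)
  fw9 <- modelForward(asBatch(g), p9, cfg9, withTrace = TRUE)
  prof9 <- energyProfile(fw9$hTrace, edgeIndex(g))
  expect_length(prof9, 10L)
  expect_equal(prof9,
               vapply(fw9$hTrace, dirichletEnergy, numeric(1),
                      edges = edgeIndex(g)))
})

test_that("group-equivariance harness flags a deliberately broken layer", {
  set.seed(58)
  cfg <- tinyConfig(nLayers = 2, f = 6)
  p <- initModelParams(cfg)
  g <- randomGraph(6)
  dev <- checkGroupEquivariance(g, p, cfg, nTrials = 20, seed = 59)
  expect_lt(dev[["invariance"]], 1e-7)
  expect_lt(dev[["equivariance"]], 1e-7)

  # identity motion only: both deviations vanish
  base <- modelForward(asBatch(g), p, cfg)
  ident <- list(R = diag(3), t = c(0, 0, 0))
  moved <- modelForward(asBatch(transformGraph(g, ident)), p, cfg)
  expect_equal(moved$pred, base$pred)
  expect_equal(moved$xFinal, base$xFinal)

  # mutation test: feed a raw coordinate into the scalar path and the
  # invariance harness must notice
  brokenForward <- function(graph) {
    b <- asBatch(graph)
    fw <- modelForward(b, p, cfg)
    fw$pred + coords(b)[1, 1]
  }
  set.seed(60)
  devBroken <- 0
  for (k in 1:10) {
    motion <- randomRigidMotion()
    devBroken <- max(devBroken,
                     abs(brokenForward(transformGraph(g, motion)) -
                         brokenForward(g)))
  }
  expect_gt(devBroken, 1e-3)
})

test_that("diagnostics reports assemble, print and serialize", {
  set.seed(61)
  cfg <- tinyConfig(nLayers = 2, f = 6)
  p <- initModelParams(cfg)
  gs <- lapply(4:6, randomGraph)
  rep <- diagnoseModel(gs, p, cfg, nTrials = 3, seed = 62)
  expect_s4_class(rep, "DiagnosticsReport")
  expect_length(rep@energies, 3L)
  expect_true(all(rep@energies >= 0))
  expect_output(show(rep), "Dirichlet")

  path <- file.path(withr::local_tempdir(), "report.txt")
  writeDiagnosticsReport(rep, path)
  txt <- readLines(path)
  expect_true(any(grepl("^invariance_deviation=", txt)))
  y <- yaml::read_yaml(paste0(path, ".yaml"))
  expect_equal(length(y$dirichlet_energies), 3L)
})
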