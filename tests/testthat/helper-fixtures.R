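# Shared fixture builders: all data are generated in code at test time.

randomGraph <- function(n, seed = NULL, target = NULL, vocab = qm9Vocabulary()) {
  if (!is.null(seed)) set.seed(seed)
  xyz <- matrix(stats::runif(n * 3, -3, 3), n, 3)
  while (n >= 2 && min(stats::dist(xyz)) < 0.3)
    xyz <- matrix(stats::runif(n * 3, -3, 3), n, 3)
  if (is.null(target)) target <- stats::rnorm(1)
  buildGraph(sample(vocab, n, replace = TRUE), xyz, target = target,
             vocabulary = vocab)
}

tinyConfig <- function(nLayers = 2L, f = 4L, preset = "full", lambda = 0.1,
                       seed = 7L, ...) {
  modelConfig(nLayers = nLayers, fHidden = f, mWidth = f,
              mode = pairRegMode(preset, lambda = lambda), seed = seed, ...)
}

## central finite-difference gradient of the batch loss over the flattened
## parameter vector
numericGradient <- function(batch, params, config, eps = 1e-6) {
  lambda <- if (config$mode$coordMode == "average") config$mode$lambda else 0
  flat <- unlist(params, use.names = FALSE)
  lossAt <- function(v) {
    p <- utils::relist(v, params)
    fw <- modelForward(batch, p, config)
    totalLoss(fw$pred, targets(batch), fw$xFinal, fw$x0,
              membership(batch), lambda)
  }
  vapply(seq_along(flat), function(i) {
    vp <- flat; vm <- flat
    vp[i] <- vp[i] + eps
    vm[i] <- vm[i] - eps
    (lossAt(vp) - lossAt(vm)) / (2 * eps)
  }, numeric(1))
}
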