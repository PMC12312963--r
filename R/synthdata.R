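## Synthetic molecular benchmark: random non-overlapping point clouds with
## categorical atom types and an analytically rigid-motion-invariant scalar
## target, emulating invariant-property prediction on small organic
## molecules without any external download.

#' Configuration of the synthetic benchmark generator
#'
#' Defaults emulate the small-organic setting: 8-16 atoms per molecule from
#' a five-element vocabulary, placed without overlap in a box of half-width
#' 4 length units with a minimum pair distance of 0.9 (a typical bond
#' length), and additive Gaussian target noise with standard deviation 0.1.
#'
#' @param nMolecules number of molecules to generate.
#' @param nAtomsRange integer range \code{c(min, max)} of atoms per molecule
#'   (min >= 2).
#' @param vocabSize number of atom types; 5 uses the element symbols
#'   H, C, N, O, F, other sizes use synthetic symbols.
#' @param boxHalfWidth half-width of the cubic sampling box.
#' @param minDist minimum allowed inter-atomic distance (> 0).
#' @param noiseSd standard deviation of the additive target noise (>= 0).
#' @param seed integer seed; the whole dataset (coordinates, types,
#'   coefficients, noise, split) is a deterministic function of it.
#' @return list of class \code{SynthConfig}.
#' @export
synthConfig <- function(nMolecules = 2500L, nAtomsRange = c(8L, 16L),
                        vocabSize = 5L, boxHalfWidth = 4, minDist = 0.9,
                        noiseSd = 0.1, seed = 1L) {
  nAtomsRange <- as.integer(nAtomsRange)
  if (length(nAtomsRange) != 2L || nAtomsRange[1L] < 2L ||
      nAtomsRange[2L] < nAtomsRange[1L])
    stop("nAtomsRange must be c(min, max) with min >= 2", call. = FALSE)
  if (minDist <= 0) stop("minDist must be positive", call. = FALSE)
  if (noiseSd < 0) stop("noiseSd must be non-negative", call. = FALSE)
  cfg <- list(nMolecules = as.integer(nMolecules),
              nAtomsRange = nAtomsRange,
              vocabSize = as.integer(vocabSize),
              boxHalfWidth = boxHalfWidth, minDist = minDist,
              noiseSd = noiseSd, seed = as.integer(seed))
  class(cfg) <- "SynthConfig"
  cfg
}

synthVocabulary <- function(vocabSize) {
  if (vocabSize == 5L) qm9Vocabulary()
  else paste0("X", seq_len(vocabSize))
}

#' Generate one synthetic molecule
#'
#' Draws the atom count uniformly from the configured range, atom types
#' uniformly from the vocabulary, and coordinates by sequential rejection
#' sampling in the box until all pairwise distances meet the minimum.
#' Consumes the current RNG state.
#'
#' @param config a \code{\link{synthConfig}}.
#' @param maxAttempts rejection attempts per atom before giving up.
#' @return list with \code{atomTypes} and \code{coords}.
#' @export
generateMolecule <- function(config, maxAttempts = 1000L) {
  span <- config$nAtomsRange[2L] - config$nAtomsRange[1L] + 1L
  n <- config$nAtomsRange[1L] + sample.int(span, 1L) - 1L
  vocab <- synthVocabulary(config$vocabSize)
  types <- sample(vocab, n, replace = TRUE)
  b <- config$boxHalfWidth
  xyz <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(maxAttempts)) {
      cand <- stats::runif(3, -b, b)
      if (i == 1L) { placed <- TRUE }
      else {
        prev <- xyz[seq_len(i - 1L), , drop = FALSE]
        d2 <- rowSums((prev - matrix(cand, i - 1L, 3L, byrow = TRUE))^2)
        placed <- all(d2 >= config$minDist^2)
      }
      if (placed) { xyz[i, ] <- cand; break }
    }
    if (!placed)
      stop("generation error: could not place atom ", i, " of ", n,
           " after ", maxAttempts, " attempts; box half-width ",
           b, " too small for minDist ", config$minDist, call. = FALSE)
  }
  list(atomTypes = types, coords = xyz)
}

#' Analytically invariant molecular target
#'
#' The pairwise-potential scalar
#' \code{y = sum_{i<j} a(t_i, t_j) exp(-d_ij) + b(t_i, t_j) / d_ij}: a
#' short-range exponential plus a long-range 1/d term, with coefficients
#' indexed by the unordered type pair.  A pure function of the pairwise
#' distances and types, hence invariant to rigid motions and atom
#' permutations by construction.
#'
#' @param atomTypes character vector of types.
#' @param coords N x 3 coordinate matrix.
#' @param coefTable list with symmetric matrices \code{a} and \code{b}
#'   (vocab x vocab, dimnames = vocabulary).
#' @return scalar target.
#' @export
invariantTarget <- function(atomTypes, coords, coefTable) {
  n <- length(atomTypes)
  if (n < 2L) return(0)
  idx <- match(atomTypes, rownames(coefTable$a))
  if (anyNA(idx)) stop("atom type missing from coefficient table",
                       call. = FALSE)
  d <- as.matrix(stats::dist(coords))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  dij <- d[pairs]
  if (any(dij == 0)) stop("domain error: zero inter-atomic distance",
                          call. = FALSE)
  ai <- coefTable$a[cbind(idx[pairs[, 1L]], idx[pairs[, 2L]])]
  bi <- coefTable$b[cbind(idx[pairs[, 1L]], idx[pairs[, 2L]])]
  sum(ai * exp(-dij) + bi / dij)
}

## draw a symmetric vocab x vocab coefficient matrix from N(0, 1)
randomSymmetricCoefs <- function(vocab) {
  k <- length(vocab)
  m <- matrix(stats::rnorm(k * k), k, k, dimnames = list(vocab, vocab))
  (m + t(m)) / 2
}

#' Generate a full synthetic dataset
#'
#' Seeds the RNG from the configuration, draws one coefficient table for
#' the invariant target, generates the molecules, adds Gaussian noise to
#' the targets, and derives train/validation/test split indices — all from
#' the single configured seed, so the dataset is bit-reproducible.
#'
#' @param config a \code{\link{synthConfig}}.
#' @param splitFractions train/validation/test fractions summing to 1.
#' @return list of class \code{SynthDataset} with \code{graphs} (list of
#'   \code{MolecularGraph} carrying the noisy targets), \code{cleanTargets},
#'   \code{coefTable}, \code{split} (list of index vectors), \code{config}.
#' @examples
#' ds <- generateDataset(synthConfig(nMolecules = 5, seed = 7))
#' length(ds$graphs)
#' @export
generateDataset <- function(config, splitFractions = c(0.7, 0.15, 0.15)) {
  stopifnot(abs(sum(splitFractions) - 1) < 1e-8, length(splitFractions) == 3L)
  set.seed(config$seed)
  vocab <- synthVocabulary(config$vocabSize)
  coefTable <- list(a = randomSymmetricCoefs(vocab),
                    b = randomSymmetricCoefs(vocab))
  mols <- lapply(seq_len(config$nMolecules), function(k)
    generateMolecule(config))
  clean <- vapply(mols, function(mol)
    invariantTarget(mol$atomTypes, mol$coords, coefTable), numeric(1))
  noise <- if (config$noiseSd > 0)
    stats::rnorm(config$nMolecules, 0, config$noiseSd)
  else numeric(config$nMolecules)
  graphs <- lapply(seq_len(config$nMolecules), function(k)
    buildGraph(mols[[k]]$atomTypes, mols[[k]]$coords,
               target = clean[k] + noise[k], vocabulary = vocab))
  ord <- sample.int(config$nMolecules)
  nTr <- round(splitFractions[1L] * config$nMolecules)
  nVa <- round(splitFractions[2L] * config$nMolecules)
  split <- list(train = sort(ord[seq_len(nTr)]),
                val = sort(ord[nTr + seq_len(min(nVa,
                  max(0, config$nMolecules - nTr)))]),
                test = sort(ord[setdiff(seq_len(config$nMolecules),
                                        seq_len(nTr + nVa))]))
  ds <- list(graphs = graphs, cleanTargets = clean, coefTable = coefTable,
             split = split, config = config)
  class(ds) <- "SynthDataset"
  ds
}

#' @export
print.SynthDataset <- function(x, ...) {
  cat("SynthDataset:", length(x$graphs), "molecules,",
      x$config$nAtomsRange[1L], "-", x$config$nAtomsRange[2L],
      "atoms, vocab", x$config$vocabSize, ", noise sd", x$config$noiseSd,
      ", seed", x$config$seed, "\n")
  cat("  split:", length(x$split$train), "train /", length(x$split$val),
      "val /", length(x$split$test), "test\n")
  invisible(x)
}

#' Extract a split of a synthetic dataset
#'
#' @param dataset a \code{SynthDataset}.
#' @param which \code{"train"}, \code{"val"} or \code{"test"}.
#' @return list of \code{MolecularGraph}.
#' @export
datasetSplit <- function(dataset, which = c("train", "val", "test")) {
  which <- match.arg(which)
  dataset$graphs[dataset$split[[which]]]
}
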