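## Oversmoothing and symmetry diagnostics.

#' Dirichlet energy of node features on a graph
#'
#' The graph-smoothness measure
#' \code{E = 1/(2 |E_dir|) * sum_{(i,j)} ||h_i - h_j||^2} over the directed
#' edge set.  Zero iff all node features coincide on a connected graph; a
#' shrinking energy across layers is the standard signature of
#' oversmoothing.  The 1/(2|E_dir|) normalization makes values comparable
#' across molecule sizes; set \code{normalized = FALSE} for the raw sum.
#'
#' @param h N x f feature matrix (a vector is treated as one column).
#' @param edges E x 2 integer matrix of directed edges.
#' @param normalized divide by twice the directed edge count (default).
#' @param scaled additionally divide by the mean squared feature norm
#'   (a Rayleigh-quotient variant).  The raw energy grows with the overall
#'   feature scale, which itself drifts across the layers of an untrained
#'   deep stack; the scaled form isolates smoothness from scale and is the
#'   variant used for layerwise oversmoothing profiles.
#' @return non-negative scalar.
#' @examples
#' dirichletEnergy(matrix(c(0, 2)), rbind(c(1, 2), c(2, 1)))  # 2
#' @export
dirichletEnergy <- function(h, edges, normalized = TRUE, scaled = FALSE) {
  if (is.null(dim(h))) h <- matrix(h, ncol = 1L)
  if (nrow(h) >= 2L && nrow(edges) == 0L)
    stop("contract violation: no edges on a multi-atom graph", call. = FALSE)
  if (nrow(edges) == 0L) return(0)
  d <- h[edges[, 1L], , drop = FALSE] - h[edges[, 2L], , drop = FALSE]
  e <- sum(d * d)
  if (normalized) e <- e / (2 * nrow(edges))
  if (scaled) {
    msq <- mean(rowSums(h * h))
    e <- if (msq > 0) e / msq else 0
  }
  e
}

#' Layerwise Dirichlet-energy profile of a forward trace
#'
#' @param hTrace list of feature matrices as returned by
#'   \code{\link{modelForward}} with \code{withTrace = TRUE}; entry 1 is the
#'   embedded input.
#' @param edges directed edge set of the (batched) graph.
#' @param normalized,scaled see \code{\link{dirichletEnergy}}.
#' @return numeric vector, one energy per trace entry.
#' @export
energyProfile <- function(hTrace, edges, normalized = TRUE, scaled = FALSE) {
  stopifnot(length(hTrace) >= 1L)
  vapply(hTrace, dirichletEnergy, numeric(1), edges = edges,
         normalized = normalized, scaled = scaled)
}

#' Empirical equivariance check under random rigid motions
#'
#' Draws \code{nTrials} random rigid motions (uniform rotations via
#' normalized quaternions, reflections with probability 1/2, translations
#' uniform in [-10, 10]) and reports the worst-case deviation of the scalar
#' prediction (invariance) and of the output coordinates from the
#' group-transformed originals (equivariance).
#'
#' @param graph a \code{MolecularGraph}.
#' @param params model parameters.
#' @param config the \code{\link{modelConfig}}.
#' @param nTrials number of random motions (>= 1).
#' @param seed RNG seed.
#' @return named numeric vector \code{c(invariance =, equivariance =)}.
#' @export
checkGroupEquivariance <- function(graph, params, config, nTrials = 20L,
                                   seed = 1L) {
  stopifnot(nTrials >= 1L)
  set.seed(seed)
  base <- modelForward(asBatch(graph), params, config)
  invDev <- 0
  eqDev <- 0
  for (k in seq_len(nTrials)) {
    motion <- randomRigidMotion()
    moved <- modelForward(asBatch(transformGraph(graph, motion)), params,
                          config)
    invDev <- max(invDev, abs(moved$pred - base$pred))
    expected <- applyRigidMotion(base$xFinal, motion)
    eqDev <- max(eqDev, max(abs(moved$xFinal - expected)))
  }
  c(invariance = invDev, equivariance = eqDev)
}

#' Empirical permutation-equivariance check
#'
#' @param graph a \code{MolecularGraph}.
#' @param params,config model parameters and configuration.
#' @param nTrials random permutations to try.
#' @param seed RNG seed.
#' @return the maximum deviation of the prediction and of the permuted
#'   coordinate rows from the originals.
#' @export
checkPermutationEquivariance <- function(graph, params, config,
                                         nTrials = 10L, seed = 1L) {
  set.seed(seed)
  base <- modelForward(asBatch(graph), params, config)
  dev <- 0
  for (k in seq_len(nTrials)) {
    perm <- sample.int(nAtoms(graph))
    moved <- modelForward(asBatch(permuteGraph(graph, perm)), params, config)
    dev <- max(dev,
               abs(moved$pred - base$pred),
               max(abs(moved$xFinal - base$xFinal[perm, , drop = FALSE])))
  }
  dev
}

#' Assemble a full diagnostics report for a model
#'
#' Computes the layerwise Dirichlet-energy profile (averaged over up to
#' \code{nProfile} molecules) and the three symmetry deviations.
#'
#' @param graphs list of \code{MolecularGraph}.
#' @param params,config model parameters and configuration.
#' @param nTrials trials per symmetry check.
#' @param nProfile molecules over which the energy profile is averaged.
#' @param seed RNG seed.
#' @return A \code{\link{DiagnosticsReport}}.
#' @export
diagnoseModel <- function(graphs, params, config, nTrials = 20L,
                          nProfile = 8L, seed = 1L) {
  probeSet <- graphs[seq_len(min(nProfile, length(graphs)))]
  profiles <- vapply(probeSet, function(g) {
    fw <- modelForward(asBatch(g), params, config, withTrace = TRUE)
    energyProfile(fw$hTrace, edgeIndex(g))
  }, numeric(config$nLayers + 1L))
  eq <- checkGroupEquivariance(graphs[[1L]], params, config, nTrials, seed)
  pd <- checkPermutationEquivariance(graphs[[1L]], params, config,
                                     nTrials, seed + 1L)
  new("DiagnosticsReport",
      energies = rowMeans(matrix(profiles, nrow = config$nLayers + 1L)),
      invarianceDeviation = unname(eq[["invariance"]]),
      equivarianceDeviation = unname(eq[["equivariance"]]),
      permutationDeviation = pd,
      fingerprint = configFingerprint(config))
}

#' Serialize a diagnostics report
#'
#' Writes a plain-text key=value file and, with a \code{.yaml} companion,
#' a machine-readable structured copy.
#'
#' @param report a \code{\link{DiagnosticsReport}}.
#' @param path output path of the text report; the structured copy goes to
#'   \code{paste0(path, ".yaml")}.
#' @return \code{path}, invisibly.
#' @export
writeDiagnosticsReport <- function(report, path) {
  lines <- c(
    paste0("fingerprint=", report@fingerprint),
    paste0("invariance_deviation=", format(report@invarianceDeviation)),
    paste0("equivariance_deviation=",
           format(report@equivarianceDeviation)),
    paste0("permutation_deviation=", format(report@permutationDeviation)),
    paste0("dirichlet_energy_", seq_along(report@energies) - 1L, "=",
           format(report@energies)))
  writeLines(lines, path)
  yaml::write_yaml(list(
    fingerprint = report@fingerprint,
    invariance_deviation = report@invarianceDeviation,
    equivariance_deviation = report@equivarianceDeviation,
    permutation_deviation = report@permutationDeviation,
    dirichlet_energies = as.numeric(report@energies)),
    paste0(path, ".yaml"))
  invisible(path)
}
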