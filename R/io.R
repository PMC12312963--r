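## File I/O: XYZ molecular files, the dataset container, model archives and
## run configurations.

#' Read molecules from an (extended) XYZ file
#'
#' Standard XYZ layout, possibly with several concatenated frames: line 1 an
#' atom count, line 2 a comment (an \code{energy=<float>} token, if present,
#' is parsed as the molecular property), then one \code{symbol x y z} line
#' per atom.
#'
#' @param path input file.
#' @return list of frames, each a list with \code{atomTypes}, \code{coords}
#'   and \code{target} (\code{NA} when absent); an empty file yields an
#'   empty list.
#' @export
readXYZ <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  frames <- list()
  pos <- 1L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1L)
      stop("parse error at line ", pos, ": expected an atom count",
           call. = FALSE)
    if (pos + 1L + n > length(lines))
      stop("parse error at line ", pos, ": truncated frame", call. = FALSE)
    comment <- lines[pos + 1L]
    target <- NA_real_
    tok <- regmatches(comment,
                      regexpr("energy=[-+0-9.eE]+", comment))
    if (length(tok) && nzchar(tok))
      target <- as.numeric(sub("energy=", "", tok))
    types <- character(n)
    xyz <- matrix(NA_real_, n, 3L)
    for (k in seq_len(n)) {
      ln <- pos + 1L + k
      fields <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1L]]
      if (length(fields) < 4L)
        stop("parse error at line ", ln, ": expected 'symbol x y z'",
             call. = FALSE)
      vals <- suppressWarnings(as.numeric(fields[2:4]))
      if (anyNA(vals))
        stop("parse error at line ", ln, ": malformed coordinates",
             call. = FALSE)
      types[k] <- fields[1L]
      xyz[k, ] <- vals
    }
    frames[[length(frames) + 1L]] <-
      list(atomTypes = types, coords = xyz, target = target)
    pos <- pos + 2L + n
  }
  frames
}

#' Write molecules to an XYZ file
#'
#' Deterministic \code{\%.12g} formatting; the output is re-readable by
#' \code{\link{readXYZ}} with coordinates intact to that precision, and a
#' finite property is recorded as an \code{energy=} token on the comment
#' line.
#'
#' @param molecules list of \code{MolecularGraph} objects, or of lists with
#'   \code{atomTypes}, \code{coords} and optional \code{target}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeXYZ <- function(molecules, path) {
  out <- character(0)
  for (mol in molecules) {
    if (is(mol, "MolecularGraph"))
      mol <- list(atomTypes = atomTypes(mol), coords = coords(mol),
                  target = targetValue(mol))
    n <- length(mol$atomTypes)
    comment <- if (!is.null(mol$target) && is.finite(mol$target))
      sprintf("energy=%.12g", mol$target) else "generated"
    body <- sprintf("%s %.12g %.12g %.12g", mol$atomTypes,
                    mol$coords[, 1L], mol$coords[, 2L], mol$coords[, 3L])
    out <- c(out, as.character(n), comment, body)
  }
  writeLines(out, path)
  invisible(path)
}

CONTAINER_VERSION <- 1L

#' Persist and reload a synthetic dataset
#'
#' The container is a single serialized file holding the ragged
#' per-molecule arrays together with the generating configuration for
#' provenance; \code{loadDataset} validates the version tag.
#'
#' @param dataset a \code{SynthDataset}.
#' @param path file path.
#' @return \code{saveDataset}: \code{path} invisibly;
#'   \code{loadDataset}: the dataset.
#' @export
saveDataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "SynthDataset"))
  saveRDS(list(version = CONTAINER_VERSION, kind = "dataset",
               dataset = dataset), path)
  invisible(path)
}

#' @rdname saveDataset
#' @export
loadDataset <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$kind, "dataset") ||
      !identical(obj$version, CONTAINER_VERSION))
    stop("not a compatible dataset container: ", path, call. = FALSE)
  obj$dataset
}

#' Persist and reload a fitted model
#'
#' The archive embeds a version tag and the generating configuration;
#' loading recomputes the configuration fingerprint and refuses a mismatch.
#'
#' @param fit a \code{PairRegFit}.
#' @param path file path.
#' @return \code{saveModel}: \code{path} invisibly; \code{loadModel}: the
#'   fit.
#' @export
saveModel <- function(fit, path) {
  stopifnot(inherits(fit, "PairRegFit"))
  saveRDS(list(version = CONTAINER_VERSION, kind = "model",
               fingerprint = configFingerprint(fit$config), fit = fit),
          path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$kind, "model") ||
      !identical(obj$version, CONTAINER_VERSION))
    stop("not a compatible model archive: ", path, call. = FALSE)
  if (!identical(obj$fingerprint, configFingerprint(obj$fit$config)))
    stop("model archive failed its configuration-hash check: ", path,
         call. = FALSE)
  obj$fit
}

.RUNCONFIG_KEYS <- list(
  dataset = c("type", "path", "nMolecules", "nAtomsMin", "nAtomsMax",
              "vocabSize", "boxHalfWidth", "minDist", "noiseSd", "seed"),
  model = c("nLayers", "fHidden", "mWidth", "mode", "lambda", "readout",
            "cMode", "seed"),
  training = c("batchSize", "epochs", "warmupEpochs", "peakLR", "floorLR",
               "standardize", "seed", "splitTrain", "splitVal", "splitTest"),
  output = c("dir"))

#' Read and write run configurations
#'
#' Run configurations are human-readable YAML with the sections
#' \code{dataset}, \code{model}, \code{training} and \code{output}.
#' Unknown keys are rejected; missing keys take package defaults.  The pair
#' round-trips: \code{readRunConfig(writeRunConfig(cfg, path))} reproduces
#' \code{cfg}.
#'
#' @param path YAML file path.
#' @return a named list of class \code{RunConfig}.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  normalizeRunConfig(raw)
}

#' @rdname readRunConfig
#' @param config a run-configuration list (validated and completed with
#'   defaults).
#' @export
writeRunConfig <- function(config, path) {
  config <- normalizeRunConfig(unclass(config))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname readRunConfig
#' @param raw a raw named list (e.g. parsed YAML).
#' @export
normalizeRunConfig <- function(raw) {
  badTop <- setdiff(names(raw), names(.RUNCONFIG_KEYS))
  if (length(badTop))
    stop("unknown config section(s): ", paste(badTop, collapse = ", "),
         call. = FALSE)
  for (sec in names(.RUNCONFIG_KEYS)) {
    bad <- setdiff(names(raw[[sec]]), .RUNCONFIG_KEYS[[sec]])
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  defaults <- list(
    dataset = list(type = "synthetic", path = NULL, nMolecules = 2500L,
                   nAtomsMin = 8L, nAtomsMax = 16L, vocabSize = 5L,
                   boxHalfWidth = 4, minDist = 0.9, noiseSd = 0.1,
                   seed = 1L),
    model = list(nLayers = 9L, fHidden = 128L, mWidth = NULL,
                 mode = "full", lambda = 0.1, readout = "sum",
                 cMode = "nminus1", seed = 1L),
    training = list(batchSize = 64L, epochs = 1000L, warmupEpochs = 250L,
                    peakLR = 1e-4, floorLR = 1e-8, standardize = TRUE,
                    seed = 1L, splitTrain = 0.7, splitVal = 0.15,
                    splitTest = 0.15),
    output = list(dir = "."))
  cfg <- defaults
  for (sec in names(defaults))
    for (key in names(raw[[sec]]))
      cfg[[sec]][[key]] <- raw[[sec]][[key]]
  intKeys <- list(dataset = c("nMolecules", "nAtomsMin", "nAtomsMax",
                              "vocabSize", "seed"),
                  model = c("nLayers", "fHidden", "mWidth", "seed"),
                  training = c("batchSize", "epochs", "warmupEpochs",
                               "seed"))
  for (sec in names(intKeys))
    for (key in intKeys[[sec]])
      if (!is.null(cfg[[sec]][[key]]))
        cfg[[sec]][[key]] <- as.integer(cfg[[sec]][[key]])
  if (is.null(cfg$model$mWidth)) cfg$model$mWidth <- cfg$model$fHidden
  class(cfg) <- "RunConfig"
  cfg
}

## realize the package objects described by a RunConfig
runConfigToObjects <- function(cfg) {
  mode <- pairRegMode(cfg$model$mode, lambda = cfg$model$lambda)
  sc <- synthConfig(nMolecules = cfg$dataset$nMolecules,
                    nAtomsRange = c(cfg$dataset$nAtomsMin,
                                    cfg$dataset$nAtomsMax),
                    vocabSize = cfg$dataset$vocabSize,
                    boxHalfWidth = cfg$dataset$boxHalfWidth,
                    minDist = cfg$dataset$minDist,
                    noiseSd = cfg$dataset$noiseSd,
                    seed = cfg$dataset$seed)
  mc <- modelConfig(vocabulary = synthVocabulary(cfg$dataset$vocabSize),
                    nLayers = cfg$model$nLayers,
                    fHidden = cfg$model$fHidden,
                    mWidth = cfg$model$mWidth, mode = mode,
                    readout = cfg$model$readout, cMode = cfg$model$cMode,
                    seed = cfg$model$seed)
  tc <- trainControl(epochs = cfg$training$epochs,
                     batchSize = cfg$training$batchSize,
                     warmupEpochs = cfg$training$warmupEpochs,
                     peakLR = cfg$training$peakLR,
                     floorLR = cfg$training$floorLR,
                     standardize = cfg$training$standardize,
                     seed = cfg$training$seed)
  list(synth = sc, model = mc, train = tc,
       splitFractions = c(cfg$training$splitTrain, cfg$training$splitVal,
                          cfg$training$splitTest))
}
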