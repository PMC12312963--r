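## Small numerical primitives shared by the layer and model code.
## Everything here operates on plain double matrices; shapes follow the
## convention rows = items (edges or nodes), columns = feature channels.

## exp() saturates to Inf/0 in double precision, so 1/(1+exp(-x)) maps the
## whole real line to [0, 1] without producing NaN
sigmoidStable <- function(x) 1 / (1 + exp(-x))

## sigmoid-weighted linear unit (SiLU / swish), the smooth activation used in
## all perceptrons here
silu <- function(x) x * sigmoidStable(x)

siluGrad <- function(x) {
  s <- sigmoidStable(x)
  s * (1 + x * (1 - s))
}

## siluGrad when sigmoid(x) is already available from the forward pass
siluGradCached <- function(x, s) s * (1 + x * (1 - s))

## y = x W + b, b broadcast over rows; tolerates zero-row inputs
linearForward <- function(x, W, b = NULL) {
  y <- x %*% W
  if (!is.null(b) && nrow(y) > 0L)
    y <- y + matrix(b, nrow(y), ncol(y), byrow = TRUE)
  y
}

## Glorot-uniform initialization
glorotUniform <- function(nin, nout, gain = 1) {
  lim <- gain * sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

## sum rows of `values` into `n` groups given by `index` (1-based); groups with
## no members get zero rows.  Backbone of all message aggregation.
segmentSum <- function(values, index, n) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  out <- matrix(0, n, ncol(values))
  if (nrow(values) > 0L) {
    r <- rowsum(values, group = index, reorder = TRUE)
    out[as.integer(rownames(r)), ] <- r
  }
  out
}

zerosLike <- function(x) {
  if (is.list(x)) return(lapply(x, zerosLike))
  x * 0
}

## elementwise sum of two parameter-shaped nested lists
addParams <- function(a, b) {
  if (is.list(a)) return(mapply(addParams, a, b, SIMPLIFY = FALSE))
  a + b
}

assertFinite <- function(x, what) {
  if (!all(is.finite(x)))
    stop("non-finite values in ", what, call. = FALSE)
  invisible(x)
}
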