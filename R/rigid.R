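#' Sample a random rigid motion of 3D space
#'
#' Draws a uniformly random rotation (via a normalized quaternion), optionally
#' composes it with a reflection (probability 1/2), and a translation with
#' components uniform on \code{[-translation, translation]}.  Uses the current
#' RNG state; seed with \code{set.seed()} for reproducibility.
#'
#' @param translation Half-width of the uniform translation box (default 10).
#' @param reflections If \code{TRUE} (default) flip the orientation with
#'   probability 1/2, so the motion is drawn from E(3) rather than SE(3).
#' @return A list with components \code{R} (3x3 orthogonal matrix) and
#'   \code{t} (length-3 translation vector).
#' @examples
#' set.seed(1)
#' g <- randomRigidMotion()
#' crossprod(g$R)  # identity up to rounding
#' @export
randomRigidMotion <- function(translation = 10, reflections = TRUE) {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
  if (reflections && stats::runif(1) < 0.5)
    R <- R %*% diag(c(-1, 1, 1))
  t <- stats::runif(3, -translation, translation)
  list(R = R, t = t)
}

#' Apply a rigid motion to a coordinate matrix
#'
#' @param x N x 3 coordinate matrix.
#' @param motion A list with \code{R} and \code{t} as returned by
#'   \code{\link{randomRigidMotion}}.
#' @return The moved N x 3 matrix \code{x R' + t}.
#' @export
applyRigidMotion <- function(x, motion) {
  y <- x %*% t(motion$R)
  y + matrix(motion$t, nrow(y), 3, byrow = TRUE)
}
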