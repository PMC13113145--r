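# Shared numeric helpers: vector geometry, angle wrapping, seeded evaluation.

#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @keywords internal
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  # %% maps exact multiples of 2*pi to -pi; convention here is (-pi, pi]
  y[y <= -pi + 1e-15 & !is.na(y)] <- pi
  y
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  a / n
}

#' Dihedral angle of four points
#'
#' Signed torsion about the B--C axis using the standard atan2 convention;
#' result in (-pi, pi].
#' @keywords internal
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / vnorm(b2))
  wrap_angle(atan2(sum(m1 * n2), sum(n1 * n2)))
}

#' Planar angle at vertex B of points A-B-C, in (0, pi)
#' @keywords internal
planar_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  cosang <- min(1, max(-1, cosang))
  acos(cosang)
}

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so library code does not disturb the
#' caller's random stream; all stochastic torsdiff functions route their
#' `seed` arguments through here.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Optimal rigid superposition RMSD (Kabsch)
#'
#' @param x,y n x 3 coordinate matrices in correspondence.
#' @return root-mean-square deviation after optimal rotation/translation.
#' @keywords internal
kabsch_rmsd <- function(x, y) {
  stopifnot(all(dim(x) == dim(y)))
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  s <- svd(crossprod(yc, xc))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  diff <- xc %*% rot - yc
  sqrt(mean(rowSums(diff^2)))
}
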