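# Small vector-geometry helpers shared by the CG model, the sampler and the
# selection metrics.  All coordinates are plain n x 3 numeric matrices in
# Angstroms; these helpers are internal.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

# deterministic unit vector perpendicular to u
perp_vector <- function(u) {
  ax <- diag(3)[, which.min(abs(u))]
  unitv(pracma_cross(u, ax))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# rotation matrix for angle (radians) about unit axis, Rodrigues form
rotation_matrix <- function(axis, angle) {
  u <- unitv(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# planar angle at b formed by points a-b-c, in degrees
pseudo_angle <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# all pairwise distances between rows of two coordinate matrices
cross_dist <- function(x, y) {
  x2 <- rowSums(x^2)
  y2 <- rowSums(y^2)
  d2 <- outer(x2, y2, "+") - 2 * x %*% t(y)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rotation and translation mapping one coordinate set onto
#' another, computed from the singular value decomposition of the
#' cross-covariance matrix with the usual determinant correction so that the
#' result is a proper rotation (no reflection).
#'
#' @param x,y n x 3 coordinate matrices (x is moved onto y).
#' @return A list with elements `R` (3 x 3 rotation), `t` (length-3
#'   translation) such that `x %*% R + t` superposes `x` onto `y`, and
#'   `rmsd`, the post-fit root-mean-square deviation in Angstroms.
#' @examples
#' x <- matrix(rnorm(15), 5, 3)
#' Rz <- rotation_matrix(c(0, 0, 1), pi / 3)
#' y <- x %*% t(Rz)
#' kabsch(x, y)$rmsd  # ~0
#' @export
kabsch <- function(x, y) {
  stopifnot(is.matrix(x), is.matrix(y), ncol(x) == 3, ncol(y) == 3,
            nrow(x) == nrow(y), nrow(x) >= 3)
  cx <- colMeans(x)
  cy <- colMeans(y)
  xc <- sweep(x, 2, cx)
  yc <- sweep(y, 2, cy)
  s <- svd(t(xc) %*% yc)
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  t <- cy - as.vector(cx %*% R)
  fitted <- x %*% R + matrix(t, nrow(x), 3, byrow = TRUE)
  list(R = R, t = t, rmsd = sqrt(mean(rowSums((fitted - y)^2))))
}

coord_rmsd <- function(x, y) sqrt(mean(rowSums((x - y)^2)))
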