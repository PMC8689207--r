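# Rigid-body and plane geometry helpers shared by the cone-scan and
# comparison machinery.

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Computes the proper rotation `R` and translation `t` minimising
#' \eqn{\sum_i \| R x_i + t - y_i \|^2} over paired coordinate sets.
#'
#' @param x,y Numeric matrices of identical dimension (n x 3), paired rows.
#' @return An object of class `rigid_transform`: list with `R` (3x3 proper
#'   rotation), `t` (length-3 translation) and `rmsd` (coordinate RMSD of the
#'   fit, in the units of the input).
#' @examples
#' x <- matrix(rnorm(12), 4, 3)
#' tr <- kabsch(x, x)          # identity, rmsd 0
#' @export
kabsch <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == 3L, ncol(y) == 3L, nrow(x) == nrow(y), nrow(x) >= 3L)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("kabsch: non-finite coordinates")
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  # degenerate (collinear) sets have a rank-deficient cross-covariance
  s <- svd(crossprod(x0, y0))
  if (s$d[2] < 1e-10 * max(s$d[1], 1e-12))
    stop("kabsch: degenerate (collinear or coincident) point set")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- cy - as.vector(R %*% cx)
  fitted <- apply_transform(list(R = R, t = t), x)
  rmsd <- sqrt(mean(rowSums((fitted - y)^2)))
  structure(list(R = R, t = t, rmsd = rmsd), class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param tr A `rigid_transform` (or list with `R`, `t`).
#' @param x n x 3 coordinate matrix or length-3 vector.
#' @return Transformed coordinates, same shape as `x`.
#' @export
apply_transform <- function(tr, x) {
  vec <- is.null(dim(x))
  x <- rbind(x)
  out <- x %*% t(tr$R) + matrix(tr$t, nrow(x), 3, byrow = TRUE)
  if (vec) as.vector(out) else out
}

#' Invert a rigid transform
#' @param tr A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(tr) {
  Rt <- t(tr$R)
  structure(list(R = Rt, t = as.vector(-Rt %*% tr$t), rmsd = tr$rmsd),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform: rotation + translation, fit rmsd",
      format(x$rmsd, digits = 4), "\n")
  invisible(x)
}

# Unit vector
unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

# Rotation matrix about an arbitrary axis (Rodrigues), angle in degrees.
rotation_about_axis <- function(axis, angle_deg) {
  k <- unit3(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Least-squares plane through points: returns list(center, normal).
fit_plane <- function(pts) {
  pts <- as.matrix(pts)
  ctr <- colMeans(pts)
  s <- svd(sweep(pts, 2, ctr))
  list(center = ctr, normal = s$v[, 3])
}

# Project points into a plane given by center + unit normal.
project_to_plane <- function(p, plane) {
  p <- rbind(p)
  d <- (p - matrix(plane$center, nrow(p), 3, byrow = TRUE)) %*% plane$normal
  out <- p - d %*% t(plane$normal)
  if (nrow(out) == 1L) as.vector(out) else out
}
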