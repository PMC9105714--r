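#' Least-squares plane through a set of points
#'
#' Fits the total-least-squares plane to three or more points (typically the
#' aromatic ring atoms of a dye molecule) via singular value decomposition of
#' the centered coordinates. The returned normal has unit length; its sign is
#' fixed so that the z component is positive (falling back to x, then y, when
#' the preceding components vanish), making the fit deterministic.
#'
#' @param points numeric matrix (or data frame) with columns x, y, z and at
#'   least 3 rows; rows must not be collinear.
#' @return a list with elements `centroid` (length-3 numeric) and `normal`
#'   (unit length-3 numeric).
#' @examples
#' ring <- cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), z = 0)
#' fit_ring_plane(ring)$normal # c(0, 0, 1)
#' @export
fit_ring_plane <- function(points) {
  if (is.data.frame(points)) {
    m <- as.matrix(points[, c("x", "y", "z")])
  } else {
    m <- as.matrix(points)
    if (!is.null(colnames(m)) && all(c("x", "y", "z") %in% colnames(m))) {
      m <- m[, c("x", "y", "z"), drop = FALSE]
    }
  }
  storage.mode(m) <- "double"
  if (nrow(m) < 3) {
    .gs_abort("plane fit needs at least 3 points", "gagstack_degenerate_plane")
  }
  ctr <- colMeans(m)
  cen <- sweep(m, 2, ctr)
  sv <- svd(cen)
  # collinear (or coincident) points: no unique plane
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12)) {
    .gs_abort("plane fit is degenerate: points are collinear or coincident",
              "gagstack_degenerate_plane")
  }
  n <- sv$v[, 3]
  n <- n / sqrt(sum(n^2))
  n <- .orient_normal(n)
  list(centroid = unname(ctr), normal = unname(n))
}

# deterministic sign convention for a unit normal
.orient_normal <- function(n, tol = 1e-12) {
  for (k in c(3, 1, 2)) {
    if (abs(n[k]) > tol) {
      if (n[k] < 0) n <- -n
      return(n)
    }
  }
  n
}

#' Mean inter-plane distance between two ring systems
#'
#' Distance between the aromatic planes of two molecules, computed as the
#' mean of the two unsigned centroid-to-plane distances (centroid of the
#' first to the plane of the second and vice versa). The measure is
#' symmetric in its arguments and is zero for purely in-plane offsets,
#' which is what makes it suitable for detecting face-to-face stacking:
#' two coplanar molecules lying side by side score 0, while a stacked pair
#' scores its normal separation (about 3.7 Angstrom for phenothiazine dyes).
#'
#' @param ring_a,ring_b coordinate matrices of the ring atoms of the two
#'   molecules (columns x, y, z).
#' @return distance in Angstrom (non-negative scalar).
#' @export
interplane_distance <- function(ring_a, ring_b) {
  pa <- fit_ring_plane(ring_a)
  pb <- fit_ring_plane(ring_b)
  d_ab <- abs(sum((pa$centroid - pb$centroid) * pb$normal))
  d_ba <- abs(sum((pb$centroid - pa$centroid) * pa$normal))
  (d_ab + d_ba) / 2
}

#' Classify the mutual orientation of two stacked dye molecules
#'
#' Compares the long axes of two molecules, each defined as the unit vector
#' from the first to the second terminal dimethylamino nitrogen. A positive
#' dot product means the molecules point the same way (parallel), a negative
#' one that they point opposite ways (antiparallel). Perpendicular long axes
#' (dot product numerically zero) are flagged indeterminate.
#'
#' @param n_pair_a,n_pair_b 2 x 3 matrices: rows are the coordinates of the
#'   two terminal nitrogens of each molecule, in template order.
#' @param tol numerical tolerance for the perpendicular case.
#' @return one of `"parallel"`, `"antiparallel"`, `"indeterminate"`.
#' @export
classify_orientation <- function(n_pair_a, n_pair_b, tol = 1e-8) {
  ua <- .unit(n_pair_a[2, ] - n_pair_a[1, ])
  ub <- .unit(n_pair_b[2, ] - n_pair_b[1, ])
  d <- sum(ua * ub)
  if (abs(d) <= tol) "indeterminate" else if (d > 0) "parallel" else "antiparallel"
}

.unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) .gs_abort("zero-length axis vector", "gagstack_bad_argument")
  v / nv
}

#' Rotation matrix from axis and angle
#'
#' Rodrigues' formula; used for rigid-body placement of dye molecules.
#'
#' @param axis length-3 axis (need not be normalized).
#' @param theta angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about <- function(axis, theta) {
  u <- .unit(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# internal: rotation with columns (long axis u, in-plane w, normal n);
# builds a proper orthonormal frame from a long-axis direction and a normal
.frame_from <- function(u, n) {
  u <- .unit(u); n <- .unit(n)
  w <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  cbind(u, .unit(w), n, deparse.level = 0)
}

# internal: apply pose (rotation R, translation t) to template coordinates
.apply_pose <- function(template_xyz, R, t) {
  sweep(template_xyz %*% t(R), 2, -t)
}
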