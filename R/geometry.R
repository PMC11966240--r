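# Elementary 3D geometry: residue frames, rigid motions, superposition.
# Points are numeric length-3 vectors (x, y, z) in Angstrom; point sets are
# n x 3 matrices with one point per row.

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

#' Construct a rigid motion (proper rotation plus translation)
#'
#' @param rotation 3x3 orthogonal matrix with determinant +1.
#' @param translation numeric length-3 translation vector in Angstrom.
#' @param tol tolerance for the orthogonality and determinant checks.
#' @return An object of class `rigid_motion` with elements `rotation` and
#'   `translation`.
#' @details Reflections (determinant -1) are rejected: the equivalence under
#'   which backbones are compared is orientation-preserving, and chirality is
#'   detected, not factored out.
#' @export
rigid_motion <- function(rotation, translation = c(0, 0, 0), tol = 1e-10) {
  rotation <- unname(as.matrix(rotation))
  if (!all(dim(rotation) == c(3L, 3L))) {
    stop_dupscan("rotation must be a 3x3 matrix", "dupscan_improper_rotation")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > tol) {
    stop_dupscan("rotation matrix is not orthogonal within tolerance",
                 "dupscan_improper_rotation")
  }
  if (abs(det(rotation) - 1) > tol) {
    stop_dupscan("rotation matrix has determinant != +1 (improper rotation)",
                 "dupscan_improper_rotation")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_motion")
}

#' Draw a uniformly random rigid motion
#'
#' Rotation sampled from the Haar measure on SO(3) (QR of a Gaussian matrix
#' with sign fix), translation components uniform on `[-max_shift, max_shift]`.
#'
#' @param max_shift half-width of the uniform translation box in Angstrom.
#' @return A `rigid_motion`.
#' @export
random_rigid_motion <- function(max_shift = 50) {
  m <- matrix(stats::rnorm(9), 3L, 3L)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  rigid_motion(q, stats::runif(3, -max_shift, max_shift))
}

#' Apply a rigid motion to a set of points
#'
#' @param coords n x 3 matrix of coordinates (or a length-3 vector).
#' @param motion a `rigid_motion`.
#' @return Coordinates of the same shape, each point mapped to
#'   `rotation %*% p + translation`.
#' @export
apply_rigid_motion <- function(coords, motion) {
  if (!inherits(motion, "rigid_motion")) {
    motion <- rigid_motion(motion$rotation, motion$translation)
  }
  vec <- is.null(dim(coords))
  m <- if (vec) matrix(coords, 1L, 3L) else as.matrix(coords)
  out <- m %*% t(motion$rotation)
  out <- sweep(out, 2L, motion$translation, "+")
  if (vec) out[1L, ] else out
}

#' Invert a rigid motion
#' @param motion a `rigid_motion`.
#' @return The inverse `rigid_motion`.
#' @export
invert_rigid_motion <- function(motion) {
  rt <- t(motion$rotation)
  rigid_motion(rt, -as.numeric(rt %*% motion$translation))
}

#' Build the orthonormal frame of one residue
#'
#' The frame has its origin at CA, first axis along CA->N, third axis along
#' the normal of the N-CA-C plane and second axis completing a right-handed
#' triple.  It is continuous in the three atoms and equivariant under rigid
#' motion; under reflection the third axis flips, which is what makes the
#' invariant built on these frames chirality-sensitive.
#'
#' @param n,ca,c coordinates (length-3 numeric) of the backbone N, CA and C
#'   atoms of the residue.
#' @param tol minimum norm of the cross product (N-CA) x (C-CA), in square
#'   Angstrom, below which the atoms are considered collinear or coincident.
#' @return An object of class `residue_frame`: list with `origin` and unit
#'   vectors `e1`, `e2`, `e3` (rows of a rotation matrix).
#' @export
build_frame <- function(n, ca, c, tol = 1e-6) {
  u <- n - ca
  v <- c - ca
  w <- cross3(u, v)
  nw <- vnorm(w)
  if (!is.finite(nw) || nw <= tol) {
    stop_dupscan(
      "degenerate residue frame: N, CA, C coincide or are collinear",
      "dupscan_degenerate_frame")
  }
  e1 <- u / vnorm(u)
  e3 <- w / nw
  e2 <- cross3(e3, e1)
  structure(list(origin = as.numeric(ca), e1 = e1, e2 = e2, e3 = e3),
            class = "residue_frame")
}

#' Express points in the local coordinates of a frame
#'
#' @param p length-3 vector or n x 3 matrix of global coordinates.
#' @param frame a `residue_frame`.
#' @return Local coordinates `((p - origin) . e1, . e2, . e3)`, same shape
#'   as the input.
#' @export
express_in_frame <- function(p, frame) {
  basis <- rbind(frame$e1, frame$e2, frame$e3)
  vec <- is.null(dim(p))
  m <- if (vec) matrix(p, 1L, 3L) else as.matrix(p)
  out <- sweep(m, 2L, frame$origin, "-") %*% t(basis)
  if (vec) out[1L, ] else out
}

#' Map local frame coordinates back to global coordinates
#'
#' Exact inverse of [express_in_frame()].
#'
#' @param local length-3 vector or n x 3 matrix of local coordinates.
#' @param frame a `residue_frame`.
#' @return Global coordinates, same shape as the input.
#' @export
frame_to_global <- function(local, frame) {
  basis <- rbind(frame$e1, frame$e2, frame$e3)
  vec <- is.null(dim(local))
  m <- if (vec) matrix(local, 1L, 3L) else as.matrix(local)
  out <- m %*% basis
  out <- sweep(out, 2L, frame$origin, "+")
  if (vec) out[1L, ] else out
}

#' Optimal rigid superposition of two point sets (Kabsch)
#'
#' Finds the proper rigid motion minimising the RMSD of `a` onto `b` via the
#' SVD of the cross-covariance matrix, with the usual sign correction so the
#' returned rotation is proper (no reflection).
#'
#' @param a,b n x 3 coordinate matrices with corresponding rows, n >= 3.
#' @return List with `motion` (the `rigid_motion` mapping `a` onto `b`) and
#'   `rmsd` in Angstrom.
#' @export
kabsch_superpose <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) {
    stop_dupscan("point sets have different sizes", "dupscan_length_mismatch")
  }
  if (nrow(a) < 3L) {
    stop_dupscan("need at least 3 points to superpose", "dupscan_too_few_points")
  }
  ca_ <- colMeans(a); cb_ <- colMeans(b)
  am <- sweep(a, 2L, ca_); bm <- sweep(b, 2L, cb_)
  h <- crossprod(am, bm)           # 3x3
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  motion <- rigid_motion(rot, cb_ - as.numeric(rot %*% ca_))
  moved <- apply_rigid_motion(a, motion)
  rmsd <- sqrt(mean(rowSums((moved - b)^2)))
  list(motion = motion, rmsd = rmsd)
}
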