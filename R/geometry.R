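## Low-level 3D geometry: internal-coordinate placement (NeRF), torsion and
## bond-angle measurement, and Kabsch superposition.  All coordinates are in
## Angstrom, all angles in degrees unless a function name says otherwise.

DEG <- pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize zero vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Wrap an angle in degrees into (-180, 180].
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Dihedral angle of four points
#'
#' IUPAC sign convention: looking from b to c, the angle from the a-side
#' half-plane to the d-side half-plane, positive clockwise.
#'
#' @param a,b,c,d numeric 3-vectors.
#' @return angle in degrees in (-180, 180].
#' @keywords internal
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(atan2(y, x) / DEG)
}

## Row-wise dihedral angles for n x 3 matrices (same convention as
## dihedral_angle).
dihedral_angle_m <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cbind(b1[, 2] * b2[, 3] - b1[, 3] * b2[, 2],
              b1[, 3] * b2[, 1] - b1[, 1] * b2[, 3],
              b1[, 1] * b2[, 2] - b1[, 2] * b2[, 1])
  n2 <- cbind(b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2],
              b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3],
              b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1])
  nb2 <- sqrt(rowSums(b2^2))
  u2 <- b2 / nb2
  m1 <- cbind(n1[, 2] * u2[, 3] - n1[, 3] * u2[, 2],
              n1[, 3] * u2[, 1] - n1[, 1] * u2[, 3],
              n1[, 1] * u2[, 2] - n1[, 2] * u2[, 1])
  wrap_angle(atan2(rowSums(m1 * n2), rowSums(n1 * n2)) / DEG)
}

## Bond angle a-b-c in degrees.
bond_angle <- function(a, b, c) {
  u <- unitv(a - b); v <- unitv(c - b)
  acos(max(-1, min(1, sum(u * v)))) / DEG
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Places atom X bonded to \code{c} with bond length \code{bond}, bond angle
#' X-c-b equal to \code{angle} and dihedral X-c-b-a equal to \code{dihedral}.
#'
#' @param a,b,c numeric 3-vectors of previously placed atoms.
#' @param bond bond length X-c (Angstrom).
#' @param angle bond angle X-c-b (degrees).
#' @param dihedral torsion X-c-b-a (degrees).
#' @return numeric 3-vector, the position of X.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- angle * DEG
  ph <- dihedral * DEG
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(th),
          bond * sin(th) * cos(ph),
          -bond * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## Rotation matrix for rotation by `theta` degrees about unit axis `u`
## (Rodrigues).
rotation_about_axis <- function(u, theta) {
  u <- unitv(u)
  th <- theta * DEG
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Kabsch superposition of paired coordinate sets
#'
#' Finds the proper rotation R and translation t minimizing the (optionally
#' weighted) RMSD between \code{R \%*\% mobile + t} and \code{reference}.
#'
#' @param mobile,reference n x 3 coordinate matrices with paired rows.
#' @param weights optional non-negative per-point weights.
#' @return list with elements \code{rotation} (3 x 3, det +1),
#'   \code{translation} (length 3), \code{rms} (Angstrom) and
#'   \code{transform}, a function mapping an m x 3 matrix through the fit.
#' @examples
#' x <- matrix(rnorm(30), 10, 3)
#' fit <- kabsch_superpose(x, x)
#' fit$rms  # 0
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3 || nrow(reference) != n)
    stop("need >= 3 paired points")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  X <- sweep(mobile, 2, cm)
  Y <- sweep(reference, 2, cr)
  H <- t(X * w) %*% Y
  sv <- svd(H)
  if (min(sv$d) < 1e-12 && sv$d[2] < 1e-12)
    stop("degenerate (collinear) point set")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tr <- cr - as.numeric(R %*% cm)
  moved <- t(R %*% t(mobile)) + matrix(tr, n, 3, byrow = TRUE)
  rms <- sqrt(sum(w * rowSums((moved - reference)^2)))
  transform <- function(xyz) {
    xyz <- as.matrix(xyz)
    t(R %*% t(xyz)) + matrix(tr, nrow(xyz), 3, byrow = TRUE)
  }
  list(rotation = R, translation = tr, rms = rms, transform = transform)
}

## Rigid transform mapping three source points exactly onto three target
## points (assumes congruent triangles); built from orthonormal frames.
rigid_from_three_points <- function(src, dst) {
  frame_of <- function(p) {
    e1 <- unitv(p[2, ] - p[1, ])
    v <- p[3, ] - p[1, ]
    v <- v - sum(v * e1) * e1
    e2 <- unitv(v)
    cbind(e1, e2, vcross(e1, e2))
  }
  Fs <- frame_of(src); Fd <- frame_of(dst)
  R <- Fd %*% t(Fs)
  tr <- dst[1, ] - as.numeric(R %*% src[1, ])
  function(xyz) {
    xyz <- if (is.matrix(xyz)) xyz else matrix(xyz, 1)
    t(R %*% t(xyz)) + matrix(tr, nrow(xyz), 3, byrow = TRUE)
  }
}

## Plain (unsuperposed) RMSD between two n x 3 matrices.
rmsd_direct <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  sqrt(mean(rowSums((a - b)^2)))
}
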