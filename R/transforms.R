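## Rigid-body transforms. Rotations are intrinsic ZYZ Euler angles in
## degrees: R = Rz(z1) %*% Ry(y) %*% Rz(z2), acting on column vectors.

#' Rotation matrix from intrinsic ZYZ Euler angles
#'
#' @param z1,y,z2 Euler angles in degrees (intrinsic z-y'-z'' convention).
#' @return A 3x3 proper rotation matrix.
#' @export
euler_zyz <- function(z1, y, z2) {
  rz <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  }
  ry <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  }
  rz(z1) %*% ry(y) %*% rz(z2)
}

#' Recover ZYZ Euler angles from a rotation matrix
#'
#' Inverse of [euler_zyz()]. At the gimbal singularity (y = 0 or 180) the
#' split between z1 and z2 is degenerate; z2 is set to 0.
#'
#' @param R 3x3 proper rotation matrix.
#' @return Numeric vector `c(z1, y, z2)` in degrees, y in \[0, 180\].
#' @export
matrix_to_euler_zyz <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  cy <- max(-1, min(1, R[3, 3]))
  y <- acos(cy)
  if (sin(y) > 1e-10) {
    z1 <- atan2(R[2, 3], R[1, 3])
    z2 <- atan2(R[3, 2], -R[3, 1])
  } else {
    ## Rz(z1) Rz(z2) (y = 0) or Rz(z1) Ry(180) Rz(z2): fold into z1
    z1 <- atan2(R[2, 1], R[1, 1]) * sign(cy)
    if (cy < 0) z1 <- atan2(-R[2, 1], -R[1, 1])
    z2 <- 0
  }
  c(z1, y, z2) * 180 / pi
}

#' Construct a rigid transform
#'
#' A rotation (given either as ZYZ Euler angles or a matrix) plus a
#' translation in nm. Applying the transform to a point p gives
#' `R %*% p + t`.
#'
#' @param rotation 3x3 rotation matrix, or length-3 numeric of ZYZ Euler
#'   angles in degrees.
#' @param translation Length-3 numeric shift in nm.
#' @return An object of class `rigid_transform` with elements `R`
#'   (matrix), `euler` (degrees) and `t` (nm).
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  if (is.matrix(rotation)) {
    R <- rotation
  } else {
    stopifnot(length(rotation) == 3)
    R <- euler_zyz(rotation[1], rotation[2], rotation[3])
  }
  stopifnot(all(dim(R) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(R = R, euler = matrix_to_euler_zyz(R),
                 t = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: ZYZ = (%.2f, %.2f, %.2f) deg, t = (%.2f, %.2f, %.2f) nm\n",
              x$euler[1], x$euler[2], x$euler[3], x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose_rigid(a, b)` returns the transform equivalent to applying `b`
#' first, then `a`.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_rigid <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#'
#' @param x A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_rigid <- function(x) {
  rigid_transform(t(x$R), as.numeric(-t(x$R) %*% x$t))
}

#' Optimal rotation between corresponding point sets (Kabsch)
#'
#' Finds the proper rotation R minimizing sum |R x_i - y_i|^2 with both
#' sets taken about the origin (no centroid subtraction: the reference
#' point of a neighborhood is the origin by construction).
#'
#' @param x,y n x 3 matrices of corresponding points.
#' @return 3x3 rotation matrix with determinant +1.
#' @export
kabsch_rotation <- function(x, y) {
  stopifnot(ncol(x) == 3, ncol(y) == 3, nrow(x) == nrow(y))
  H <- crossprod(x, y)              # sum x_i y_i^T
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

## Deterministic RNG scope: runs `expr` under `seed` and restores the
## caller's RNG state afterwards.
local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
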