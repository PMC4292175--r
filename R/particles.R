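## ParticleSet: positions in nm plus optional per-particle orientations
## (ZYZ Euler, degrees) and matching scores.

#' Construct a particle set
#'
#' @param positions n x 3 matrix of positions in nm.
#' @param scores Optional numeric vector of correlation scores in
#'   \[-1, 1\].
#' @param orientations Optional n x 3 matrix of intrinsic ZYZ Euler
#'   angles in degrees.
#' @param source_volume Optional identifier of the originating volume.
#' @return An object of class `particle_set`.
#' @export
particle_set <- function(positions, scores = NULL, orientations = NULL,
                         source_volume = NA_character_) {
  positions <- matrix(as.numeric(positions), ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z")))
  n <- nrow(positions)
  if (!is.null(scores)) {
    stopifnot(length(scores) == n)
    if (n > 0 && (min(scores) < -1 - 1e-6 || max(scores) > 1 + 1e-6))
      stop("scores must lie in [-1, 1]")
  }
  if (!is.null(orientations)) {
    orientations <- matrix(as.numeric(orientations), ncol = 3)
    stopifnot(nrow(orientations) == n)
  }
  structure(list(positions = positions, scores = scores,
                 orientations = orientations, source_volume = source_volume),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("particle_set: %d particles", nrow(x$positions)))
  if (!is.null(x$scores) && length(x$scores))
    cat(sprintf(", scores [%.3f, %.3f]", min(x$scores), max(x$scores)))
  cat("\n")
  invisible(x)
}

#' @export
length.particle_set <- function(x) nrow(x$positions)

#' Write particles to CSV
#'
#' Columns: `x_nm, y_nm, z_nm, rot_z1, rot_y, rot_z2` (intrinsic ZYZ,
#' degrees) and, when present, `score`. Missing orientations are written
#' as zeros.
#'
#' @param particles A `particle_set` or `synthetic_scene`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_particles <- function(particles, path) {
  if (inherits(particles, "synthetic_scene"))
    particles <- as_particle_set(particles)
  ori <- particles$orientations
  if (is.null(ori)) ori <- matrix(0, nrow(particles$positions), 3)
  df <- data.frame(x_nm = particles$positions[, 1],
                   y_nm = particles$positions[, 2],
                   z_nm = particles$positions[, 3],
                   rot_z1 = ori[, 1], rot_y = ori[, 2], rot_z2 = ori[, 3])
  if (!is.null(particles$scores)) df$score <- particles$scores
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read particles from CSV
#'
#' @param path CSV path written by [write_particles()] (or with at least
#'   `x_nm, y_nm, z_nm` columns).
#' @return A `particle_set`.
#' @export
read_particles <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("x_nm", "y_nm", "z_nm") %in% names(df)))
  ori <- if (all(c("rot_z1", "rot_y", "rot_z2") %in% names(df)))
    as.matrix(df[, c("rot_z1", "rot_y", "rot_z2")]) else NULL
  particle_set(as.matrix(df[, c("x_nm", "y_nm", "z_nm")]),
               scores = df$score, orientations = ori,
               source_volume = path)
}

#' Convert a synthetic scene to a particle set
#'
#' @param x A `synthetic_scene`.
#' @return A `particle_set` carrying the scene's ground-truth positions
#'   and orientations.
#' @export
as_particle_set <- function(x) {
  stopifnot(inherits(x, "synthetic_scene"))
  particle_set(x$positions, orientations = x$orientations,
               source_volume = "synthetic")
}
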