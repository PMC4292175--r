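## Synthetic-data generator: ground-truthed hard-sphere lattice scenes,
## rendered density volumes, layered membrane phantoms and invagination
## fixtures. These emulate the statistical structure of a pyrenoid
## matrix (densely packed ~13 nm quasi-spherical particles on a jittered
## close-packed lattice) and of thylakoid membrane stacks.

LATTICE_MODELS <- c("HCP", "CCP", "BCC", "RANDOM")

#' Specify a hard-sphere lattice hypothesis
#'
#' @param model One of `"HCP"`, `"CCP"`, `"BCC"`, `"RANDOM"`. HCP and
#'   CCP are the two close packings (coordination 12, A-B-A vs A-B-C
#'   stacking); BCC has coordination 8; RANDOM is a disordered
#'   hard-sphere control.
#' @param sphere_diameter Sphere diameter in nm (> 0) -- for the periodic
#'   models this equals the nearest-neighbor center distance of touching
#'   spheres; for RANDOM it is the minimum allowed center distance.
#' @param orientation 3x3 proper rotation of the lattice axes relative
#'   to the scene frame.
#' @return An object of class `lattice_spec`.
#' @export
lattice_spec <- function(model = c("HCP", "CCP", "BCC", "RANDOM"),
                         sphere_diameter, orientation = diag(3)) {
  model <- match.arg(toupper(model), LATTICE_MODELS)
  if (!is.numeric(sphere_diameter) || length(sphere_diameter) != 1 ||
      sphere_diameter <= 0)
    stop("sphere_diameter must be a single positive length (nm)")
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-9 ||
      abs(det(orientation) - 1) > 1e-9)
    stop("orientation must be orthonormal with determinant +1")
  structure(list(model = model, sphere_diameter = sphere_diameter,
                 orientation = orientation),
            class = "lattice_spec")
}

## Lattice primitive vectors (columns) and basis offsets (rows), scaled
## so the nearest-neighbor distance equals d. HCP uses the ideal axial
## ratio c/a = sqrt(8/3) of touching spheres.
lattice_basis <- function(model, d) {
  switch(model,
    HCP = {
      a <- d
      cc <- sqrt(8 / 3) * a
      A <- cbind(c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0), c(0, 0, cc))
      B <- rbind(c(0, 0, 0), c(a / 2, a / (2 * sqrt(3)), cc / 2))
      list(A = A, basis = B)
    },
    CCP = {
      ac <- d * sqrt(2)
      A <- diag(3) * ac
      B <- ac * rbind(c(0, 0, 0), c(.5, .5, 0), c(.5, 0, .5), c(0, .5, .5))
      list(A = A, basis = B)
    },
    BCC = {
      ac <- 2 * d / sqrt(3)
      A <- diag(3) * ac
      B <- ac * rbind(c(0, 0, 0), c(.5, .5, .5))
      list(A = A, basis = B)
    },
    stop("no periodic basis for model ", model))
}

#' Generate a ground-truthed synthetic particle scene
#'
#' Places all lattice points of the chosen model inside a box, centers
#' the lattice on the box, applies the spec's lattice orientation and
#' optional isotropic Gaussian positional jitter. For `model = "RANDOM"`
#' points are placed by hard-sphere rejection sampling (disordered
#' negative control).
#'
#' @param spec A [lattice_spec()].
#' @param extent Length-3 box dimensions in nm; points lie in
#'   `[0, extent]`.
#' @param jitter_sd SD of isotropic Gaussian jitter per particle, nm
#'   (>= 0). Jittered points leaving the box are dropped.
#' @param seed Integer seed; the same seed reproduces the scene exactly.
#' @param n_random Number of points to place for `RANDOM` (default
#'   `0.3 * sqrt(2) * V / d^3`, about 40 percent of close-packed
#'   density).
#' @param max_tries Rejection-sampling retry bound per RANDOM point.
#' @return An object of class `synthetic_scene` with fields `positions`
#'   (n x 3 nm), `orientations` (n x 3 ZYZ degrees), `spec`,
#'   `jitter_sd`, `extent`, `seed`.
#' @export
generate_lattice_points <- function(spec, extent, jitter_sd = 0, seed = 1,
                                    n_random = NULL, max_tries = 1e4) {
  stopifnot(inherits(spec, "lattice_spec"), length(extent) == 3,
            all(extent > 0), jitter_sd >= 0)
  extent <- as.numeric(extent)
  d <- spec$sphere_diameter
  local_seed(seed, {
    if (spec$model == "RANDOM") {
      if (is.null(n_random))
        n_random <- max(1, round(0.3 * sqrt(2) * prod(extent) / d^3))
      pos <- matrix(NA_real_, n_random, 3)
      for (i in seq_len(n_random)) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          p <- runif(3) * extent
          if (i == 1 || min(sqrt(colSums((t(pos[seq_len(i - 1), , drop = FALSE]) - p)^2))) >= d) {
            pos[i, ] <- p
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("RANDOM placement failed after ", max_tries,
               " tries for point ", i)
      }
      ori <- random_rotations(n_random)
    } else {
      lb <- lattice_basis(spec$model, d)
      A <- spec$orientation %*% lb$A
      basis <- t(spec$orientation %*% t(lb$basis))
      center <- extent / 2
      ## conservative integer ranges: box corners +/- basis reach, in
      ## lattice fractional coordinates
      corners <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1))) *
        rep(extent, each = 8)
      frac <- t(solve(A) %*% (t(corners) - center))
      pad <- 2
      rng <- apply(frac, 2, range)
      idx <- expand.grid(i = seq(floor(rng[1, 1]) - pad, ceiling(rng[2, 1]) + pad),
                         j = seq(floor(rng[1, 2]) - pad, ceiling(rng[2, 2]) + pad),
                         k = seq(floor(rng[1, 3]) - pad, ceiling(rng[2, 3]) + pad))
      cells <- as.matrix(idx) %*% t(A)
      pos <- do.call(rbind, lapply(seq_len(nrow(basis)), function(b)
        sweep(cells, 2, basis[b, ] + center, `+`)))
      keep <- pos[, 1] >= 0 & pos[, 1] <= extent[1] &
              pos[, 2] >= 0 & pos[, 2] <= extent[2] &
              pos[, 3] >= 0 & pos[, 3] <= extent[3]
      pos <- pos[keep, , drop = FALSE]
      if (nrow(pos) == 0)
        stop("extent too small to contain a lattice point")
      eul <- matrix_to_euler_zyz(spec$orientation)
      ori <- matrix(rep(eul, each = nrow(pos)), ncol = 3)
    }
    if (jitter_sd > 0) {
      pos <- pos + matrix(rnorm(length(pos), sd = jitter_sd), ncol = 3)
      keep <- pos[, 1] >= 0 & pos[, 1] <= extent[1] &
              pos[, 2] >= 0 & pos[, 2] <= extent[2] &
              pos[, 3] >= 0 & pos[, 3] <= extent[3]
      pos <- pos[keep, , drop = FALSE]
      ori <- ori[keep, , drop = FALSE]
    }
    colnames(pos) <- c("x", "y", "z")
    structure(list(positions = pos, orientations = ori, spec = spec,
                   jitter_sd = jitter_sd, extent = extent, seed = seed),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %d %s particles (d = %.2f nm, jitter %.2f nm) in %s nm box\n",
              nrow(x$positions), x$spec$model, x$spec$sphere_diameter,
              x$jitter_sd, paste(round(x$extent, 1), collapse = " x ")))
  invisible(x)
}

## Uniform random rotations as ZYZ Euler degree triples (n x 3):
## z1, z2 uniform on [0, 360), cos(y) uniform on [-1, 1].
random_rotations <- function(n) {
  cbind(runif(n, 0, 360), acos(runif(n, -1, 1)) * 180 / pi,
        runif(n, 0, 360))
}

#' Ideal first-shell unit cell of a lattice model
#'
#' Returns the reference point at the origin plus all points at the
#' minimal lattice distance, in the lattice frame: 13 points for HCP
#' (A-B-A layering: 3 below, 6 coplanar, 3 above, with the two outer
#' triangles eclipsed) and CCP (A-B-C: outer triangles staggered by
#' 60 degrees), 9 for BCC.
#'
#' @param spec A [lattice_spec()] (model must not be RANDOM), or a model
#'   name when `sphere_diameter` is given.
#' @param sphere_diameter Diameter in nm when `spec` is a model name.
#' @return n x 3 matrix of points in nm; row 1 is the origin.
#' @export
ideal_unit_cell <- function(spec, sphere_diameter = NULL) {
  if (!inherits(spec, "lattice_spec"))
    spec <- lattice_spec(spec, sphere_diameter)
  if (spec$model == "RANDOM")
    stop("RANDOM has no ideal unit cell")
  d <- spec$sphere_diameter
  hexagon <- t(sapply(seq(0, 300, by = 60) * pi / 180,
                      function(a) c(cos(a), sin(a), 0))) * d
  tri <- function(azimuths_deg, z_sign) {
    r <- d / sqrt(3)
    h <- z_sign * d * sqrt(2 / 3)
    t(sapply(azimuths_deg * pi / 180,
             function(a) c(r * cos(a), r * sin(a), h)))
  }
  pts <- switch(spec$model,
    HCP = rbind(c(0, 0, 0), hexagon,
                tri(c(30, 150, 270), +1), tri(c(30, 150, 270), -1)),
    CCP = rbind(c(0, 0, 0), hexagon,
                tri(c(30, 150, 270), +1), tri(c(90, 210, 330), -1)),
    BCC = rbind(c(0, 0, 0),
                as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) *
                  d / sqrt(3)))
  pts <- unname(pts)
  colnames(pts) <- c("x", "y", "z")
  pts
}

## Soft-sphere edge profiles, cosine edge of width `taper`.
##
## sphere_taper: half maximum exactly at `radius` (edge straddles the
## boundary), so the enclosed mass matches the hard sphere's to second
## order -- the convention for the matching template, whose nominal
## diameter marks its half-maximum surface.
sphere_taper <- function(dist, radius, taper) {
  v <- numeric(length(dist))
  lo <- radius - taper / 2
  hi <- radius + taper / 2
  v[dist <= lo] <- 1
  edge <- dist > lo & dist < hi
  v[edge] <- 0.5 * (1 + cos(pi * (dist[edge] - lo) / taper))
  v
}

## sphere_taper_inside: support strictly inside `radius` (edge rolls
## off to zero at the boundary) -- the convention for rendered hard
## spheres, whose densities must not overlap when touching at the
## stated diameter.
sphere_taper_inside <- function(dist, radius, taper) {
  v <- numeric(length(dist))
  v[dist <= radius - taper] <- 1
  edge <- dist > radius - taper & dist < radius
  v[edge] <- 0.5 * (1 + cos(pi * (dist[edge] - (radius - taper)) / taper))
  v
}

#' Render a synthetic scene into a density volume
#'
#' Each particle becomes a soft-edged sphere (cosine taper one voxel
#' wide) of the given diameter and amplitude on a zero background.
#' Optionally a missing-wedge Fourier mask is applied, then i.i.d.
#' Gaussian noise is added.
#'
#' @param scene A `synthetic_scene`.
#' @param voxel_size Voxel size in nm (> 0).
#' @param particle_diameter Rendered sphere diameter in nm (default 13,
#'   the long extent of a RuBisCO holoenzyme; must be >= 2 voxels).
#' @param amplitude Peak sphere intensity (AU).
#' @param noise_sd SD of additive Gaussian noise (AU); `noise_sd`
#'   equal to `amplitude` corresponds to SNR 1.
#' @param tilt Optional [tilt_geometry()]; when given, a binary
#'   missing-wedge mask for that tilt range is applied before noise.
#' @param seed Integer seed for the noise (ignored when `noise_sd = 0`).
#' @return A `density_volume` covering `scene$extent`.
#' @export
render_scene <- function(scene, voxel_size, particle_diameter = 13,
                         amplitude = 1, noise_sd = 0, tilt = NULL,
                         seed = 1) {
  stopifnot(inherits(scene, "synthetic_scene"), voxel_size > 0)
  if (particle_diameter < 2 * voxel_size)
    stop("particle_diameter must be at least 2 voxels")
  dims <- pmax(2L, as.integer(ceiling(scene$extent / voxel_size)))
  vol <- array(0, dims)
  r <- particle_diameter / 2
  n_clipped <- 0L
  for (p in seq_len(nrow(scene$positions))) {
    pos <- scene$positions[p, ]
    ctr <- pos / voxel_size + 0.5          # fractional 1-based index
    lo <- floor(ctr - r / voxel_size - 1)
    hi <- ceiling(ctr + r / voxel_size + 1)
    if (any(lo < 1) || any(hi > dims)) n_clipped <- n_clipped + 1L
    lo <- pmax(lo, 1); hi <- pmin(hi, dims)
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    cx <- (ix - 0.5) * voxel_size - pos[1]
    cy <- (iy - 0.5) * voxel_size - pos[2]
    cz <- (iz - 0.5) * voxel_size - pos[3]
    dist <- sqrt(outer(outer(cx^2, cy^2, `+`), cz^2, `+`))
    vol[ix, iy, iz] <- vol[ix, iy, iz] +
      amplitude * sphere_taper_inside(dist, r, voxel_size)
  }
  if (n_clipped > 0)
    message(n_clipped, " particle(s) clipped at the volume boundary")
  if (!is.null(tilt))
    vol <- apply_missing_wedge_array(vol, tilt)
  if (noise_sd > 0)
    vol <- vol + local_seed(seed,
      array(rnorm(length(vol), sd = noise_sd), dims))
  density_volume(vol, voxel_size)
}

#' Tilt-series geometry
#'
#' @param tilt_increment Tilt step in degrees (> 0).
#' @param tilt_range Half-range of the tilt series in degrees (e.g. 60
#'   for a +/-60 degree series).
#' @return An object of class `tilt_geometry`.
#' @export
tilt_geometry <- function(tilt_increment = 2, tilt_range = 60) {
  if (!(tilt_increment > 0 && tilt_increment <= tilt_range))
    stop("need 0 < tilt_increment <= tilt_range")
  structure(list(tilt_increment = tilt_increment, tilt_range = tilt_range),
            class = "tilt_geometry")
}

## Binary missing-wedge mask: tilting about y with the beam along z
## samples Fourier space where the (kx, kz) direction lies within
## tilt_range of the kx axis; the complementary wedge is zeroed.
apply_missing_wedge_array <- function(vol, tilt) {
  stopifnot(inherits(tilt, "tilt_geometry"))
  dims <- dim(vol)
  fr <- function(n) c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
  kx <- fr(dims[1]); kz <- fr(dims[3])
  ang <- atan2(abs(rep(kz, each = dims[1])), abs(rep(kx, times = dims[3])))
  keep2d <- matrix(ang <= tilt$tilt_range * pi / 180 + 1e-12,
                   dims[1], dims[3])
  mask <- aperm(array(rep(keep2d, times = dims[2]),
                      c(dims[1], dims[3], dims[2])), c(1, 3, 2))
  Re(fft(fft(vol) * mask, inverse = TRUE)) / length(vol)
}

#' Apply a missing wedge to a volume
#'
#' @param vol A `density_volume`.
#' @param tilt A [tilt_geometry()].
#' @return The wedge-filtered `density_volume`.
#' @export
apply_missing_wedge <- function(vol, tilt) {
  stopifnot(inherits(vol, "density_volume"))
  density_volume(apply_missing_wedge_array(vol$data, tilt),
                 vol$voxel_size, vol$origin)
}

#' Layered thylakoid-stack model
#'
#' One lateral repeat is membrane, lumen, membrane, interthylakoid
#' stromal gap, so the repeat distance is
#' `2 * membrane_width + lumen_width + stromal_gap`. Defaults are the
#' measured Chlamydomonas stack widths (4.9 / 9.0 / 3.6 nm, repeat
#' 22.4 nm). Intensities follow cryo-ET contrast: dense membranes dark,
#' lumen bright (least dense), stroma and gap intermediate.
#'
#' @param membrane_width,lumen_width,stromal_gap Layer widths in nm
#'   (> 0).
#' @param n_layers Number of stacked thylakoids (>= 2).
#' @param levels Named intensities (AU) for `membrane`, `lumen`,
#'   `stroma` (also used for the interthylakoid gap).
#' @return An object of class `layer_model`.
#' @export
layer_model <- function(membrane_width = 4.9, lumen_width = 9.0,
                        stromal_gap = 3.6, n_layers = 5,
                        levels = c(membrane = 0, lumen = 1, stroma = 0.5)) {
  stopifnot(membrane_width > 0, lumen_width > 0, stromal_gap > 0,
            n_layers >= 2,
            all(c("membrane", "lumen", "stroma") %in% names(levels)))
  if (levels["lumen"] <= levels["stroma"])
    stop("lumen must be brighter (less dense) than stroma/gap")
  structure(list(membrane_width = membrane_width,
                 lumen_width = lumen_width, stromal_gap = stromal_gap,
                 n_layers = as.integer(n_layers), levels = levels,
                 repeat_nm = 2 * membrane_width + lumen_width + stromal_gap),
            class = "layer_model")
}

## Piecewise-constant stack pattern along x: stroma margin, then
## n_layers thylakoids (membrane, lumen, membrane) separated by gaps.
## Returns breakpoints and per-segment levels.
stack_segments <- function(model, margin) {
  lv <- model$levels
  widths <- c(margin)
  levels <- c(lv[["stroma"]])
  for (l in seq_len(model$n_layers)) {
    widths <- c(widths, model$membrane_width, model$lumen_width,
                model$membrane_width)
    levels <- c(levels, lv[["membrane"]], lv[["lumen"]], lv[["membrane"]])
    if (l < model$n_layers) {
      widths <- c(widths, model$stromal_gap)
      levels <- c(levels, lv[["stroma"]])
    }
  }
  widths <- c(widths, margin)
  levels <- c(levels, lv[["stroma"]])
  list(breaks = cumsum(c(0, widths)), levels = levels)
}

## Area-sample the piecewise-constant pattern: value at x is the mean of
## the pattern over [x - h/2, x + h/2] (exact partial-volume rendering,
## so boundaries carry sub-sample information).
sample_segments <- function(seg, x, h) {
  cumF <- cumsum(c(0, diff(seg$breaks) * seg$levels))
  Fint <- function(q) {
    q <- pmin(pmax(q, seg$breaks[1]), seg$breaks[length(seg$breaks)])
    i <- findInterval(q, seg$breaks, rightmost.closed = TRUE)
    i <- pmin(i, length(seg$levels))
    cumF[i] + (q - seg$breaks[i]) * seg$levels[i]
  }
  (Fint(x + h / 2) - Fint(x - h / 2)) / h
}

#' Generate a synthetic membrane-stack volume
#'
#' Renders the layered pattern of a [layer_model()] along the x axis
#' (constant in y and z), with exact partial-volume sampling at layer
#' boundaries and optional additive Gaussian noise.
#'
#' @param model A [layer_model()].
#' @param voxel_size Voxel size in nm; every layer width must span at
#'   least 2 voxels.
#' @param noise_sd SD of additive Gaussian noise (AU).
#' @param margin Stroma margin added at both ends, nm.
#' @param yz_extent Lateral extent in nm of the y and z axes.
#' @param seed Integer seed for the noise.
#' @return A `density_volume`.
#' @export
generate_membrane_stack <- function(model, voxel_size, noise_sd = 0,
                                    margin = 2 * model$repeat_nm,
                                    yz_extent = 10, seed = 1) {
  stopifnot(inherits(model, "layer_model"), voxel_size > 0)
  if (min(model$membrane_width, model$lumen_width, model$stromal_gap) <
      2 * voxel_size)
    stop("layer widths must each span at least 2 voxels at this voxel size")
  seg <- stack_segments(model, margin)
  nx <- ceiling(seg$breaks[length(seg$breaks)] / voxel_size)
  nyz <- max(2L, ceiling(yz_extent / voxel_size))
  x <- (seq_len(nx) - 0.5) * voxel_size
  prof <- sample_segments(seg, x, voxel_size)
  vol <- array(rep(prof, times = nyz * nyz), c(nx, nyz, nyz))
  if (noise_sd > 0)
    vol <- vol + local_seed(seed,
      array(rnorm(length(vol), sd = noise_sd), dim(vol)))
  density_volume(vol, voxel_size)
}

#' Generate a 1D membrane-stack intensity profile
#'
#' The noiseless analytic line profile of a [layer_model()] at a given
#' sampling, as produced by a line scan normal to the layers.
#'
#' @param model A [layer_model()].
#' @param spacing Sample spacing in nm.
#' @param margin Stroma margin at both ends, nm.
#' @param noise_sd SD of additive Gaussian noise (AU).
#' @param seed Integer seed for the noise.
#' @return A `profile_scan` (see [average_line_profile()]).
#' @export
membrane_profile <- function(model, spacing = 0.25,
                             margin = 2 * model$repeat_nm, noise_sd = 0,
                             seed = 1) {
  stopifnot(inherits(model, "layer_model"), spacing > 0)
  seg <- stack_segments(model, margin)
  total <- seg$breaks[length(seg$breaks)]
  x <- seq(spacing / 2, total - spacing / 2, by = spacing)
  y <- sample_segments(seg, x, spacing)
  if (noise_sd > 0)
    y <- y + local_seed(seed, rnorm(length(y), sd = noise_sd))
  profile_scan(x, y, width = 1)
}

#' Generate a ground-truthed invagination fixture
#'
#' Samples inner-membrane invagination records: stromal projection size
#' `i`, envelope double-membrane width `m`, and 3D distance to the
#' nearest thylakoid tip. A record is counted when `i > m`.
#'
#' @param n Number of invaginations over the membrane patch.
#' @param size_distribution Function of `n` returning sampled sizes in
#'   nm (default log-normal around ~40 nm).
#' @param tip_distance_distribution Function of `n` returning tip
#'   distances in nm (default log-normal around ~70 nm).
#' @param envelope_width Envelope double-membrane width `m` in nm (> 0).
#' @param membrane_area Membrane patch area in square micrometers (> 0).
#' @param seed Integer seed.
#' @return A list of class `invagination_fixture`: `records` (data.frame
#'   with `size_i`, `envelope_m`, `tip_distance`, `counted`),
#'   `membrane_area`, and the ground-truth `density` = n / area.
#' @export
generate_invagination_fixture <- function(n,
    size_distribution = function(n) stats::rlnorm(n, log(40), 0.5),
    tip_distance_distribution = function(n) stats::rlnorm(n, log(70), 0.6),
    envelope_width = 15, membrane_area = 1, seed = 1) {
  stopifnot(n >= 0, envelope_width > 0, membrane_area > 0)
  local_seed(seed, {
    size_i <- size_distribution(n)
    tipd <- tip_distance_distribution(n)
    records <- data.frame(size_i = size_i, envelope_m = envelope_width,
                          tip_distance = tipd,
                          counted = size_i > envelope_width)
    structure(list(records = records, membrane_area = membrane_area,
                   density = n / membrane_area),
              class = "invagination_fixture")
  })
}
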