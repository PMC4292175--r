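## Particle localization by rotation-free spherical-template matching:
## Crowther-criterion low-pass, locally normalized FFT cross-correlation
## under a spherical mask, and exhaustive greedy peak extraction.

#' Build a spherical matching template
#'
#' A cubic volume containing a centered soft-edged sphere (cosine taper
#' one voxel wide, the same edge model used by [render_scene()]), values
#' in \[0, 1\]. The default diameter is 13.68 nm, a RuBisCO-sized probe.
#'
#' @param diameter Sphere diameter in nm (>= 2 voxels).
#' @param voxel_size Voxel size in nm.
#' @return A `density_volume` with odd cubic edge >= diameter + 2 voxels.
#' @export
make_spherical_template <- function(diameter = 13.68, voxel_size) {
  stopifnot(voxel_size > 0)
  if (diameter < 2 * voxel_size)
    stop("diameter must be at least 2 voxels at this voxel size")
  edge <- 2L * as.integer(ceiling(diameter / (2 * voxel_size))) + 3L
  ctr <- (edge + 1) / 2
  ax <- ((seq_len(edge)) - ctr) * voxel_size
  dist <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  density_volume(array(sphere_taper(dist, diameter / 2, voxel_size),
                       dim(dist)), voxel_size)
}

#' Crowther-criterion resolution cutoff
#'
#' The attainable resolution of a tilt series with N = 180 / increment
#' projections imaging a particle of diameter D is d = pi * D / N.
#' When `voxel_size` is supplied the result is clamped to be no finer
#' than the Nyquist spacing (2 voxels).
#'
#' @param particle_diameter Particle diameter D in nm (> 0).
#' @param tilt A [tilt_geometry()] (only the increment is used).
#' @param voxel_size Optional voxel size in nm for Nyquist clamping.
#' @return Resolution in nm.
#' @export
crowther_cutoff <- function(particle_diameter, tilt, voxel_size = NULL) {
  stopifnot(particle_diameter > 0, inherits(tilt, "tilt_geometry"))
  n_proj <- 180 / tilt$tilt_increment
  d_res <- pi * particle_diameter / n_proj
  if (!is.null(voxel_size)) d_res <- max(d_res, 2 * voxel_size)
  d_res
}

#' Low-pass filter a volume
#'
#' Fourier amplitudes beyond 1 / cutoff are removed through a
#' raised-cosine edge 3 Fourier voxels wide. The cutoff is clamped to
#' the Nyquist spacing; the mean (DC term) is always preserved.
#'
#' @param vol A `density_volume`.
#' @param cutoff_resolution Cutoff resolution in nm.
#' @return The filtered `density_volume`.
#' @export
lowpass <- function(vol, cutoff_resolution) {
  stopifnot(inherits(vol, "density_volume"), cutoff_resolution > 0)
  density_volume(lowpass_array(vol$data, vol$voxel_size,
                               cutoff_resolution),
                 vol$voxel_size, vol$origin)
}

lowpass_mask <- function(dims, voxel_size, cutoff_resolution) {
  cutoff <- max(cutoff_resolution, 2 * voxel_size)
  f <- freq_grid(dims, voxel_size)
  fc <- 1 / cutoff
  w <- 3 / (max(dims) * voxel_size)   # 3 Fourier voxels
  mask <- array(0, dims)
  mask[f <= fc] <- 1
  edge <- f > fc & f < fc + w
  mask[edge] <- 0.5 * (1 + cos(pi * (f[edge] - fc) / w))
  mask
}

lowpass_array <- function(arr, voxel_size, cutoff_resolution) {
  mask <- lowpass_mask(dim(arr), voxel_size, cutoff_resolution)
  Re(fft(fft(arr) * mask, inverse = TRUE)) / length(arr)
}

#' Locally normalized cross-correlation with a spherical template
#'
#' Computes, at every position, the correlation of the template with
#' the underlying volume patch under the template's spherical support
#' mask, normalized by the patch mean and standard deviation under that
#' mask (matched-filter contract for a dense, uneven background). No
#' rotational search is performed: the template is spherical. Positions
#' whose mask overlaps the volume boundary are assigned -1.
#'
#' @param volume A `density_volume`.
#' @param template A `density_volume` from [make_spherical_template()]
#'   (same voxel size, edge <= volume edge).
#' @param tilt Optional [tilt_geometry()]; when given, the template is
#'   missing-wedge filtered before matching so it matches
#'   wedge-distorted particles.
#' @return A `density_volume` correlation map with values in \[-1, 1\].
#' @export
match_template <- function(volume, template, tilt = NULL) {
  stopifnot(inherits(volume, "density_volume"),
            inherits(template, "density_volume"))
  if (abs(volume$voxel_size - template$voxel_size) > 1e-9)
    stop("volume and template voxel sizes differ")
  dims <- dim(volume$data)
  td <- dim(template$data)
  if (any(td > dims)) stop("template larger than volume")
  tdat <- template$data
  mask <- tdat > 1e-9            # spherical support of the soft sphere
  if (!is.null(tilt))
    tdat <- apply_missing_wedge_array(tdat, tilt)
  n <- sum(mask)
  tmu <- sum(tdat[mask]) / n
  a <- array(0, td)
  a[mask] <- tdat[mask] - tmu
  ss_t <- sum(a^2)
  v <- volume$data
  num <- fft_correlate(v, embed_kernel(a, dims))
  s1 <- fft_correlate(v, embed_kernel(mask * 1, dims))
  s2 <- fft_correlate(v * v, embed_kernel(mask * 1, dims))
  ss_v <- pmax(s2 - s1^2 / n, 0)
  floor_v <- 1e-9 * n * (mean(v^2) + 1e-300)
  ncc <- array(0, dims)
  ok <- ss_v > floor_v
  ncc[ok] <- num[ok] / sqrt(ss_t * ss_v[ok])
  ## mask radius in voxels: how far the support extends from the
  ## template center voxel
  which_m <- which(mask, arr.ind = TRUE)
  rad_vox <- ceiling(max(abs(sweep(which_m, 2, (td + 1) / 2))))
  bound <- array(FALSE, dims)
  idx <- lapply(dims, function(nn) {
    i <- seq_len(nn)
    i <= rad_vox | i > nn - rad_vox
  })
  bound[idx[[1]], , ] <- TRUE
  bound[, idx[[2]], ] <- TRUE
  bound[, , idx[[3]]] <- TRUE
  ncc[bound] <- -1
  density_volume(ncc, volume$voxel_size, volume$origin)
}

#' Exhaustively extract correlation peaks
#'
#' Greedy extraction: take the global maximum of the correlation map,
#' record it, zero out a sphere of `exclusion_radius` around it, and
#' repeat until `max_peaks` is reached or the next maximum falls below
#' `min_score`. The default exclusion radius equals the hard-sphere
#' template radius (6.84 nm): touching particles cannot be closer.
#'
#' @param corr A correlation-map `density_volume` from
#'   [match_template()].
#' @param exclusion_radius Exclusion radius in nm (> 0).
#' @param max_peaks Safety bound on the number of peaks.
#' @param min_score Stop when the next peak falls below this score.
#' @param subvoxel Refine each peak position by separable parabolic
#'   interpolation of the correlation values at the neighboring voxels
#'   (default TRUE).
#' @return A `particle_set` sorted by descending score; positions in
#'   nm.
#' @export
extract_peaks <- function(corr, exclusion_radius = 6.84, max_peaks = Inf,
                          min_score = 0.2, subvoxel = TRUE) {
  stopifnot(inherits(corr, "density_volume"), exclusion_radius > 0)
  dims <- dim(corr$data)
  vs <- corr$voxel_size
  m <- corr$data
  rv <- exclusion_radius / vs
  ri <- ceiling(rv)
  off <- as.matrix(expand.grid(-ri:ri, -ri:ri, -ri:ri))
  off <- off[rowSums(off^2) <= rv^2, , drop = FALSE]
  pos <- list(); sco <- numeric(0)
  while (length(sco) < max_peaks) {
    i <- which.max(m)
    s <- m[i]
    if (!is.finite(s) || s < min_score) break
    ijk <- arrayInd(i, dims)
    frac <- as.numeric(ijk)
    if (subvoxel) {
      for (ax in 1:3) {
        if (ijk[ax] > 1 && ijk[ax] < dims[ax]) {
          at <- function(di) {
            q <- as.numeric(ijk); q[ax] <- q[ax] + di
            corr$data[q[1] + dims[1] * (q[2] - 1) +
                        dims[1] * dims[2] * (q[3] - 1)]
          }
          cm1 <- at(-1); cp1 <- at(1)
          den <- cm1 - 2 * s + cp1
          if (is.finite(cm1) && is.finite(cp1) && den < -1e-12) {
            delta <- 0.5 * (cm1 - cp1) / den
            frac[ax] <- frac[ax] + max(-0.5, min(0.5, delta))
          }
        }
      }
    }
    pos[[length(pos) + 1]] <- (frac - 0.5) * vs + corr$origin
    sco <- c(sco, s)
    zone <- sweep(off, 2, as.numeric(ijk), `+`)
    keep <- zone[, 1] >= 1 & zone[, 1] <= dims[1] &
            zone[, 2] >= 1 & zone[, 2] <= dims[2] &
            zone[, 3] >= 1 & zone[, 3] <= dims[3]
    zone <- zone[keep, , drop = FALSE]
    m[zone[, 1] + dims[1] * (zone[, 2] - 1) +
        dims[1] * dims[2] * (zone[, 3] - 1)] <- -Inf
  }
  if (length(sco) == 0)
    return(particle_set(matrix(numeric(0), 0, 3), scores = numeric(0)))
  particle_set(do.call(rbind, pos), scores = pmin(pmax(sco, -1), 1))
}
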