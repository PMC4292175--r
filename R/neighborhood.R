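## Nearest-neighbor point-cloud analysis: range queries around each
## particle, pooling of alignment-rotated neighborhoods into one 3D
## cloud, and k-means extraction of the 13 cluster centers (reference
## particle + 12 nearest neighbors of a close packing).

#' Range query around every particle
#'
#' For each particle i, the offsets `p_j - p_i` of all other particles
#' within `radius` (closed ball). The reference's own zero offset is
#' not included here; see `include_self` in [pooled_cloud()].
#'
#' @param particles A `particle_set` (or n x 3 position matrix).
#' @param radius Query radius in nm (default 22.8, about 1.5 sphere
#'   diameters at 15 nm spacing: first shell plus the sqrt(2) d second
#'   shell).
#' @return A list of m_i x 3 offset matrices, one per particle
#'   (possibly 0-row).
#' @export
range_query <- function(particles, radius = 22.8) {
  stopifnot(radius > 0)
  pos <- if (inherits(particles, "particle_set")) particles$positions
         else matrix(as.numeric(particles), ncol = 3)
  n <- nrow(pos)
  d2 <- as.matrix(stats::dist(pos))^2
  r2 <- radius^2 + 1e-12
  lapply(seq_len(n), function(i) {
    j <- which(d2[i, ] <= r2 & seq_len(n) != i)
    sweep(pos[j, , drop = FALSE], 2, pos[i, ])
  })
}

#' Pool rotated neighborhoods into a reference-frame cloud
#'
#' Each particle's neighborhood offsets are rotated by that particle's
#' alignment rotation (the rotation mapping its subvolume into the
#' average's frame) and pooled into a single 3D point cloud.
#' Translations are not applied: offsets are already centered on the
#' reference particle. With `include_self = TRUE` (default) a zero
#' offset is added per reference so the k = 13 clustering covers the
#' reference particle and its 12 nearest neighbors.
#'
#' @param neighborhoods List of offset matrices from [range_query()].
#' @param transforms List of [rigid_transform()]s (or 3x3 rotation
#'   matrices), one per reference particle; `NULL` means identity for
#'   all.
#' @param include_self Add the reference's own zero offset per particle.
#' @return An object of class `neighbor_cloud`: `offsets` (m x 3 nm),
#'   `source` (reference particle index per offset), `query_radius`
#'   (attribute of the inputs, NA if unknown).
#' @export
pooled_cloud <- function(neighborhoods, transforms = NULL,
                         include_self = TRUE) {
  n <- length(neighborhoods)
  if (!is.null(transforms) && length(transforms) != n)
    stop("need one transform per reference particle")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    off <- neighborhoods[[i]]
    if (!is.null(transforms)) {
      R <- transforms[[i]]
      if (inherits(R, "rigid_transform")) R <- R$R
      off <- off %*% t(R)
    }
    if (include_self) off <- rbind(off, c(0, 0, 0))
    out[[i]] <- off
  }
  offsets <- do.call(rbind, out)
  colnames(offsets) <- c("x", "y", "z")
  structure(list(offsets = offsets,
                 source = rep(seq_len(n), vapply(out, nrow, 1L))),
            class = "neighbor_cloud")
}

#' @export
print.neighbor_cloud <- function(x, ...) {
  cat(sprintf("neighbor_cloud: %d offsets from %d reference particles\n",
              nrow(x$offsets), length(unique(x$source))))
  invisible(x)
}

#' Keep only each reference's k nearest neighbors
#'
#' Optional pre-filter that trims every neighborhood to its `k` closest
#' offsets, removing second-shell contamination before clustering
#' (clean-recovery mode; the default analysis keeps the full 22.8 nm
#' query).
#'
#' @param neighborhoods List of offset matrices from [range_query()].
#' @param k Neighbors to keep per reference (default 12).
#' @return Filtered list of offset matrices.
#' @export
nearest_k_filter <- function(neighborhoods, k = 12) {
  lapply(neighborhoods, function(off) {
    if (nrow(off) <= k) return(off)
    d <- sqrt(rowSums(off^2))
    off[order(d)[seq_len(k)], , drop = FALSE]
  })
}

#' Cluster centers of a neighbor cloud
#'
#' Best-of-restarts k-means (squared-Euclidean, Lloyd iterations) with
#' greedy D^2-weighted (k-means++) seeding from a fixed RNG;
#' deterministic given `seed`. Restarts that produce an empty cluster
#' are retried; it is an error only if every restart fails.
#'
#' @param cloud A `neighbor_cloud` (or m x 3 matrix), m >= k.
#' @param k Number of clusters (default 13: the reference + 12 nearest
#'   neighbors of a close packing).
#' @param n_restarts Number of seeded restarts (default 10).
#' @param seed Integer seed.
#' @return An object of class `cluster_model`: `k`, `centers` (k x 3,
#'   sorted by distance from the origin), `assignment`, `withinss`
#'   (total within-cluster sum of squares, nm^2).
#' @export
cluster_centers <- function(cloud, k = 13, n_restarts = 10, seed = 1) {
  pts <- if (inherits(cloud, "neighbor_cloud")) cloud$offsets
         else matrix(as.numeric(cloud), ncol = 3)
  m <- nrow(pts)
  if (m < k) stop("cloud has fewer points than k")
  best <- NULL
  local_seed(seed, {
    for (r in seq_len(n_restarts)) {
      centers <- farthest_point_seeds(pts, k)
      fit <- tryCatch(
        suppressWarnings(kmeans(pts, centers = centers, iter.max = 100,
                                algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(fit) || any(fit$size == 0)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss)
        best <- fit
    }
  })
  if (is.null(best))
    stop("k-means failed in all restarts (empty clusters)")
  ord <- order(sqrt(rowSums(best$centers^2)))
  centers <- best$centers[ord, , drop = FALSE]
  colnames(centers) <- c("x", "y", "z")
  rownames(centers) <- NULL
  relabel <- match(seq_len(k), ord)
  structure(list(k = k, centers = centers,
                 assignment = relabel[best$cluster],
                 withinss = best$tot.withinss),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: k = %d, total within-SS = %.3f nm^2\n",
              x$k, x$withinss))
  invisible(x)
}

## Greedy D^2-weighted seeding (k-means++): random first center, then
## each next center drawn with probability proportional to its squared
## distance to the nearest chosen center. Spreads seeds over the shell
## without latching onto isolated outliers the way pure farthest-point
## seeding does.
farthest_point_seeds <- function(pts, k) {
  m <- nrow(pts)
  idx <- integer(k)
  idx[1] <- sample.int(m, 1)
  mind <- rowSums(sweep(pts, 2, pts[idx[1], ])^2)
  for (j in seq_len(k - 1)) {
    if (all(mind <= 0)) {
      idx[j + 1] <- sample.int(m, 1)
    } else {
      idx[j + 1] <- sample.int(m, 1, prob = mind)
    }
    mind <- pmin(mind, rowSums(sweep(pts, 2, pts[idx[j + 1], ])^2))
  }
  pts[idx, , drop = FALSE]
}

#' Gaussian-smoothed density rendering of a cloud
#'
#' Renders each cloud point as a discrete Gaussian kernel normalized to
#' unit mass, so the volume integral (sum times voxel volume) equals
#' the number of points.
#'
#' @param cloud A `neighbor_cloud`.
#' @param voxel_size Voxel size in nm.
#' @param sigma Gaussian SD in nm.
#' @param extent Half-extent of the rendered cube in nm (default: max
#'   offset + 3 sigma).
#' @return A `density_volume` centered on the origin.
#' @export
cloud_density <- function(cloud, voxel_size = 0.5, sigma = 1,
                          extent = NULL) {
  stopifnot(inherits(cloud, "neighbor_cloud"))
  pts <- cloud$offsets
  if (is.null(extent))
    extent <- max(sqrt(rowSums(pts^2))) + 3 * sigma
  n <- 2L * as.integer(ceiling(extent / voxel_size)) + 1L
  ctr <- (n + 1) / 2
  vol <- array(0, c(n, n, n))
  rk <- as.integer(ceiling(3 * sigma / voxel_size))
  for (p in seq_len(nrow(pts))) {
    ci <- pts[p, ] / voxel_size + ctr
    lo <- pmax(floor(ci) - rk, 1)
    hi <- pmin(floor(ci) + rk + 1, n)
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    gx <- exp(-((ix - ci[1]) * voxel_size)^2 / (2 * sigma^2))
    gy <- exp(-((iy - ci[2]) * voxel_size)^2 / (2 * sigma^2))
    gz <- exp(-((iz - ci[3]) * voxel_size)^2 / (2 * sigma^2))
    kern <- outer(outer(gx, gy), gz)
    kern <- kern / (sum(kern) * voxel_size^3)
    vol[ix, iy, iz] <- vol[ix, iy, iz] + kern
  }
  density_volume(vol, voxel_size,
                 origin = rep(-(ctr - 0.5) * voxel_size, 3))
}
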