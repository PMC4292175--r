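## Subtomogram averaging: fixed-size subvolume extraction around
## detected particles, exhaustive-grid rigid alignment, symmetry-free
## iterative averaging, and Fourier shell correlation.

#' Extract subvolumes around particles
#'
#' Cubic boxes (default 45.6 nm edge) centered on particle positions
#' rounded to the nearest voxel, cut from the unfiltered volume.
#' Particles whose box would leave the volume are dropped with a
#' message.
#'
#' @param volume A `density_volume` (the unfiltered tomogram).
#' @param particles A `particle_set`.
#' @param box_edge Box edge in nm (default 45.6).
#' @return An object of class `subvolume_stack`: `boxes` (list of 3D
#'   arrays), `voxel_size`, `box_edge`, `ids` (indices of retained
#'   particles), `positions` (their nm positions).
#' @export
extract_subvolumes <- function(volume, particles, box_edge = 45.6) {
  stopifnot(inherits(volume, "density_volume"),
            inherits(particles, "particle_set"))
  vs <- volume$voxel_size
  dims <- dim(volume$data)
  b <- as.integer(round(box_edge / vs))
  if (b < 2) stop("box_edge below 2 voxels")
  half <- floor(b / 2)
  ctr <- round(sweep(particles$positions, 2, volume$origin) / vs + 0.5)
  start <- sweep(ctr, 2, half)
  ok <- start[, 1] >= 1 & start[, 2] >= 1 & start[, 3] >= 1 &
        start[, 1] + b - 1 <= dims[1] &
        start[, 2] + b - 1 <= dims[2] &
        start[, 3] + b - 1 <= dims[3]
  n_drop <- sum(!ok)
  if (n_drop > 0)
    message(n_drop, " particle(s) too close to the volume boundary dropped")
  if (!any(ok)) stop("no particles retained: all boxes leave the volume")
  ids <- which(ok)
  boxes <- lapply(ids, function(i) {
    s <- start[i, ]
    volume$data[s[1]:(s[1] + b - 1), s[2]:(s[2] + b - 1),
                s[3]:(s[3] + b - 1)]
  })
  structure(list(boxes = boxes, voxel_size = vs, box_edge = b * vs,
                 ids = ids,
                 positions = particles$positions[ids, , drop = FALSE]),
            class = "subvolume_stack")
}

#' @export
print.subvolume_stack <- function(x, ...) {
  cat(sprintf("subvolume_stack: %d boxes of %d^3 voxels (%.1f nm edge)\n",
              length(x$boxes), dim(x$boxes[[1]])[1], x$box_edge))
  invisible(x)
}

#' @export
length.subvolume_stack <- function(x) length(x$boxes)

#' Apply a rigid transform to a volume
#'
#' Trilinear resampling: the volume is rotated about the box center by
#' the transform's rotation, then shifted by its translation, so a
#' feature at center offset p moves to `R p + t`.
#'
#' @param vol A `density_volume` or 3D array.
#' @param transform A [rigid_transform()] (translation in nm for a
#'   `density_volume`, in voxels for a bare array).
#' @return Same type as `vol`.
#' @export
apply_rigid <- function(vol, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(vol, "density_volume")) {
    out <- .rotate_vol(vol$data, dim(vol$data), transform$R,
                       transform$t / vol$voxel_size)
    return(density_volume(out, vol$voxel_size, vol$origin))
  }
  .rotate_vol(vol, dim(vol), transform$R, transform$t)
}

## Soft spherical alignment mask for an n^3 box: raised-cosine edge,
## radius just inside the box.
soft_box_mask <- function(n) {
  ctr <- (n + 1) / 2
  ax <- seq_len(n) - ctr
  dist <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  sphere_taper(dist, n / 2 - 0.5, 3)
}

## Weighted (masked) normalized correlation of two arrays.
ncc_masked <- function(a, b, w) {
  sw <- sum(w)
  da <- a - sum(w * a) / sw
  db <- b - sum(w * b) / sw
  den <- sqrt(sum(w * da^2) * sum(w * db^2))
  if (den < 1e-300) return(0)
  sum(w * da * db) / den
}

## ZYZ Euler grid at a given angular step, in lexicographic (z1, y, z2)
## order; y spans [0, 180], z1/z2 span [0, 360).
euler_grid <- function(step) {
  stopifnot(step > 0)
  z1 <- seq(0, 360 - step, by = step)
  y <- seq(0, 180, by = step)
  z2 <- seq(0, 360 - step, by = step)
  g <- expand.grid(z2 = z2, y = y, z1 = z1)   # z1 slowest
  cbind(g$z1, g$y, g$z2)
}

## Wrapped FFT index offsets (0-based shifts) within a voxel radius.
shift_window <- function(n, max_shift_vox) {
  s <- floor(max_shift_vox)
  s <- min(s, floor((n - 1) / 2))
  shifts <- -s:s
  list(shifts = shifts, idx = shifts %% n + 1)
}

#' Align one volume to a reference
#'
#' Exhaustive search over a ZYZ Euler grid; for each rotation the
#' optimal integer-voxel translation is found by Fourier
#' cross-correlation restricted to `|shift| <= max_shift`. Returns the
#' transform that maps `moving` into the reference frame (apply it with
#' [apply_rigid()]). Ties on the grid resolve to the first-encountered
#' maximum in lexicographic (z1, y, z2) order.
#'
#' @param moving,reference `density_volume`s of equal shape.
#' @param angular_step Euler grid step in degrees (> 0).
#' @param max_shift Maximum translation magnitude per axis in nm.
#' @return A list: `transform` ([rigid_transform()], translation in
#'   nm), `score` (constrained correlation under a soft spherical
#'   mask).
#' @export
align_pair <- function(moving, reference, angular_step = 30,
                       max_shift = 5) {
  stopifnot(inherits(moving, "density_volume"),
            inherits(reference, "density_volume"),
            all(dim(moving$data) == dim(reference$data)))
  if (angular_step <= 0) stop("angular_step must be positive")
  vs <- moving$voxel_size
  dims <- dim(moving$data)
  ref_f <- fft(reference$data)
  grid <- euler_grid(angular_step)
  sw <- lapply(dims, shift_window, max_shift_vox = max_shift / vs)
  best <- list(c = -Inf)
  for (g in seq_len(nrow(grid))) {
    R <- euler_zyz(grid[g, 1], grid[g, 2], grid[g, 3])
    rot <- .rotate_vol(moving$data, dims, R, c(0, 0, 0))
    cmap <- Re(fft(ref_f * Conj(fft(rot)), inverse = TRUE)) / length(rot)
    sub <- cmap[sw[[1]]$idx, sw[[2]]$idx, sw[[3]]$idx, drop = FALSE]
    i <- which.max(sub)
    if (sub[i] > best$c) {
      ijk <- arrayInd(i, dim(sub))
      best <- list(c = sub[i], R = R,
                   shift = c(sw[[1]]$shifts[ijk[1]],
                             sw[[2]]$shifts[ijk[2]],
                             sw[[3]]$shifts[ijk[3]]))
    }
  }
  tr <- rigid_transform(best$R, best$shift * vs)
  aligned <- apply_rigid(moving, tr)
  w <- soft_box_mask(dims[1])
  list(transform = tr, score = ncc_masked(aligned$data, reference$data, w))
}

#' Iteratively align and average a subvolume stack
#'
#' Symmetry-free subtomogram averaging. Iteration 0 uses the unaligned
#' mean as reference; each subsequent iteration aligns every box to the
#' current reference and re-averages with the transforms applied. No
#' point-group symmetry is imposed at any step.
#'
#' Rotations are scored in batch by masked zero-shift correlation
#' against rotated copies of the reference (template matching has
#' already centered the boxes), then the translation is refined by
#' Fourier cross-correlation at each box's best rotation. A drop in
#' mean alignment score between iterations is reported as a warning,
#' not an error.
#'
#' @param stack A `subvolume_stack`.
#' @param angular_schedule Euler grid step per iteration, degrees
#'   (default coarse-to-fine 30, 30, 15, 7.5).
#' @param max_shift Maximum translation per axis in nm.
#' @param align_lowpass Optional resolution cutoff in nm: when set,
#'   rotation and translation scoring use low-pass-filtered copies of
#'   the boxes and reference (noise suppression during alignment); the
#'   averages themselves are always built from the raw boxes.
#' @param initial_reference `"mean"` (iteration 0 reference is the
#'   unaligned mean) or `"box"` (a single member box, index drawn from
#'   `seed`) -- the latter breaks the orientational symmetry of the
#'   naive mean and speeds convergence on strongly symmetric scenes.
#' @param seed Integer seed (used only for the `"box"` reference
#'   draw); the rest of the procedure is deterministic.
#' @return A list: `average` (`density_volume`), `transforms` (list of
#'   [rigid_transform()], one per box, mapping each box into the
#'   average's frame), `scores` (final per-box masked correlations),
#'   `score_history` (mean score per iteration).
#' @export
iterative_average <- function(stack, angular_schedule = c(30, 30, 15, 7.5),
                              max_shift = 5, align_lowpass = NULL,
                              initial_reference = c("mean", "box"),
                              seed = 1) {
  initial_reference <- match.arg(initial_reference)
  stopifnot(inherits(stack, "subvolume_stack"), length(stack$boxes) > 0)
  vs <- stack$voxel_size
  dims <- dim(stack$boxes[[1]])
  nvox <- prod(dims)
  nbox <- length(stack$boxes)
  w <- soft_box_mask(dims[1])
  wv <- as.numeric(w)
  sww <- sum(wv)
  B <- matrix(unlist(stack$boxes), nvox, nbox)
  ## masked demeaned unit columns: crossprod then ranks rotations by
  ## weighted correlation
  prep <- function(M) {
    mu <- colSums(M * wv) / sww
    Mc <- sweep(M, 2, mu) * sqrt(wv)
    nrm <- sqrt(colSums(Mc^2))
    sweep(Mc, 2, pmax(nrm, 1e-300), `/`)
  }
  lpmask <- if (!is.null(align_lowpass))
    lowpass_mask(dims, vs, align_lowpass) else NULL
  lp <- function(arr) {
    if (is.null(lpmask)) return(arr)
    array(Re(fft(fft(arr) * lpmask, inverse = TRUE)) / nvox, dims)
  }
  Bs <- if (is.null(lpmask)) B else
    vapply(seq_len(nbox), function(i) as.numeric(lp(array(B[, i], dims))),
           numeric(nvox))
  Bn <- prep(Bs)
  reference <- if (initial_reference == "box")
    array(B[, local_seed(seed, sample.int(nbox, 1))], dims)
  else array(rowMeans(B), dims)
  transforms <- rep(list(rigid_transform()), nbox)
  score_history <- numeric(0)
  sw <- lapply(dims, shift_window, max_shift_vox = max_shift / vs)
  for (it in seq_along(angular_schedule)) {
    grid <- euler_grid(angular_schedule[it])
    nrot <- nrow(grid)
    best_score <- rep(-Inf, nbox)
    best_rot <- integer(nbox)
    ref_s <- lp(reference)
    chunk <- 150L
    for (lo in seq(1L, nrot, by = chunk)) {
      hi <- min(lo + chunk - 1L, nrot)
      Rs <- lapply(lo:hi, function(g)
        euler_zyz(grid[g, 1], grid[g, 2], grid[g, 3]))
      refQ <- vapply(Rs, function(R)
        as.numeric(.rotate_vol(ref_s, dims, R, c(0, 0, 0))),
        numeric(nvox))
      S <- crossprod(Bn, prep(refQ))          # nbox x chunk
      for (jj in seq_len(ncol(S))) {
        upd <- S[, jj] > best_score
        best_score[upd] <- S[upd, jj]
        best_rot[upd] <- lo + jj - 1L
      }
    }
    aligned <- matrix(0, nvox, nbox)
    scores <- numeric(nbox)
    ref_f <- fft(ref_s)
    for (i in seq_len(nbox)) {
      Q <- euler_zyz(grid[best_rot[i], 1], grid[best_rot[i], 2],
                     grid[best_rot[i], 3])
      R <- t(Q)     # box aligned by R matches reference rotated by Q
      rot <- .rotate_vol(array(Bs[, i], dims), dims, R, c(0, 0, 0))
      cmap <- Re(fft(ref_f * Conj(fft(rot)), inverse = TRUE)) / nvox
      subm <- cmap[sw[[1]]$idx, sw[[2]]$idx, sw[[3]]$idx, drop = FALSE]
      k <- which.max(subm)
      ijk <- arrayInd(k, dim(subm))
      shift <- c(sw[[1]]$shifts[ijk[1]], sw[[2]]$shifts[ijk[2]],
                 sw[[3]]$shifts[ijk[3]])
      transforms[[i]] <- rigid_transform(R, shift * vs)
      aligned[, i] <- .rotate_vol(array(B[, i], dims), dims, R, shift)
      scores[i] <- ncc_masked(.rotate_vol(array(Bs[, i], dims), dims, R,
                                          shift),
                              ref_s, w)
    }
    score_history <- c(score_history, mean(scores))
    if (it > 1 &&
        score_history[it] < score_history[it - 1] - 1e-6)
      warning(sprintf("mean alignment score dropped at iteration %d (%.4f -> %.4f)",
                      it, score_history[it - 1], score_history[it]))
    reference <- array(rowMeans(aligned), dims)
  }
  list(average = density_volume(reference, vs),
       transforms = transforms, scores = scores,
       score_history = score_history)
}

#' Fourier shell correlation of two maps
#'
#' Correlation of Fourier coefficients over concentric shells one
#' Fourier voxel wide. Shells with no signal in either map are reported
#' as 1 (identical nothing), which keeps the self-FSC identity exact.
#'
#' @param map_a,map_b `density_volume`s of equal cubic shape and voxel
#'   size.
#' @return An object of class `fsc_curve`: data.frame with `freq`
#'   (1/nm, strictly increasing) and `fsc`; attribute `voxel_size`.
#' @export
fourier_shell_correlation <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "density_volume"),
            inherits(map_b, "density_volume"))
  if (!all(dim(map_a$data) == dim(map_b$data)))
    stop("map shapes differ")
  if (abs(map_a$voxel_size - map_b$voxel_size) > 1e-9)
    stop("voxel sizes differ")
  dims <- dim(map_a$data)
  n <- dims[1]
  vs <- map_a$voxel_size
  fa <- fft(map_a$data)
  fb <- fft(map_b$data)
  shell <- round(freq_grid(dims, vs) * n * vs)   # radius in Fourier voxels
  nshell <- floor(min(dims) / 2)
  keep <- shell <= nshell
  s <- factor(shell[keep], levels = 0:nshell)
  num <- tapply(Re(fa[keep] * Conj(fb[keep])), s, sum)
  pa <- tapply(abs(fa[keep])^2, s, sum)
  pb <- tapply(abs(fb[keep])^2, s, sum)
  den <- sqrt(pa * pb)
  fsc <- ifelse(den < 1e-300, 1, num / pmax(den, 1e-300))
  curve <- data.frame(freq = (0:nshell) / (n * vs), fsc = as.numeric(fsc))
  structure(curve, class = c("fsc_curve", "data.frame"), voxel_size = vs)
}

#' Resolution at an FSC threshold
#'
#' Locates the first crossing of the curve below the threshold by
#' linear interpolation between shells and returns 1 / frequency. A
#' shell exactly at the threshold counts as the crossing. If the curve
#' never crosses, the Nyquist spacing is returned with attribute
#' `crossed = FALSE`.
#'
#' @param curve An `fsc_curve`.
#' @param threshold FSC threshold (default 0.5).
#' @return Resolution in nm with attribute `crossed`.
#' @export
resolution_at <- function(curve, threshold = 0.5) {
  stopifnot(inherits(curve, "fsc_curve"), nrow(curve) > 0)
  vs <- attr(curve, "voxel_size")
  f <- curve$freq
  y <- curve$fsc
  for (i in seq_along(y)) {
    if (y[i] == threshold && f[i] > 0)
      return(structure(1 / f[i], crossed = TRUE))
    if (y[i] < threshold) {
      if (i == 1 || f[i - 1] == 0 && y[i - 1] < threshold)
        return(structure(Inf, crossed = TRUE))
      fc <- f[i - 1] + (threshold - y[i - 1]) / (y[i] - y[i - 1]) *
        (f[i] - f[i - 1])
      if (fc <= 0) return(structure(Inf, crossed = TRUE))
      return(structure(1 / fc, crossed = TRUE))
    }
  }
  structure(2 * vs, crossed = FALSE)
}
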