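## Measurement procedures: averaged line-scan densitometry of membrane
## stacks, autocorrelation-based layer measurement, invagination
## counting statistics, and center-spacing gap arithmetic.

#' Construct a profile scan
#'
#' @param position Strictly increasing, uniformly spaced sample
#'   positions along the scan line (nm).
#' @param intensity Mean intensity per position (AU).
#' @param width Averaging width in pixels.
#' @return An object of class `profile_scan`.
#' @export
profile_scan <- function(position, intensity, width = 1) {
  stopifnot(length(position) == length(intensity), length(position) >= 3)
  dp <- diff(position)
  if (any(dp <= 0) || diff(range(dp)) > 1e-6 * mean(dp))
    stop("positions must be strictly increasing with uniform spacing")
  structure(list(position = as.numeric(position),
                 intensity = as.numeric(intensity),
                 width = width, spacing = mean(dp)),
            class = "profile_scan")
}

#' @export
print.profile_scan <- function(x, ...) {
  cat(sprintf("profile_scan: %d samples over %.1f nm (spacing %.3f nm, width %d px)\n",
              length(x$position), diff(range(x$position)), x$spacing,
              x$width))
  invisible(x)
}

## Trilinear interpolation of a volume at physical nm positions
## (m x 3); positions outside the grid return NA.
interp_volume <- function(vol, pts) {
  dims <- dim(vol$data)
  idx <- pos_to_index(vol, pts)          # fractional 1-based
  out <- rep(NA_real_, nrow(pts))
  ok <- idx[, 1] >= 1 & idx[, 1] <= dims[1] &
        idx[, 2] >= 1 & idx[, 2] <= dims[2] &
        idx[, 3] >= 1 & idx[, 3] <= dims[3]
  if (!any(ok)) return(out)
  p <- idx[ok, , drop = FALSE]
  f0 <- pmin(floor(p), rep(dims, each = nrow(p)) - 1)
  fr <- p - f0
  acc <- numeric(nrow(p))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (ifelse(dx == 1, fr[, 1], 1 - fr[, 1])) *
         (ifelse(dy == 1, fr[, 2], 1 - fr[, 2])) *
         (ifelse(dz == 1, fr[, 3], 1 - fr[, 3]))
    acc <- acc + w * vol$data[cbind(f0[, 1] + dx, f0[, 2] + dy,
                                    f0[, 3] + dz)]
  }
  out[ok] <- acc
  out
}

#' Averaged line-scan intensity profile
#'
#' Samples the volume along the line from `start` to `end` at
#' voxel-size spacing and averages, at each sample, over `width`
#' parallel lines: offsets span the perpendicular in-plane direction
#' for a single-slice volume, or a perpendicular disc of diameter
#' `width` pixels for a 3D volume (trilinear sampling throughout).
#'
#' @param volume A `density_volume`.
#' @param start,end Line endpoints in nm (inside the volume).
#' @param width Averaging width in pixels (>= 1; default 80).
#' @return A `profile_scan`.
#' @export
average_line_profile <- function(volume, start, end, width = 80) {
  stopifnot(inherits(volume, "density_volume"), length(start) == 3,
            length(end) == 3, width >= 1)
  vs <- volume$voxel_size
  L <- sqrt(sum((end - start)^2))
  if (L <= 0) stop("degenerate line")
  u <- (end - start) / L
  ## perpendicular basis
  a <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v <- c(u[2] * a[3] - u[3] * a[2], u[3] * a[1] - u[1] * a[3],
         u[1] * a[2] - u[2] * a[1])
  v <- v / sqrt(sum(v^2))
  wvec <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
  flat <- dim(volume$data)[3] == 1
  hw <- (width - 1) / 2
  if (flat || width == 1) {
    offs <- if (width == 1) matrix(0, 1, 3)
            else outer(seq(-hw, hw) * vs, v)
  } else {
    g <- expand.grid(p = seq(-hw, hw), q = seq(-hw, hw))
    g <- g[g$p^2 + g$q^2 <= hw^2 + 1e-9, ]
    offs <- outer(g$p * vs, v) + outer(g$q * vs, wvec)
  }
  t_nm <- seq(0, L, by = vs)
  prof <- vapply(t_nm, function(t0) {
    base <- start + t0 * u
    pts <- sweep(offs, 2, base, `+`)
    vals <- interp_volume(volume, pts)
    if (anyNA(vals)) return(NA_real_)
    mean(vals)
  }, 0)
  if (anyNA(prof)) stop("line (or its averaging width) exits the volume")
  profile_scan(t_nm, prof, width = as.integer(width))
}

## Unbiased-location autocorrelation repeat estimate with parabolic
## sub-sample refinement. Searches for the global max of the (biased)
## autocorrelation after it first drops below zero, which skips the
## main lobe and any partial-alignment side peaks.
profile_repeat <- function(y, spacing, min_corr = 0.2) {
  y <- y - mean(y)
  n <- length(y)
  nfft <- 2^ceiling(log2(2 * n))
  Y <- fft(c(y, rep(0, nfft - n)))
  ac <- Re(fft(Y * Conj(Y), inverse = TRUE))[seq_len(n)] / nfft
  ac <- ac / ac[1]
  neg <- which(ac < 0)
  if (length(neg) == 0) return(NULL)
  lo <- neg[1]
  hi <- floor(2 * n / 3)
  if (hi <= lo + 1) return(NULL)
  seg <- ac[lo:hi]
  k <- lo + which.max(seg) - 1
  if (ac[k] < min_corr) return(NULL)
  ## parabolic refinement on (k-1, k, k+1), 1-based lags
  if (k > 1 && k < n) {
    denom <- ac[k - 1] - 2 * ac[k] + ac[k + 1]
    delta <- if (abs(denom) > 1e-15)
      0.5 * (ac[k - 1] - ac[k + 1]) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
  } else delta <- 0
  ((k - 1) + delta) * spacing
}

#' Measure membrane-stack layer widths from a line profile
#'
#' The lateral repeat comes from the first autocorrelation peak of the
#' profile beyond its main lobe (parabolic sub-sample refinement).
#' Layer widths come from half-maximum crossings between each membrane
#' extremum and its adjacent plateau levels, averaged over repeats:
#' membrane width is the span between a trough's two half-depth
#' crossings; the intervals between consecutive membranes are classed
#' as lumen (brighter) or interthylakoid gap (darker) and measured
#' between facing crossings. Intervals touching the profile ends
#' (stroma margins) are excluded.
#'
#' @param profile A `profile_scan` covering at least two repeats.
#' @param polarity `"dark"` if membranes are intensity minima (cryo-ET
#'   convention, default) or `"bright"`.
#' @return An object of class `layer_measurement`: `lateral_repeat`,
#'   `membrane_width`, `lumen_width`, `stromal_gap` (nm) and
#'   `n_layers` (membranes measured).
#' @export
measure_layers <- function(profile, polarity = c("dark", "bright")) {
  stopifnot(inherits(profile, "profile_scan"))
  polarity <- match.arg(polarity)
  x <- profile$position
  y <- profile$intensity
  if (polarity == "bright") y <- -y
  rep_nm <- profile_repeat(y, profile$spacing)
  if (is.null(rep_nm))
    stop("no periodic signal: autocorrelation peak below 0.2")
  ## membrane troughs: minima below the mid level, separated by > P/2
  mid <- (min(y) + max(y)) / 2
  n <- length(y)
  is_min <- c(FALSE, y[2:(n - 1)] <= y[1:(n - 2)] &
                     y[2:(n - 1)] <= y[3:n], FALSE) & y < mid
  cand <- which(is_min)
  ## separation guard: wider than a flat trough bottom, narrower than
  ## the closest membrane-center spacing (membrane + gap)
  min_sep <- rep_nm / (4 * profile$spacing)
  troughs <- integer(0)
  for (i in cand[order(y[cand])]) {
    if (all(abs(i - troughs) > min_sep)) troughs <- c(troughs, i)
  }
  troughs <- sort(troughs)
  if (length(troughs) < 2)
    stop("fewer than two membrane troughs found")
  ## plateau level between adjacent troughs (and toward the ends)
  bounds <- c(1, troughs, n)
  plateau <- vapply(seq_len(length(troughs) + 1), function(j) {
    seg <- y[bounds[j]:bounds[j + 1]]
    max(seg)
  }, 0)
  cross <- function(i0, level, dir) {
    ## walk from trough index i0 in direction dir to the first sample
    ## above `level`, then linearly interpolate the crossing position
    i <- i0
    while (i + dir >= 1 && i + dir <= n && y[i + dir] < level) i <- i + dir
    if (i + dir < 1 || i + dir > n) return(NA_real_)
    x[i] + (level - y[i]) / (y[i + dir] - y[i]) * (x[i + dir] - x[i])
  }
  memb <- matrix(NA_real_, length(troughs), 2)
  for (j in seq_along(troughs)) {
    tr <- troughs[j]
    half_l <- (y[tr] + plateau[j]) / 2
    half_r <- (y[tr] + plateau[j + 1]) / 2
    memb[j, 1] <- cross(tr, half_l, -1L)
    memb[j, 2] <- cross(tr, half_r, +1L)
  }
  ok <- stats::complete.cases(memb)
  memb <- memb[ok, , drop = FALSE]
  troughs <- troughs[ok]
  if (nrow(memb) < 2) stop("could not delimit two membranes")
  mwidths <- memb[, 2] - memb[, 1]
  ## intervals between consecutive membranes: lumen vs gap by mean
  ## intensity (lumen is the brighter class)
  k <- nrow(memb) - 1
  iw <- numeric(k); imean <- numeric(k)
  for (j in seq_len(k)) {
    iw[j] <- memb[j + 1, 1] - memb[j, 2]
    sel <- x > memb[j, 2] & x < memb[j + 1, 1]
    imean[j] <- mean(y[sel])
  }
  thr <- (max(imean) + min(imean)) / 2
  lumen <- imean >= thr
  if (!any(lumen) || all(lumen))
    stop("could not distinguish lumen from interthylakoid gap")
  structure(list(lateral_repeat = rep_nm,
                 membrane_width = mean(mwidths),
                 lumen_width = mean(iw[lumen]),
                 stromal_gap = mean(iw[!lumen]),
                 n_layers = nrow(memb)),
            class = "layer_measurement")
}

#' @export
print.layer_measurement <- function(x, ...) {
  cat(sprintf("layer_measurement: repeat %.2f nm = 2 x %.2f (membrane) + %.2f (lumen) + %.2f (gap); %d membranes\n",
              x$lateral_repeat, x$membrane_width, x$lumen_width,
              x$stromal_gap, x$n_layers))
  invisible(x)
}

#' Invagination summary statistics
#'
#' Applies the counting rule (an invagination is counted when its
#' stromal projection `i` exceeds the envelope double-membrane width
#' `m`), then reports the areal density of counted invaginations and
#' the cumulative fractions of counted invaginations found within
#' given distances of a thylakoid tip.
#'
#' @param records Data frame with columns `size_i`, `envelope_m`,
#'   `tip_distance` (nm), or an `invagination_fixture`.
#' @param membrane_area Membrane area in square micrometers (> 0).
#' @param tip_breaks Distances (nm) at which cumulative tip-distance
#'   fractions are reported (default 40 and 100).
#' @return A list: `n_counted`, `density` (per um^2), `median_size`
#'   (nm), `tip_fraction` (named cumulative fractions), `sizes`
#'   (counted sizes, nm).
#' @export
invagination_stats <- function(records, membrane_area = NULL,
                               tip_breaks = c(40, 100)) {
  if (inherits(records, "invagination_fixture")) {
    if (is.null(membrane_area)) membrane_area <- records$membrane_area
    records <- records$records
  }
  stopifnot(is.data.frame(records),
            all(c("size_i", "envelope_m", "tip_distance") %in%
                names(records)),
            !is.null(membrane_area), membrane_area > 0)
  counted <- records$size_i > records$envelope_m
  cr <- records[counted, , drop = FALSE]
  nc <- nrow(cr)
  tip_fraction <- vapply(tip_breaks, function(b)
    if (nc == 0) NA_real_ else mean(cr$tip_distance < b), 0)
  names(tip_fraction) <- paste0("<", tip_breaks, "nm")
  list(n_counted = nc, density = nc / membrane_area,
       median_size = if (nc) stats::median(cr$size_i) else NA_real_,
       tip_fraction = tip_fraction, sizes = cr$size_i)
}

#' Surface-to-surface gap from center spacing
#'
#' The free space between two particles whose centers are a given
#' distance apart: `center_distance - particle_extent`. With 15 nm
#' center spacing this gives ~4.5 nm between face-to-face complexes
#' (10.5 nm short extent) and ~2 nm corner-to-corner (13 nm long
#' extent). Negative values signal overlap.
#'
#' @param center_distance Center-to-center distance in nm (> 0).
#' @param particle_extent Particle extent along the center line in nm
#'   (> 0).
#' @return Gap in nm.
#' @export
surface_gap <- function(center_distance, particle_extent) {
  stopifnot(all(center_distance > 0), all(particle_extent > 0))
  center_distance - particle_extent
}
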