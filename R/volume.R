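## DensityVolume: a 3D scalar grid with isotropic physical voxel size.
## Physical convention: right-handed axes, nm units, origin at the corner
## of the first voxel, so voxel (i, j, k) (1-based array index) has its
## center at origin + (c(i, j, k) - 0.5) * voxel_size.

#' Construct a density volume
#'
#' @param data 3D numeric array of intensities (arbitrary units). A 2D
#'   matrix is promoted to a single-slice volume.
#' @param voxel_size Isotropic voxel size in nm (> 0).
#' @param origin Physical offset of the first voxel corner in nm.
#' @return An object of class `density_volume`.
#' @export
density_volume <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!all(is.finite(data))) stop("volume values must all be finite")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    stop("voxel_size must be a single positive number (nm)")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("density_volume: %d x %d x %d voxels @ %.3f nm (%.1f x %.1f x %.1f nm)\n",
              d[1], d[2], d[3], x$voxel_size,
              d[1] * x$voxel_size, d[2] * x$voxel_size, d[3] * x$voxel_size))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

#' @export
dim.density_volume <- function(x) dim(x$data)

## physical position (nm) of voxel centers along one axis
axis_coords <- function(vol, axis) {
  (seq_len(dim(vol$data)[axis]) - 0.5) * vol$voxel_size + vol$origin[axis]
}

## nm position -> fractional 1-based voxel index
pos_to_index <- function(vol, pos) {
  sweep(pos, 2, vol$origin) / vol$voxel_size + 0.5
}

## 1-based voxel index -> nm position of the voxel center
index_to_pos <- function(vol, idx) {
  sweep((idx - 0.5) * vol$voxel_size, 2, vol$origin, `+`)
}

#' Read an MRC volume
#'
#' Minimal MRC2014 reader for mode 2 (float32) and mode 1 (int16)
#' volumes. The voxel size is taken from the cell dimensions divided by
#' the sampling (Angstrom in the header, converted to nm).
#'
#' @param path Path to an MRC file.
#' @return A `density_volume`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_num <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  mx <- hdr_int[8]
  xlen <- hdr_num[11]
  if (nx <= 0 || ny <= 0 || nz <= 0) stop("corrupt MRC header")
  voxel_ang <- if (mx > 0 && xlen > 0) xlen / mx else 1
  seek(con, 1024 + hdr_int[24])   # skip extended header (NSYMBT)
  n <- nx * ny * nz
  data <- switch(as.character(mode),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2, endian = "little")),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    stop("unsupported MRC mode: ", mode))
  density_volume(array(data, c(nx, ny, nz)), voxel_size = voxel_ang / 10)
}

#' Write an MRC volume
#'
#' Writes mode 2 (float32), little endian, with the voxel size recorded
#' in the cell/sampling header fields (Angstrom).
#'
#' @param vol A `density_volume`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mrc <- function(vol, path) {
  stopifnot(inherits(vol, "density_volume"))
  d <- dim(vol$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                         # nx ny nz
  wi(2)                         # mode 2 = float32
  wi(c(0, 0, 0))                # nxstart
  wi(d)                         # mx my mz
  wf(d * vol$voxel_size * 10)   # cella (Angstrom)
  wf(c(90, 90, 90))             # cellb
  wi(c(1, 2, 3))                # mapc mapr maps
  wf(c(min(vol$data), max(vol$data), mean(vol$data)))  # dmin dmax dmean
  wi(c(0, 0))                   # ispg nsymbt
  wi(rep(0, 25))                # extra
  wf(vol$origin * 10)           # origin (Angstrom)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.numeric(vol$data)))               # rms
  wi(0)                          # nlabl
  writeBin(raw(800), con)        # labels
  wf(as.numeric(vol$data))
  invisible(path)
}

## --- Fourier helpers (shared by matching, filtering, alignment) -------

## Spatial-frequency magnitude grid (cycles/nm) for an FFT of this volume,
## in R's unshifted fft layout.
freq_grid <- function(dims, voxel_size) {
  fr <- function(n) {
    k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
    k / (n * voxel_size)
  }
  fx <- fr(dims[1]); fy <- fr(dims[2]); fz <- fr(dims[3])
  sqrt(outer(outer(fx^2, fy^2, `+`), fz^2, `+`))
}

## Embed a small kernel (odd or even cube) centered on the FFT origin of
## a larger grid, with wraparound, so fft-based correlation peaks index
## directly.
embed_kernel <- function(kernel, dims) {
  kd <- dim(kernel)
  stopifnot(all(kd <= dims))
  out <- array(0, dims)
  ## kernel center voxel (1-based): floor(kd/2) + 1
  cc <- floor(kd / 2) + 1
  for (i in seq_len(kd[1])) for (j in seq_len(kd[2])) {
    ii <- (i - cc[1]) %% dims[1] + 1
    jj <- (j - cc[2]) %% dims[2] + 1
    kk <- (seq_len(kd[3]) - cc[3]) %% dims[3] + 1
    out[ii, jj, kk] <- kernel[i, j, ]
  }
  out
}

## Circular cross-correlation C(x) = sum_i k(i) v(x + i), i taken about
## the kernel center. Returns a real array of dim(v).
fft_correlate <- function(v, kernel_embedded) {
  n <- length(v)
  Re(fft(fft(v) * Conj(fft(kernel_embedded)), inverse = TRUE)) / n
}
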