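test_that("spherical templates are centered, bounded and volumetrically correct", {
  tm <- make_spherical_template(13.68, 1.14)
  n <- dim(tm$data)[1]
  expect_true(n %% 2 == 1)
  expect_gte(n * 1.14, 13.68 + 2 * 1.14)
  ctr <- (n + 1) / 2
  expect_identical(tm$data[ctr, ctr, ctr], 1)
  expect_identical(tm$data[1, 1, 1], 0)
  expect_true(all(tm$data >= 0 & tm$data <= 1))
  ## integral close to the analytic sphere volume for a large sphere
  tm2 <- make_spherical_template(12, 1)   # 12-voxel diameter
  expect_equal(sum(tm2$data), pi / 6 * 12^3, tolerance = 0.05)
  expect_error(make_spherical_template(1, 1), "2 voxels")
})

test_that("the Crowther cutoff follows pi D / N with Nyquist clamping", {
  tilt2 <- tilt_geometry(2, 60)
  expect_equal(crowther_cutoff(12, tilt2), pi * 12 / 90, tolerance = 1e-12)
  ## coarse increment: N = 2
  expect_equal(crowther_cutoff(12, tilt_geometry(90, 90)), pi * 12 / 2,
               tolerance = 1e-12)
  ## linear in D
  expect_equal(crowther_cutoff(24, tilt2), 2 * crowther_cutoff(12, tilt2),
               tolerance = 1e-12)
  ## clamped no finer than 2 voxels
  expect_identical(crowther_cutoff(12, tilt2, voxel_size = 1.14), 2 * 1.14)
})

test_that("low-pass filtering preserves the mean and strictly reduces noise variance", {
  set.seed(31)
  v <- density_volume(array(rnorm(24^3), c(24, 24, 24)), 1)
  f <- lowpass(v, 5)
  expect_equal(mean(f$data), mean(v$data), tolerance = 1e-6)
  expect_lt(var(as.numeric(f$data)), var(as.numeric(v$data)))
  ## constant volume is exactly invariant
  cst <- density_volume(array(2.5, c(16, 16, 16)), 1)
  expect_equal(lowpass(cst, 4)$data, cst$data, tolerance = 1e-9)
})

test_that("template matching matches a direct sliding-window correlation oracle", {
  set.seed(11)
  vs <- 1
  vdat <- array(rnorm(20^3, sd = 0.2), c(20, 20, 20))
  vdat[8:12, 9:13, 7:11] <- vdat[8:12, 9:13, 7:11] + 2
  vol <- density_volume(vdat, vs)
  tm <- make_spherical_template(5, vs)
  cm <- match_template(vol, tm)
  ## direct-space oracle: Pearson correlation of template and patch
  ## under the spherical support mask, at every interior position
  td <- dim(tm$data)
  mask <- tm$data > 1e-9
  tvals <- tm$data[mask]
  r <- (td[1] - 1) / 2
  offs <- which(mask, arr.ind = TRUE) - (r + 1)
  dims <- dim(vdat)
  rad <- max(abs(offs))
  worst <- 0
  for (i in seq(rad + 1, dims[1] - rad, by = 3))
    for (j in seq(rad + 1, dims[2] - rad, by = 3))
      for (k in seq(rad + 1, dims[3] - rad, by = 3)) {
        patch <- vdat[cbind(offs[, 1] + i, offs[, 2] + j, offs[, 3] + k)]
        worst <- max(worst, abs(cm$data[i, j, k] - cor(tvals, patch)))
      }
  expect_lt(worst, 1e-6)
  ## bounds and degenerate-variance rule
  expect_true(all(cm$data >= -1 - 1e-6 & cm$data <= 1 + 1e-6))
  cst <- density_volume(array(1, c(16, 16, 16)), vs)
  cc <- match_template(cst, tm)
  interior <- cc$data[8, 8, 8]
  expect_identical(interior, 0)
})

test_that("a planted template is found at its position with near-perfect score", {
  vs <- 1
  tm <- make_spherical_template(6, vs)
  vdat <- array(0, c(24, 24, 24))
  td <- dim(tm$data)[1]
  at <- c(12, 10, 14)
  lo <- at - (td - 1) / 2
  vdat[lo[1]:(lo[1] + td - 1), lo[2]:(lo[2] + td - 1),
       lo[3]:(lo[3] + td - 1)] <- tm$data
  set.seed(4)
  vdat <- vdat + array(rnorm(length(vdat), sd = 1e-4), dim(vdat))
  cm <- match_template(density_volume(vdat, vs), tm)
  expect_equal(as.numeric(arrayInd(which.max(cm$data), dim(cm$data))), at)
  expect_gt(max(cm$data), 0.99)
})

test_that("greedy peak extraction recovers a noiseless planted lattice exactly", {
  vs <- 1.9
  sc <- make_interior_scene("HCP", 15.05, c(80, 80, 80), seed = 6,
                            margin = 12)
  expect_gte(nrow(sc$positions), 50)
  vol <- render_scene(sc, vs, particle_diameter = 13)
  tm <- make_spherical_template(13.68, vs)
  cm <- match_template(vol, tm)
  pk <- extract_peaks(cm, exclusion_radius = 6.84, min_score = 0.5)
  expect_identical(length(pk), nrow(sc$positions))
  derr <- apply(sc$positions, 1, function(p)
    min(sqrt(rowSums(sweep(pk$positions, 2, p)^2))))
  expect_true(all(derr <= vs))
  ## threshold above the maximum possible score yields nothing
  expect_identical(length(extract_peaks(cm, 6.84, min_score = 1.01)), 0L)
  ## two sub-exclusion peaks collapse to one
  one <- sc
  one$positions <- rbind(c(40, 40, 40), c(43, 40, 40))
  one$orientations <- matrix(0, 2, 3)
  v2 <- render_scene(one, vs, particle_diameter = 13)
  p2 <- extract_peaks(match_template(v2, tm), exclusion_radius = 6.84,
                      min_score = 0.5)
  expect_identical(length(p2), 1L)
  ## pairwise exclusion invariant
  dmat <- as.matrix(dist(pk$positions)); diag(dmat) <- Inf
  expect_gte(min(dmat), 6.84 - vs)  # subvoxel refinement can move < 1 voxel
})

test_that("matching stays sensitive at SNR 1 with a band-limited search", {
  vs <- 1.9
  sc <- make_interior_scene("HCP", 15.05, c(100, 100, 70), seed = 6,
                            margin = 12)
  vol <- render_scene(sc, vs, particle_diameter = 13, amplitude = 1,
                      noise_sd = 1, seed = 21)
  tm <- make_spherical_template(13.68, vs)
  cm <- match_template(lowpass(vol, 6.8), lowpass(tm, 6.8))
  pk <- extract_peaks(cm, 6.84, min_score = 0.3)
  derr <- apply(sc$positions, 1, function(p)
    min(sqrt(rowSums(sweep(pk$positions, 2, p)^2))))
  expect_gte(mean(derr <= vs), 0.9)
})
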