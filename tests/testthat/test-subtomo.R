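test_that("subvolume extraction centers boxes and drops boundary particles", {
  vs <- 1.14
  vdat <- array(rnorm(51^3), c(51, 51, 51))
  vol <- density_volume(vdat, vs)
  ctr_nm <- (26 - 0.5) * vs
  ps <- particle_set(rbind(rep(ctr_nm, 3),      # dead center
                           c(0.6, ctr_nm, ctr_nm)))  # 1 voxel from a face
  expect_message(st <- extract_subvolumes(vol, ps, box_edge = 45.6),
                 "dropped")
  expect_identical(length(st), 1L)
  b <- dim(st$boxes[[1]])[1]
  expect_identical(b, 40L)                       # 45.6 nm at 1.14 nm voxels
  ## the box's center voxel is the volume's center voxel
  expect_identical(st$boxes[[1]][b %/% 2 + 1, b %/% 2 + 1, b %/% 2 + 1],
                   vdat[26, 26, 26])
  ps_out <- particle_set(matrix(c(2, 2, 2), 1))
  expect_error(suppressMessages(extract_subvolumes(vol, ps_out, 45.6)),
               "no particles")
})

test_that("pairwise alignment recovers shifts exactly and rotations to a grid step", {
  ref <- make_asym_object(16, 1)
  ## self-alignment
  a0 <- align_pair(ref, ref, angular_step = 45, max_shift = 4)
  expect_equal(a0$transform$R, diag(3), tolerance = 1e-9)
  expect_equal(a0$transform$t, c(0, 0, 0), tolerance = 1e-9)
  expect_gt(a0$score, 0.999)
  ## pure +3 voxel shift in x: recovered translation is -3
  mov <- ref
  mov$data <- array(0, dim(ref$data))
  mov$data[4:16, , ] <- ref$data[1:13, , ]
  a1 <- align_pair(mov, ref, angular_step = 90, max_shift = 6)
  expect_equal(a1$transform$t, c(-3, 0, 0), tolerance = 1e-9)
  ## 90-degree rotation about z at a 15-degree grid
  movr <- apply_rigid(ref, rigid_transform(euler_zyz(90, 0, 0)))
  a2 <- align_pair(movr, ref, angular_step = 15, max_shift = 3)
  resid <- a2$transform$R %*% euler_zyz(90, 0, 0)
  ang <- acos(min(1, (sum(diag(resid)) - 1) / 2)) * 180 / pi
  expect_lte(ang, 15 + 1e-6)
  expect_gt(a2$score, 0.9)
  expect_error(align_pair(ref, ref, angular_step = 0), "positive")
})

test_that("iterative averaging is exact on degenerate stacks and honors its own transforms", {
  ref <- make_asym_object(12, 1)
  boxes <- list(ref$data, ref$data, ref$data, ref$data)
  st <- structure(list(boxes = boxes, voxel_size = 1, box_edge = 12,
                       ids = 1:4, positions = matrix(0, 4, 3)),
                  class = "subvolume_stack")
  out <- iterative_average(st, angular_schedule = c(45), max_shift = 2)
  expect_equal(out$average$data, ref$data, tolerance = 1e-6)
  ## variance about the member is zero
  expect_lt(max(abs(out$average$data - ref$data)), 1e-12 + 1e-9 * max(ref$data))
  ## single-box stack: identity transform, average = the box
  st1 <- structure(list(boxes = boxes[1], voxel_size = 1, box_edge = 12,
                        ids = 1L, positions = matrix(0, 1, 3)),
                   class = "subvolume_stack")
  o1 <- iterative_average(st1, angular_schedule = c(45), max_shift = 2)
  expect_equal(o1$average$data, ref$data, tolerance = 1e-9)
  expect_equal(o1$transforms[[1]]$R, diag(3), tolerance = 1e-9)
  ## transform contract: applying the returned transforms to the raw
  ## boxes and averaging reproduces the returned average
  rebuilt <- Reduce(`+`, lapply(seq_along(out$transforms), function(i)
    apply_rigid(boxes[[i]], rigid_transform(out$transforms[[i]]$R,
                                            out$transforms[[i]]$t)))) / 4
  expect_equal(rebuilt, out$average$data, tolerance = 1e-6)
})

test_that("known on-grid rotations are recovered by iterative averaging", {
  ref <- make_asym_object(12, 1)
  angs <- rbind(c(0, 0, 0), c(90, 0, 0), c(0, 90, 0), c(180, 90, 0),
                c(270, 0, 0), c(90, 90, 0))
  boxes <- lapply(seq_len(nrow(angs)), function(i)
    apply_rigid(ref, rigid_transform(euler_zyz(angs[i, 1], angs[i, 2],
                                               angs[i, 3])))$data)
  st <- structure(list(boxes = boxes, voxel_size = 1, box_edge = 12,
                       ids = seq_len(nrow(angs)),
                       positions = matrix(0, nrow(angs), 3)),
                  class = "subvolume_stack")
  out <- iterative_average(st, angular_schedule = c(90, 90, 90),
                           max_shift = 2, initial_reference = "box",
                           seed = 2)
  ## every recovered rotation must undo its ground truth up to the
  ## common global rotation of the average: residuals R_i %*% G_i must
  ## all be the same rotation
  resid <- lapply(seq_len(nrow(angs)), function(i)
    out$transforms[[i]]$R %*% euler_zyz(angs[i, 1], angs[i, 2], angs[i, 3]))
  for (i in 2:length(resid)) {
    rel <- resid[[1]] %*% t(resid[[i]])
    ang <- acos(min(1, max(-1, (sum(diag(rel)) - 1) / 2))) * 180 / pi
    expect_lt(ang, 1e-6)
  }
  ## alignment score history is non-decreasing (1e-6 slack)
  expect_true(all(diff(out$score_history) >= -1e-6))
})

test_that("FSC is 1 on self, symmetric, and near zero for independent noise", {
  set.seed(17)
  a <- density_volume(array(rnorm(20^3), c(20, 20, 20)), 1)
  b <- density_volume(array(rnorm(20^3), c(20, 20, 20)), 1)
  self <- fourier_shell_correlation(a, a)
  expect_true(all(abs(self$fsc - 1) < 1e-9))
  expect_true(all(diff(self$freq) > 0))
  ab <- fourier_shell_correlation(a, b)
  ba <- fourier_shell_correlation(b, a)
  expect_identical(ab$fsc, ba$fsc)
  ## null: shell correlations are O(1/sqrt(n_shell)); skip DC
  expect_lt(mean(abs(ab$fsc[-1])), 0.25)
  expect_error(fourier_shell_correlation(a,
    density_volume(array(0, c(10, 10, 10)), 1)), "shape")
})

test_that("FSC-threshold resolution interpolates crossings and flags non-crossing curves", {
  curve <- structure(data.frame(freq = c(0, 0.05, 0.1, 0.15, 0.2),
                                fsc = c(1, 1, 0.6, 0.4, 0.2)),
                     class = c("fsc_curve", "data.frame"), voxel_size = 2.5)
  res <- resolution_at(curve, 0.5)
  ## crossing halfway between 0.1 and 0.15 cycles/nm
  expect_equal(as.numeric(res), 1 / 0.125, tolerance = 1e-9)
  expect_true(attr(res, "crossed"))
  ## exact-threshold shell wins directly
  curve2 <- structure(data.frame(freq = c(0, 0.05, 0.1),
                                 fsc = c(1, 0.5, 0.2)),
                      class = c("fsc_curve", "data.frame"), voxel_size = 2.5)
  expect_equal(as.numeric(resolution_at(curve2, 0.5)), 20, tolerance = 1e-9)
  ## self-FSC never crosses: Nyquist spacing, flagged
  a <- density_volume(array(rnorm(16^3), c(16, 16, 16)), 1.14)
  res2 <- resolution_at(fourier_shell_correlation(a, a), 0.5)
  expect_equal(as.numeric(res2), 2 * 1.14, tolerance = 1e-9)
  expect_false(attr(res2, "crossed"))
})

test_that("half-set averages of a noisy scene agree at low frequency and cross 0.5", {
  vs <- 1.9
  sc <- make_interior_scene("HCP", 15.05, c(90, 90, 70), seed = 8,
                            margin = 12)
  vol <- render_scene(sc, vs, particle_diameter = 13, noise_sd = 1,
                      seed = 33)
  ps <- as_particle_set(sc)
  st <- extract_subvolumes(vol, ps, box_edge = 22.8)
  even <- seq(1, length(st$boxes), by = 2)
  odd <- seq(2, length(st$boxes), by = 2)
  avg_of <- function(idx) {
    s <- st; s$boxes <- st$boxes[idx]; s$ids <- st$ids[idx]
    s$positions <- st$positions[idx, , drop = FALSE]
    iterative_average(s, angular_schedule = c(360), max_shift = 0)$average
  }
  fsc <- fourier_shell_correlation(avg_of(even), avg_of(odd))
  expect_gt(fsc$fsc[2], 0.9)
  res <- resolution_at(fsc, 0.5)
  expect_true(attr(res, "crossed"))
  expect_gt(as.numeric(res), 2 * vs)
})
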