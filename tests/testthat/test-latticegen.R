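test_that("jitter-free lattices touch at the sphere diameter with the right coordination", {
  cases <- list(list(model = "HCP", d = 15.05, coord = 12),
                list(model = "CCP", d = 15.05, coord = 12),
                list(model = "BCC", d = 13.0,  coord = 8))
  for (cs in cases) {
    sc <- generate_lattice_points(lattice_spec(cs$model, cs$d),
                                  c(90, 90, 90), jitter_sd = 0, seed = 1)
    dmat <- as.matrix(dist(sc$positions))
    diag(dmat) <- Inf
    expect_equal(min(dmat), cs$d, tolerance = 1e-9)
    ## coordination census at the most interior point
    ctr <- which.min(rowSums(sweep(sc$positions, 2, c(45, 45, 45))^2))
    expect_identical(sum(abs(dmat[ctr, ] - cs$d) < 1e-6 * cs$d),
                     as.integer(cs$coord))
  }
})

test_that("HCP second distance class is sqrt(2) times the diameter", {
  d <- 15.05
  sc <- generate_lattice_points(lattice_spec("HCP", d), c(100, 100, 100),
                                jitter_sd = 0, seed = 1)
  ctr <- which.min(rowSums(sweep(sc$positions, 2, c(50, 50, 50))^2))
  dd <- sort(sqrt(rowSums(sweep(sc$positions, 2,
                                sc$positions[ctr, ])^2)))
  second <- min(dd[dd > d * (1 + 1e-6)])
  expect_equal(second, sqrt(2) * d, tolerance = 1e-9)
})

test_that("ideal unit cells have the canonical point counts, distances and stacking", {
  d <- 15.05
  hcp <- ideal_unit_cell("HCP", d)
  ccp <- ideal_unit_cell("CCP", d)
  bcc <- ideal_unit_cell("BCC", d)
  expect_identical(nrow(hcp), 13L)
  expect_identical(nrow(ccp), 13L)
  expect_identical(nrow(bcc), 9L)
  for (cell in list(hcp, ccp, bcc))
    expect_equal(sqrt(rowSums(cell[-1, ]^2)), rep(d, nrow(cell) - 1),
                 tolerance = 1e-9)
  ## A-B-A layering: 3 below, 6 coplanar, 3 above
  z <- round(hcp[, 3], 9)
  expect_identical(as.integer(table(factor(sign(z), c(-1, 0, 1)))),
                   c(3L, 7L, 3L))
  ## HCP outer triangles eclipsed, CCP staggered by 60 degrees
  azi <- function(p) sort(round(atan2(p[, 2], p[, 1]) * 180 / pi) %% 360)
  hcp_top <- hcp[hcp[, 3] > 1, ]; hcp_bot <- hcp[hcp[, 3] < -1, ]
  ccp_top <- ccp[ccp[, 3] > 1, ]; ccp_bot <- ccp[ccp[, 3] < -1, ]
  expect_equal(azi(hcp_top), azi(hcp_bot))
  expect_equal(sort((azi(ccp_bot) - azi(ccp_top)) %% 120), rep(60, 3))
  expect_error(ideal_unit_cell("RANDOM", d), "unit cell")
})

test_that("scene generation is seed-reproducible and respects the extent", {
  sc1 <- generate_lattice_points(lattice_spec("HCP", 15), c(80, 80, 80),
                                 jitter_sd = 1, seed = 9)
  sc2 <- generate_lattice_points(lattice_spec("HCP", 15), c(80, 80, 80),
                                 jitter_sd = 1, seed = 9)
  expect_identical(sc1$positions, sc2$positions)
  expect_true(all(sc1$positions >= 0 & sc1$positions <= 80))
  ## degenerate box holds exactly the centered point
  tiny <- generate_lattice_points(lattice_spec("HCP", 15), c(10, 10, 10),
                                  jitter_sd = 0, seed = 1)
  expect_identical(nrow(tiny$positions), 1L)
  expect_error(lattice_spec("HCP", -1), "positive")
})

test_that("RANDOM scenes are hard-sphere and fail cleanly when over-packed", {
  sc <- generate_lattice_points(lattice_spec("RANDOM", 12), c(80, 80, 80),
                                jitter_sd = 0, seed = 3, n_random = 40)
  dmat <- as.matrix(dist(sc$positions))
  diag(dmat) <- Inf
  expect_gte(min(dmat), 12)
  sc2 <- generate_lattice_points(lattice_spec("RANDOM", 12), c(80, 80, 80),
                                 jitter_sd = 0, seed = 3, n_random = 40)
  expect_identical(sc$positions, sc2$positions)
  expect_error(
    generate_lattice_points(lattice_spec("RANDOM", 30), c(40, 40, 40),
                            seed = 1, n_random = 50, max_tries = 50),
    "placement")
})

test_that("scene rendering is deterministic, linear, and mass-conserving", {
  sc <- make_interior_scene("HCP", 15.05, c(70, 70, 70), seed = 2)
  ## snap to voxel centers so every sphere is sampled identically
  sc$positions <- (round(sc$positions / 1.9 - 0.5) + 0.5) * 1.9
  v1 <- render_scene(sc, 1.9, particle_diameter = 13)
  v2 <- render_scene(sc, 1.9, particle_diameter = 13)
  expect_identical(v1$data, v2$data)
  ## single particle: the center voxel attains the global maximum
  one <- sc
  ctr_idx <- 19
  ctr_nm <- (ctr_idx - 0.5) * 1.9
  one$positions <- matrix(rep(ctr_nm, 3), 1)
  one$orientations <- matrix(0, 1, 3)
  r1 <- render_scene(one, 1.9, particle_diameter = 13)
  expect_equal(r1$data[ctr_idx, ctr_idx, ctr_idx], max(r1$data),
               tolerance = 1e-12)
  ## total mass = n particles x one-sphere mass (all spheres interior,
  ## voxel-aligned)
  expect_equal(sum(v1$data), nrow(sc$positions) * sum(r1$data),
               tolerance = 1e-6)
  ## linearity: union scene equals sum of part renders
  scA <- sc; scA$positions <- sc$positions[1:3, , drop = FALSE]
  scB <- sc; scB$positions <- sc$positions[-(1:3), , drop = FALSE]
  vA <- render_scene(scA, 1.9, particle_diameter = 13)
  vB <- render_scene(scB, 1.9, particle_diameter = 13)
  expect_equal(v1$data, vA$data + vB$data, tolerance = 1e-6)
})

test_that("missing wedge removes the complementary Fourier sector", {
  sc <- make_interior_scene("HCP", 15.05, c(60, 60, 60), seed = 2)
  tilt <- tilt_geometry(2, 60)
  vw <- render_scene(sc, 2, particle_diameter = 13, tilt = tilt)
  f <- fft(vw$data)
  dims <- dim(vw$data)
  fr <- function(n) c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
  kx <- fr(dims[1])[5]; kz <- fr(dims[3])[12]
  ## a coefficient well inside the wedge (|angle from kx axis| > 60 deg)
  expect_true(atan2(abs(kz), abs(kx)) > 60 * pi / 180)
  expect_lt(Mod(f[5, 1, 12]), 1e-6 * max(Mod(f)))
  expect_error(tilt_geometry(0, 60), "tilt_increment")
})

test_that("membrane stacks repeat at the summed layer widths with a bright lumen", {
  lm <- layer_model(4.9, 9.0, 3.6, n_layers = 5)
  expect_equal(lm$repeat_nm, 22.4)
  vol <- generate_membrane_stack(lm, voxel_size = 0.5)
  x <- (seq_len(dim(vol$data)[1]) - 0.5) * 0.5
  prof <- vol$data[, 1, 1]
  margin <- 2 * lm$repeat_nm
  lum1 <- x > margin + 4.9 + 1 & x < margin + 4.9 + 8      # first lumen core
  gap1 <- x > margin + 18.8 + 0.8 & x < margin + 22.4 - 0.8 # first gap core
  expect_gt(mean(prof[lum1]), mean(prof[gap1]))
  ## two layers -> exactly one interthylakoid gap
  seg <- tomopack:::stack_segments(layer_model(n_layers = 2), margin = 10)
  expect_identical(sum(abs(seg$levels - 0.5) < 1e-12) - 2L, 1L)
  expect_error(generate_membrane_stack(lm, voxel_size = 2), "2 voxels")
})

test_that("invagination fixtures honor the counting rule and ground-truth density", {
  fx <- generate_invagination_fixture(12, membrane_area = 1, seed = 5)
  expect_identical(fx$density, 12)
  expect_identical(fx$records$counted,
                   fx$records$size_i > fx$records$envelope_m)
  all_small <- generate_invagination_fixture(
    10, size_distribution = function(n) rep(5, n),
    envelope_width = 15, membrane_area = 2, seed = 1)
  expect_identical(sum(all_small$records$counted), 0L)
  all_big <- generate_invagination_fixture(
    10, size_distribution = function(n) rep(50, n),
    envelope_width = 15, membrane_area = 2, seed = 1)
  expect_identical(sum(all_big$records$counted), 10L)
})
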