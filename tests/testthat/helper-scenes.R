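# Fixtures built in code: interior lattice scenes (no boundary-clipped
# spheres), small asymmetric alignment objects, polycrystal clouds.

# Lattice scene whose particles all sit >= margin from every face, so a
# render at the given diameter has no clipped spheres.
make_interior_scene <- function(model, d, extent, jitter_sd = 0, seed = 1,
                                margin = 8) {
  sc <- generate_lattice_points(lattice_spec(model, d), extent,
                                jitter_sd = jitter_sd, seed = seed)
  keep <- rowSums(sweep(sc$positions, 2, rep(margin, 3), `>=`) &
                  sweep(sc$positions, 2, extent - margin, `<=`)) == 3
  sc$positions <- sc$positions[keep, , drop = FALSE]
  sc$orientations <- sc$orientations[keep, , drop = FALSE]
  sc
}

# Small asymmetric density object (no rotational symmetry) for
# alignment recovery tests.
make_asym_object <- function(n = 16, voxel_size = 1) {
  obj <- array(0, c(n, n, n))
  q <- n %/% 4
  obj[(q + 1):(2 * q), (q + 1):(3 * q), (2 * q - 1):(2 * q + 1)] <- 1
  obj[(2 * q + 1):(3 * q), (2 * q - 1):(2 * q + 1), (q + 1):(3 * q)] <- 2
  obj[(q):(q + 1), (q):(q + 1), (q):(q + 1)] <- 3
  density_volume(obj, voxel_size)
}

# Offsets of the 12 ideal first-shell HCP neighbors under a rotation.
rotated_shell <- function(model, d, R) {
  ideal_unit_cell(model, d)[-1, , drop = FALSE] %*% t(R)
}

# Two-domain polycrystal neighborhoods: n_per domain references, each
# with the full first-shell neighborhood, domain 2 rotated by R2.
# Returns neighborhoods plus the true per-reference rotations that map
# each domain back to the common frame.
make_polycrystal <- function(d = 15.05, n_per = 20, R2 = euler_zyz(30, 0, 0),
                             jitter_sd = 0.2, seed = 1) {
  shell <- ideal_unit_cell("HCP", d)[-1, ]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  nbhd <- list(); rots <- list()
  for (i in seq_len(n_per)) {
    nbhd[[i]] <- shell + matrix(rnorm(36, sd = jitter_sd), ncol = 3)
    rots[[i]] <- diag(3)
  }
  for (i in seq_len(n_per)) {
    nbhd[[n_per + i]] <- (shell + matrix(rnorm(36, sd = jitter_sd),
                                         ncol = 3)) %*% t(R2)
    rots[[n_per + i]] <- t(R2)   # maps domain-2 offsets back to common frame
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  list(neighborhoods = nbhd, rotations = rots)
}

# Mean distance of pooled points to the nearest of the 12 ideal shell
# positions (cloud tightness metric).
shell_tightness <- function(offsets, d) {
  shell <- ideal_unit_cell("HCP", d)[-1, ]
  mean(apply(offsets, 1, function(p)
    min(sqrt(rowSums(sweep(shell, 2, p)^2)))))
}

# End-to-end recovery pipeline at desk scale: jittered HCP scene (SNR 1)
# -> spherical-template matching -> subtomogram alignment/averaging ->
# transform-pooled neighbor cloud -> k-means -> hard-sphere model
# selection. Matching knobs scale with the scene's lattice spacing d
# (see the methods vignette): band-limit 0.35 d, exclusion 0.475 d,
# score threshold 0.15 + 0.02 (d - 13).
run_recovery_pipeline <- function(d_true, seed, voxel_size = 1.9,
                                  extent = c(120, 120, 80)) {
  sc <- generate_lattice_points(lattice_spec("HCP", d_true), extent,
                                jitter_sd = 0.05 * d_true, seed = seed)
  vol <- suppressMessages(render_scene(sc, voxel_size,
                                       particle_diameter = 13,
                                       noise_sd = 1, seed = seed + 100))
  ## matched filter: template half-max diameter = rendered half-max
  ## (rendered spheres roll off to zero at their nominal radius)
  tmpl <- make_spherical_template(13 - voxel_size, voxel_size)
  co <- 0.35 * d_true
  cmap <- match_template(lowpass(vol, co), lowpass(tmpl, co))
  pk <- extract_peaks(cmap, 0.475 * d_true, min_score = 0.22)
  st <- suppressMessages(extract_subvolumes(vol, pk, 45.6))
  avg <- suppressWarnings(
    iterative_average(st, angular_schedule = c(30, 30, 15, 15),
                      max_shift = 3, align_lowpass = co,
                      initial_reference = "box", seed = 7))
  nb12 <- nearest_k_filter(range_query(pk, 1.5 * d_true)[st$ids], 12)
  cl <- pooled_cloud(nb12, avg$transforms, include_self = TRUE)
  cmod <- cluster_centers(cl, 13, seed = 3)
  fit <- select_model(cmod$centers)
  list(scene = sc, n_particles = nrow(sc$positions),
       n_peaks = length(pk), n_boxes = length(st), fit = fit)
}
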