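test_that("phantom truth is zero under identity transforms", {
  ph <- make_phantom(edge_length = 1.2)
  s <- ph$truth$pre$summary
  expect_equal(s$max_step_off, 0)
  expect_equal(s$max_gap, 0)
  expect_equal(length(ph$pre$meshes), 2)
  expect_error(make_phantom(radius = 3, thickness = 4),
               class = "acefrac_invalid_argument")
})

test_that("phantom fragments tile the intact cup shell", {
  ph <- make_phantom(edge_length = 1.2)
  # fragment surfaces lie on the intact (same-side) cup except cut faces
  cup <- ph$fractured_side
  for (m in ph$reduced_fragments$meshes) {
    d <- RANN::nn2(cup$vertices, m$vertices, k = 1)$nn.dists
    expect_lt(stats::quantile(d, 0.90), 0.7) # cut faces are the far tail
    expect_lt(max(d), ph$params$thickness / 2 + 0.1)
  }
  # shell volume adds up to the intact shell volume
  vol_frag <- sum(vapply(ph$reduced_fragments$meshes, mesh_volume, 0))
  expect_lt(abs(vol_frag - mesh_volume(cup)) / mesh_volume(cup), 0.02)
})

test_that("the intact side is an exact mirror of the fractured side", {
  ph <- make_phantom(edge_length = 1.0)
  mirrored <- transform_mesh(ph$intact,
                             mirror_transform(frac_plane(c(0, 0, 0), c(1, 0, 0))))
  d <- RANN::nn2(ph$fractured_side$vertices, mirrored$vertices, k = 1)$nn.dists
  expect_lt(max(d), 1e-9)
  # and ICP confirms it: mirrored-contralateral onto ipsilateral, RMS < 0.1
  set.seed(6)
  fit <- icp_register(mirrored, ph$fractured_side, n_samples = 2000)
  expect_lt(fit$rms, 0.1)
})

test_that("phantom construction is deterministic and seeds drive displacements", {
  d1 <- random_displacements(2, seed = 123)
  d2 <- random_displacements(2, seed = 123)
  d3 <- random_displacements(2, seed = 124)
  expect_equal(d1$fragment_1$translation, d2$fragment_1$translation)
  expect_false(isTRUE(all.equal(d1$fragment_1$translation,
                                d3$fragment_1$translation)))
  # drawn components respect the stated ranges
  for (s in 1:10) {
    dd <- random_displacements(2, seed = s)
    for (i in 1:2) {
      tr <- dd[[i]]$translation
      p <- drop(acefrac:::.cup_point(c(40, 0, 0), 27, pi / 4,
                                     mean(acefrac:::.sector_ranges(2)[[i]])))
      u_n <- (c(40, 0, 0) - p) / sqrt(sum((c(40, 0, 0) - p)^2))
      n_mag <- abs(sum(tr * u_n))
      t_mag <- sqrt(sum((tr - sum(tr * u_n) * u_n)^2))
      expect_gte(n_mag, 2 - 1e-9); expect_lte(n_mag, 8 + 1e-9)
      expect_gte(t_mag, 2 - 1e-9); expect_lte(t_mag, 20 + 1e-9)
    }
  }
})

test_that("voxelization reproduces analytic volumes and surfaces", {
  ph1 <- make_phantom(n_fragments = 1, edge_length = 1.0, rim_mod_deg = 0)
  cup <- ph1$pre$meshes[[1]]
  vol <- voxelize(cup, spacing = 1, bone_hu = 700)
  occupied <- sum(vol$data == 700)
  shell <- 2 / 3 * pi * (27^3 - 23^3) # hemispherical shell volume
  expect_lt(abs(occupied * 1 - shell) / shell, 0.03)
  # empty input gives uniform background
  v0 <- voxelize(list(), spacing = 1, background_hu = -1000)
  expect_true(all(v0$data == -1000))
  # re-meshing the voxelization stays within a voxel of the source surface
  mesh2 <- mask_to_mesh(vol$data >= 226, volume = vol)
  d <- RANN::nn2(cup$vertices, mesh2$vertices, k = 1)$nn.dists
  expect_lt(mean(d), 1)
})

test_that("voxelized sphere occupancy matches the analytic volume", {
  # analytic sphere r = 20 voxelized at 1 mm: count within 3% of 4/3 pi r^3
  theta <- seq(0, pi, length.out = 80)
  phi <- seq(0, 2 * pi, length.out = 160)
  P <- array(0, c(80, 160, 3))
  for (j in seq_along(phi)) {
    P[, j, 1] <- 20 * sin(theta) * cos(phi[j])
    P[, j, 2] <- 20 * sin(theta) * sin(phi[j])
    P[, j, 3] <- 20 * cos(theta)
  }
  sph <- merge_vertices(acefrac:::.grid_mesh(P), 1e-7)
  vol <- voxelize(sph, spacing = 1)
  count <- sum(vol$data > 0)
  expect_lt(abs(count - 4 / 3 * pi * 20^3) / (4 / 3 * pi * 20^3), 0.03)
})
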