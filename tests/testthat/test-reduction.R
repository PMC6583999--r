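test_that("mirror templates reflect across the midsagittal plane and invert", {
  cube <- unit_cube_mesh()
  pl <- frac_plane(c(0, 0, 0), c(1, 0, 0))
  tmpl <- build_mirror_template(cube, pl)
  expect_equal(sort(tmpl$vertices[, 1]), sort(-cube$vertices[, 1]))
  back <- transform_mesh(tmpl, mirror_transform(pl))
  ord <- function(v) unname(v[order(v[, 1], v[, 2], v[, 3]), ])
  expect_equal(ord(back$vertices), ord(cube$vertices), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("ICP recovers identity on self-registration and rejects degenerate input", {
  set.seed(2)
  ph <- make_phantom(n_fragments = 1, edge_length = 1.5)
  cup <- ph$pre$meshes[[1]]
  cloud <- cup$vertices[sample.int(nrow(cup$vertices), 1500), ]
  fit <- icp_register(cloud, cup)
  expect_lt(fit$rms, 1e-6)
  expect_lt(transform_magnitude(fit$transform)["translation_mm"], 1e-3)
  expect_error(icp_register(matrix(rnorm(6), 2, 3), cup),
               class = "acefrac_invalid_argument")
  expect_error(icp_register(cbind(1:5, 2 * (1:5), 3 * (1:5)), cup),
               class = "acefrac_invalid_argument")
})

test_that("ICP inverts a known rigid displacement to sub-millidegree accuracy", {
  set.seed(3)
  ph <- make_phantom(n_fragments = 1, edge_length = 1.0)
  cup <- ph$pre$meshes[[1]]
  cloud <- cup$vertices[sample.int(nrow(cup$vertices), 3000), ]
  applied <- rotation_about(c(0, 0, 1), 10, centre = colMeans(cup$vertices),
                            translation = c(5, 0, 0))
  moved <- transform_points(applied, cloud)
  fit <- icp_register(moved, cup)
  err <- compose_transforms(fit$transform, applied)
  expect_lt(transform_magnitude(err)["translation_mm"], 1e-3)
  expect_lt(transform_magnitude(err)["rotation_deg"], 1e-3)
  expect_lt(fit$rms, fit$rms_init)
})

test_that("registration is equivariant under a joint rotation of the scene", {
  set.seed(4)
  ph <- make_phantom(n_fragments = 1, edge_length = 1.5)
  cup <- ph$pre$meshes[[1]]
  applied <- rigid_transform(translation = c(3, -2, 1))
  moved <- transform_mesh(cup, applied)
  set.seed(10)
  fit <- icp_register(moved, cup, n_samples = 2000)
  R <- rotation_about(c(1, 1, 1), 25, centre = c(10, 0, 0))
  set.seed(10)
  fit_rot <- icp_register(transform_mesh(moved, R), transform_mesh(cup, R),
                          n_samples = 2000)
  conj <- compose_transforms(R, compose_transforms(fit$transform,
                                                   invert_transform(R)))
  expect_lt(max(abs(conj$linear - fit_rot$transform$linear)), 1e-4)
  expect_lt(max(abs(conj$translation - fit_rot$transform$translation)), 5e-3)
})

test_that("virtual reduction recovers applied fragment displacements", {
  disp <- random_displacements(2, seed = 77)
  ph <- make_phantom(displacements = disp, edge_length = 1.0)
  tmpl <- build_mirror_template(ph$intact, frac_plane(c(0, 0, 0), c(1, 0, 0)))
  set.seed(1)
  red <- reduce_fragments(ph$pre, tmpl, region = ph$region, n_samples = 4000)
  expect_true(all(red$reduced))
  for (i in 1:2) {
    err <- compose_transforms(red$transform[[i]], disp[[i]])
    expect_lt(transform_magnitude(err)["translation_mm"], 0.2)
    expect_lt(transform_magnitude(err)["rotation_deg"], 0.2)
  }
})

test_that("already-reduced fragments yield near-identity reductions", {
  ph <- make_phantom(edge_length = 1.2)
  tmpl <- build_mirror_template(ph$intact, frac_plane(c(0, 0, 0), c(1, 0, 0)))
  set.seed(1)
  red <- reduce_fragments(ph$pre, tmpl, region = ph$region, n_samples = 3000)
  for (tf in red$transform)
    expect_lt(transform_magnitude(tf)["translation_mm"], 0.05)
})

test_that("a fragment from a different bone is flagged unreduced", {
  ph <- make_phantom(edge_length = 1.2)
  tmpl <- build_mirror_template(ph$intact, frac_plane(c(0, 0, 0), c(1, 0, 0)))
  alien <- unit_cube_mesh()
  alien$vertices <- alien$vertices * 10 + matrix(c(80, 40, 40), 8, 3, byrow = TRUE)
  alien$fragment_id <- "alien"
  set.seed(1)
  expect_warning(
    red <- reduce_fragments(fragment_set(list(alien), "pre"), tmpl,
                            region = ph$region, n_samples = 2000),
    regexp = "unreduced")
  expect_false(red$reduced[1])
})

test_that("pre-to-post matching finds residual poses from reduction inits", {
  resid <- list(fragment_1 = rigid_transform(translation = c(0.8, -0.5, 0.3)),
                fragment_2 = rigid_transform(translation = c(-1.2, 0.6, -0.4)))
  disp <- random_displacements(2, seed = 9, tangential_range = c(2, 8))
  ph <- make_phantom(displacements = disp, post_displacements = resid,
                     edge_length = 1.0)
  post_model <- merge_meshes(ph$post$meshes, "post")
  tmpl <- build_mirror_template(ph$intact, frac_plane(c(0, 0, 0), c(1, 0, 0)))
  set.seed(1)
  red <- reduce_fragments(ph$pre, tmpl, region = ph$region, n_samples = 4000)
  set.seed(2)
  mat <- match_pre_to_post(ph$pre, post_model,
                           init_transforms = reduction_transforms(red),
                           n_samples = 4000)
  expect_true(all(mat$matched))
  for (i in 1:2) {
    # displaced pre -> post should equal resid o (applied displacement)^-1
    want <- compose_transforms(resid[[i]], invert_transform(disp[[i]]))
    err <- compose_transforms(invert_transform(mat$transform[[i]]), want)
    expect_lt(transform_magnitude(err)["translation_mm"], 0.2)
  }
})
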