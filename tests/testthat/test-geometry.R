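test_that("euclidean distance matches hand-computed values and properties", {
  expect_equal(euclidean_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(euclidean_distance(c(1, 1, 1), c(1, 1, 1)), 0)
  expect_equal(euclidean_distance(c(1, 2, 2), c(0, 0, 0)), 3) # sqrt(1+4+4)
  set.seed(11)
  a <- matrix(rnorm(30), ncol = 3); b <- matrix(rnorm(30), ncol = 3)
  expect_equal(euclidean_distance(a, b), euclidean_distance(b, a))
  expect_true(all(euclidean_distance(a, b) >= 0))
  expect_error(euclidean_distance(c(NA, 0, 0), c(0, 0, 0)),
               class = "acefrac_invalid_argument")
})

test_that("displacement decomposition reproduces worked examples", {
  d1 <- decompose_displacement(c(0, 0, 3), c(0, 0, 1))
  expect_equal(d1$step_off, 3)
  expect_equal(d1$gap, 0)
  d2 <- decompose_displacement(c(3, 4, 0), c(0, 0, 1))
  expect_equal(d2$step_off, 0)
  expect_equal(d2$gap, 5)
  d3 <- decompose_displacement(c(1, 2, 2), c(0, 0, 1))
  expect_equal(d3$step_off, 2)
  expect_equal(d3$gap, sqrt(5), tolerance = 1e-12)
  expect_error(decompose_displacement(c(1, 0, 0), c(0, 0, 2)),
               class = "acefrac_invalid_argument")
})

test_that("step-off and gap close pythagorically and are rotation-invariant", {
  set.seed(7)
  d <- matrix(rnorm(3e4), ncol = 3)
  n <- t(apply(matrix(rnorm(3e4), ncol = 3), 1, function(v) v / sqrt(sum(v^2))))
  dec <- decompose_displacement(d, n)
  expect_lt(max(abs(dec$step_off^2 + dec$gap^2 - rowSums(d^2))), 1e-9)
  # joint rotation of d and n leaves the decomposition unchanged
  R <- random_rotation()
  dec_rot <- decompose_displacement(d %*% t(R), n %*% t(R))
  expect_lt(max(abs(dec_rot$step_off - dec$step_off)), 1e-9)
  expect_lt(max(abs(dec_rot$gap - dec$gap)), 1e-9)
})

test_that("planes from points contain their generators and reject collinear input", {
  pl <- plane_from_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(abs(pl$normal), c(0, 0, 1))
  pl5 <- plane_from_points(c(0, 0, 5), c(1, 0, 5), c(0, 1, 5))
  expect_equal(abs(pl5$normal), c(0, 0, 1))
  expect_lt(abs(plane_distance(pl5, c(2, 7, 5))), 1e-9)
  pl2 <- plane_from_points(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1))
  expect_equal(abs(pl2$normal), c(0, 1, 0))
  expect_error(plane_from_points(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               class = "acefrac_degenerate_geometry")
})

test_that("mirror transform is an involutive isometry fixing its plane", {
  m <- mirror_transform(frac_plane(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(drop(transform_points(m, c(1, 2, 3))), c(-1, 2, 3))
  expect_equal(det(m$linear), -1)
  set.seed(3)
  pts <- matrix(rnorm(60, sd = 10), ncol = 3)
  pl <- frac_plane(rnorm(3), random_unit_vector())
  mt <- mirror_transform(pl)
  twice <- transform_points(mt, transform_points(mt, pts))
  expect_lt(max(abs(twice - pts)), 1e-9)
  # points on the plane are fixed
  on_plane <- sweep(t(replicate(5, {
    v <- rnorm(3); v - sum(v * pl$normal) * pl$normal
  })), 2, pl$point, "+")
  expect_lt(max(abs(transform_points(mt, on_plane) - on_plane)), 1e-9)
  # pairwise distances preserved
  refl <- transform_points(mt, pts)
  expect_lt(max(abs(dist(refl) - dist(pts))), 1e-9)
})

test_that("rigid transforms validate, compose and invert correctly", {
  expect_error(rigid_transform(matrix(1, 3, 3)), class = "acefrac_invalid_argument")
  R <- random_rotation()
  tf <- rigid_transform(R, c(1, -2, 3))
  rt <- compose_transforms(invert_transform(tf), tf)
  expect_lt(max(abs(rt$linear - diag(3))), 1e-9)
  expect_lt(max(abs(rt$translation)), 1e-9)
  back <- from_matrix4(as_matrix4(tf))
  expect_equal(back$linear, tf$linear)
  expect_equal(back$translation, tf$translation)
  rot <- rotation_about(c(0, 0, 1), 90, centre = c(1, 0, 0))
  expect_equal(drop(transform_points(rot, c(2, 0, 0))), c(1, 1, 0),
               tolerance = 1e-12)
})
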