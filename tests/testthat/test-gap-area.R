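flat_lines <- function(length_mm = 10, step = 0.1) {
  tibble::tibble(
    line_id = "l1", fragment_id = "fragment_1",
    adjacent_fragment_id = "fragment_2", articular = TRUE,
    length_mm = length_mm,
    points = list(cbind(seq(0, length_mm, by = step), 0, 0)))
}

flat_view <- function() {
  standard_view(landmark_set(list(
    aiis = c(0, 0, 0), foramen_inferolateral = c(50, 0, 0),
    ramus_superior_prominence = c(0, 50, 0))),
    midline_hint = c(0, 0, -100))
}

test_that("the standardized view is oriented away from the midline", {
  lm <- landmark_set(list(aiis = c(0, 0, 0), foramen_inferolateral = c(50, 0, 0),
                          ramus_superior_prominence = c(0, 50, 0)))
  v1 <- standard_view(lm, midline_hint = c(0, 0, -100))
  expect_equal(v1$plane$normal, c(0, 0, 1))
  v2 <- standard_view(lm, midline_hint = c(0, 0, 100))
  expect_equal(v2$plane$normal, c(0, 0, -1))
  expect_error(standard_view(landmark_set(list(
    aiis = c(0, 0, 0), foramen_inferolateral = c(50, 0, 0),
    ramus_superior_prominence = c(100, 0, 0))), c(0, 0, -1)),
    class = "acefrac_degenerate_geometry")
})

test_that("the phantom's landmark plane reproduces its cup axis", {
  ph <- make_phantom(edge_length = 1.5)
  v <- standard_view(ph$landmarks, midline_hint = c(0, 0, 0))
  # cup opens along +x; the view normal should be the cup axis within 1 degree
  ang <- acos(abs(sum(v$plane$normal * c(1, 0, 0)))) * 180 / pi
  expect_lt(ang, 1)
})

test_that("a straight separated fracture line gives the analytic rectangle", {
  lines <- flat_lines(10)
  poses <- list(fragment_1 = rigid_transform(),
                fragment_2 = rigid_transform(translation = c(0, 2, 0)))
  res <- total_gap_area(lines, poses, flat_view())
  expect_equal(res$area, 20, tolerance = 0.02 * 20)
  # zero displacement: zero area
  res0 <- total_gap_area(lines, list(fragment_1 = rigid_transform(),
                                     fragment_2 = rigid_transform()),
                         flat_view())
  expect_equal(res0$area, 0)
  # pure view-direction (step-off) displacement projects to zero width
  resz <- total_gap_area(lines, list(
    fragment_1 = rigid_transform(),
    fragment_2 = rigid_transform(translation = c(0, 0, 5))), flat_view())
  expect_lt(resz$area, 1e-9)
})

test_that("overlapping ribbons are counted once (union, not sum)", {
  lines <- dplyr::bind_rows(flat_lines(10), flat_lines(10))
  lines$line_id <- c("l1", "l2")
  lines$points[[2]] <- cbind(seq(5, 15, by = 0.1), 0, 0) # shifted copy
  poses <- list(fragment_1 = rigid_transform(),
                fragment_2 = rigid_transform(translation = c(0, 2, 0)))
  res <- total_gap_area(lines, poses, flat_view())
  # two 20 mm^2 ribbons sharing 10 mm^2 -> union 30, sum 40
  expect_equal(res$area, 30, tolerance = 0.02 * 30)
  expect_lt(res$area, 40 - 5)
})

test_that("polygon union and rasterization agree within the stated bound", {
  set.seed(9)
  for (rep in 1:3) {
    y <- cumsum(rnorm(60, sd = 0.3))
    lines <- flat_lines(10)
    lines$points[[1]] <- cbind(seq(0, 10, length.out = 60), y, 0)
    poses <- list(fragment_1 = rigid_transform(),
                  fragment_2 = rigid_transform(translation = c(0.3, 1.5, 0)))
    a_poly <- total_gap_area(lines, poses, flat_view())$area
    a_rast <- total_gap_area(lines, poses, flat_view(), method = "raster",
                             raster_step = 0.05)$area
    len <- sum(sqrt(rowSums(diff(lines$points[[1]])^2)))
    expect_lt(abs(a_poly - a_rast), 2 * 0.05 * len)
  }
})

test_that("gap area is invariant under in-plane rotation of the scene", {
  lines <- flat_lines(12)
  poses <- list(fragment_1 = rigid_transform(translation = c(1, 0.5, 0)),
                fragment_2 = rigid_transform(translation = c(-0.5, -1.5, 0)))
  a0 <- total_gap_area(lines, poses, flat_view())$area
  rot <- rotation_about(c(0, 0, 1), 37, centre = c(5, 5, 0))
  lines_r <- lines
  lines_r$points[[1]] <- transform_points(rot, lines$points[[1]])
  poses_r <- lapply(poses, function(p) compose_transforms(
    rot, compose_transforms(p, invert_transform(rot))))
  a1 <- total_gap_area(lines_r, poses_r, flat_view())$area
  expect_equal(a1, a0, tolerance = 1e-6 * max(a0, 1))
})

test_that("scaling tangential separation never shrinks the gap area", {
  set.seed(14)
  for (rep in 1:20) {
    d <- c(runif(1, 0.5, 3), runif(1, 0.5, 3), 0)
    lines <- flat_lines(8)
    areas <- vapply(c(1, 1.5, 2.5), function(k)
      total_gap_area(lines, list(
        fragment_1 = rigid_transform(),
        fragment_2 = rigid_transform(translation = k * d)), flat_view())$area, 0)
    expect_true(all(diff(areas) >= -1e-9))
  }
})

test_that("peripheral lines enter the area only on request", {
  lines <- flat_lines(10)
  lines$adjacent_fragment_id <- NA_character_
  poses <- list(fragment_1 = rigid_transform(translation = c(0, 3, 0)))
  expect_equal(total_gap_area(lines, poses, flat_view())$area, 0)
  res <- total_gap_area(lines, poses, flat_view(), include_peripheral = TRUE)
  expect_equal(res$area, 30, tolerance = 0.02 * 30)
})
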