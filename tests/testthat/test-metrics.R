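test_that("fracture lines follow the cut meridians at the articular surface", {
  # perfect hemisphere (no rim modulation): cut through the apex gives one
  # line per fragment of length ~ pi * articular radius (half great circle)
  ph <- make_phantom(radius = 27, thickness = 4, rim_mod_deg = 0,
                     edge_length = 0.8)
  tmpl <- ph$fractured_side
  lines <- extract_fracture_lines(ph$reduced_fragments, ph$region, tmpl,
                                  resample_step = 0.5)
  expect_equal(nrow(lines), 2) # one per fragment
  ri <- 27 - 4
  # the measured line stops rim_tol short of the rim at each end
  for (i in seq_len(nrow(lines)))
    expect_lt(abs(lines$length_mm[i] - pi * ri) / (pi * ri), 0.06)
  # interior adjacency is reciprocal between the two fragments
  expect_setequal(lines$fragment_id, c("fragment_1", "fragment_2"))
  expect_equal(lines$adjacent_fragment_id[lines$fragment_id == "fragment_1"],
               "fragment_2")
  expect_equal(lines$adjacent_fragment_id[lines$fragment_id == "fragment_2"],
               "fragment_1")
  # resampling respects the step bound
  for (p in lines$points)
    expect_lte(max(sqrt(rowSums(diff(p)^2))), 0.5 + 1e-9)
})

test_that("an unfractured cup has no fracture lines", {
  ph <- make_phantom(n_fragments = 1, edge_length = 1.0)
  lines <- extract_fracture_lines(ph$reduced_fragments, ph$region,
                                  ph$fractured_side)
  expect_equal(nrow(lines), 0)
})

test_that("three-fragment phantoms give reciprocal interior lines", {
  ph <- make_phantom(n_fragments = 3, edge_length = 1.0)
  lines <- extract_fracture_lines(ph$reduced_fragments, ph$region,
                                  ph$fractured_side)
  expect_true(all(!is.na(lines$adjacent_fragment_id)))
  pairs <- unique(t(apply(cbind(lines$fragment_id,
                                lines$adjacent_fragment_id), 1, sort)))
  expect_equal(nrow(pairs), 3) # (1,2), (2,3), (1,3)
})

test_that("identity poses give an all-zero displacement profile", {
  ph <- make_phantom(edge_length = 1.0)
  prof <- ph$truth$pre$profile
  expect_true(all(prof$step_off == 0))
  expect_true(all(prof$gap == 0))
  expect_equal(summarize_displacement(prof)$max_gap, 0)
})

test_that("flat-patch phantoms decompose applied offsets exactly", {
  # pure normal offset: step-off everywhere, no gap
  phn <- make_flat_phantom(displacements = list(
    fragment_1 = rigid_transform(translation = c(0, 0, 3))), edge_length = 1)
  pn <- phn$truth$pre$profile
  expect_lt(max(abs(pn$step_off - 3)), 1e-9)
  expect_lt(max(pn$gap), 1e-9)
  # pure tangential offset: gap everywhere, no step-off
  pht <- make_flat_phantom(displacements = list(
    fragment_1 = rigid_transform(translation = c(4, 0, 0))), edge_length = 1)
  pt <- pht$truth$pre$profile
  expect_lt(max(abs(pt$gap - 4)), 1e-9)
  expect_lt(max(pt$step_off), 1e-9)
})

test_that("surface-tangential offsets stay gap-only on the cut meridian", {
  # the cut meridians lie in the plane y = 0, so a +y translation is
  # tangential to the articular sphere at every line point: gap = 4,
  # step-off ~ 0 (template normals lie in the meridian plane)
  ph <- make_phantom(radius = 29, thickness = 4, displacements = list(
    fragment_1 = rigid_transform(translation = c(0, 4, 0))), edge_length = 1)
  prof <- ph$truth$pre$profile
  expect_lt(max(prof$step_off), 0.15)
  expect_gt(min(prof$gap), 3.9)
  expect_lte(max(prof$gap), 4 + 1e-9)
})

test_that("summaries average with uniform arc-length weight across lines", {
  lines <- tibble::tibble(
    line_id = c("a", "b"), fragment_id = "fragment_1",
    adjacent_fragment_id = NA_character_, articular = TRUE,
    length_mm = c(10, 20),
    points = list(cbind(seq(0, 10, by = 0.5), 0, 0),
                  cbind(seq(40, 60, by = 0.5), 0, 0)))
  poses <- list(fragment_1 = rigid_transform(translation = c(0, 0, 2)))
  region <- articular_plane(c(0, 0, 0), c(0, 0, 1))
  prof <- displacement_profile(lines, poses, region)
  # brute-force enumeration over all resampled points
  expect_equal(summarize_displacement(prof)$mean_step_off,
               mean(prof$step_off))
  expect_equal(summarize_displacement(prof)$n_points, 21 + 41)
  s <- summarize_displacement(prof)
  expect_gte(s$max_step_off, s$mean_step_off)
  expect_error(summarize_displacement(prof[0, ]),
               class = "acefrac_invalid_argument")
})

test_that("profile errors on missing poses and respects pair deduplication", {
  lines <- tibble::tibble(
    line_id = c("l1", "l2"),
    fragment_id = c("fragment_1", "fragment_2"),
    adjacent_fragment_id = c("fragment_2", "fragment_1"), articular = TRUE,
    length_mm = 10, points = list(cbind(0:10, 0, 0), cbind(0:10, 0, 0)))
  region <- articular_plane(c(0, 0, 0), c(0, 0, 1))
  poses <- list(fragment_1 = rigid_transform(),
                fragment_2 = rigid_transform(translation = c(0, 0, 1)))
  prof <- displacement_profile(lines, poses, region)
  # the pair is measured once, owned by the smaller fragment id
  expect_equal(unique(prof$line_id), "l1")
  expect_error(displacement_profile(lines, poses["fragment_1"], region),
               class = "acefrac_invalid_argument")
})

test_that("2D slice emulation projects out the through-plane component", {
  mk_prof <- function(d, n = c(0, 0, 1)) {
    lines <- tibble::tibble(
      line_id = "l", fragment_id = "fragment_1",
      adjacent_fragment_id = NA_character_, articular = TRUE, length_mm = 10,
      points = list(cbind(seq(0, 10, 0.5), 0, 0)))
    displacement_profile(lines,
                         list(fragment_1 = rigid_transform(translation = d)),
                         articular_plane(c(0, 0, 0), n))
  }
  # displacement along the slice-stack axis vanishes in-plane
  p1 <- slice_2d_measurement(mk_prof(c(0, 0, 3), n = c(0, 1, 0)), "axial")
  expect_equal(p1$max_gap_2d, 0, tolerance = 1e-12)
  # in-plane displacement is fully seen by axial slicing
  p2 <- slice_2d_measurement(mk_prof(c(3, 4, 0), n = c(0, 0, 1)), "axial")
  expect_equal(p2$max_gap_2d, 5, tolerance = 1e-12)
  # oblique displacement is underestimated: (0,3,4) -> in-plane 3 vs norm 5
  p3 <- slice_2d_measurement(mk_prof(c(0, 3, 4), n = c(0, 1, 0)), "axial")
  expect_equal(sqrt(p3$max_gap_2d^2 + p3$max_step_2d^2), 3, tolerance = 1e-12)
  expect_error(slice_2d_measurement(mk_prof(c(1, 1, 1)), "axial",
                                    slice_thickness = -1),
               class = "acefrac_invalid_argument")
})

test_that("2D slice measurements never exceed their 3D counterparts", {
  set.seed(12)
  for (rep in 1:5) {
    disp <- random_displacements(2, seed = 300 + rep)
    ph <- make_phantom(displacements = disp, edge_length = 1.2)
    prof <- ph$truth$pre$profile
    s3 <- summarize_displacement(prof)
    for (ax in c("axial", "coronal", "sagittal")) {
      s2 <- slice_2d_measurement(prof, ax)
      expect_lte(s2$max_gap_2d, s3$max_gap + 1e-9)
      expect_lte(s2$max_step_2d, s3$max_step_off + 1e-9)
    }
  }
})

test_that("halving the resample step barely moves the summaries", {
  disp <- random_displacements(2, seed = 55)
  ph1 <- make_phantom(displacements = disp, edge_length = 1, resample_step = 0.5)
  ph2 <- make_phantom(displacements = disp, edge_length = 1, resample_step = 0.25)
  s1 <- ph1$truth$pre$summary
  s2 <- ph2$truth$pre$summary
  expect_lt(abs(s1$max_gap - s2$max_gap), 0.05)
  expect_lt(abs(s1$max_step_off - s2$max_step_off), 0.05)
})
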