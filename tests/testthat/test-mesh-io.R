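test_that("STL round-trips preserve geometry in both dialects", {
  cube <- unit_cube_mesh()
  ascii <- withr::local_tempfile(fileext = ".stl")
  bin <- withr::local_tempfile(fileext = ".stl")
  write_mesh(cube, ascii)
  write_mesh(cube, bin, binary = TRUE)
  ma <- read_mesh(ascii)
  mb <- read_mesh(bin)
  expect_equal(nrow(ma$vertices), 8)
  expect_equal(nrow(ma$faces), 12)
  # both dialects describe the same cube after vertex merging
  expect_equal(ma$vertices[order(ma$vertices[, 1], ma$vertices[, 2], ma$vertices[, 3]), ],
               mb$vertices[order(mb$vertices[, 1], mb$vertices[, 2], mb$vertices[, 3]), ],
               tolerance = 1e-6)
  expect_equal(mesh_area(ma), 6, tolerance = 1e-6)
  expect_equal(mesh_volume(ma), 1, tolerance = 1e-6)
})

test_that("PLY round-trip is stable and malformed meshes are refused", {
  cube <- unit_cube_mesh()
  ply <- withr::local_tempfile(fileext = ".ply")
  write_mesh(cube, ply)
  mp <- read_mesh(ply)
  expect_equal(sort(mp$vertices[, 1] + 2 * mp$vertices[, 2] + 4 * mp$vertices[, 3]),
               0:7, tolerance = 1e-6)
  expect_error(read_mesh(withr::local_tempfile(fileext = ".stl")),
               class = "acefrac_format_error")
  bad <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("not", "a", "ply"), bad)
  expect_error(read_mesh(bad), class = "acefrac_format_error")
  expect_error(triangle_mesh(matrix(0, 2, 3), matrix(c(1, 2, 5), 1)),
               class = "acefrac_invalid_argument")
})

test_that("volumes map voxel indices to world mm through their spacing", {
  vol <- voxel_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 2))
  # voxel (1,1,2) sits 2 mm along z from the origin voxel
  expect_equal(voxel_to_world(vol, c(1, 1, 2)), matrix(c(0, 0, 2), 1))
  expect_warning(voxel_volume(array(0, c(2, 2, 2)), spacing = c(1, 1, 3)))
  expect_error(voxel_volume(array(0, c(2, 2)), c(1, 1, 1)),
               class = "acefrac_format_error")
})

test_that("NIfTI volumes round-trip with intensities and spacing intact", {
  vol <- voxel_volume(array(rnorm(6 * 5 * 4), c(6, 5, 4)), c(1, 1, 2),
                      origin = c(-3, 2, 7))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(max(abs(back$data - vol$data)), 0, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-5)
})

test_that("landmark files enforce the required names and units", {
  lm <- landmark_set(list(aiis = c(0, 0, 0),
                          foramen_inferolateral = c(50, 0, 0),
                          ramus_superior_prominence = c(0, 50, 0),
                          extra = c(9, 9, 9)))
  path <- withr::local_tempfile(fileext = ".json")
  write_landmarks(lm, path)
  back <- read_landmarks(path)
  expect_equal(back$aiis, c(0, 0, 0))
  expect_equal(back$extra, c(9, 9, 9))
  expect_error(landmark_set(list(foramen_inferolateral = c(50, 0, 0),
                                 ramus_superior_prominence = c(0, 50, 0))),
               regexp = "aiis", class = "acefrac_schema_error")
  expect_error(landmark_set(list(aiis = c(0, 0, 0),
                                 foramen_inferolateral = c(1, 0, 0),
                                 ramus_superior_prominence = c(0, 50, 0))),
               class = "acefrac_schema_error")
  nojson <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(units = "cm", points = list(aiis = c(0, 0, 0))),
                       nojson, auto_unbox = TRUE)
  expect_error(read_landmarks(nojson), class = "acefrac_schema_error")
})

test_that("fracture lines and reports survive a write/read cycle", {
  lines <- tibble::tibble(
    line_id = "line_1", fragment_id = "fragment_1",
    adjacent_fragment_id = "fragment_2", articular = TRUE,
    points = list(cbind(0, seq(-5, 5, by = 0.5), 0)))
  path <- withr::local_tempfile(fileext = ".json")
  write_fracture_lines(lines, path)
  back <- read_fracture_lines(path)
  expect_equal(back$points[[1]], lines$points[[1]], tolerance = 1e-12)
  expect_equal(back$adjacent_fragment_id, "fragment_2")

  ph <- make_flat_phantom(displacements = list(
    fragment_2 = rigid_transform(translation = c(0, 0, 2))), edge_length = 2)
  s <- ph$truth$pre$summary
  report <- structure(list(
    summaries = list(pre = as.list(s[, 1:6]), post = NULL),
    gap_area = list(pre = 12.5, post = NULL),
    provenance = list(seed = 1)), class = "frac_report")
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_report(report, jp, cp)
  back <- read_report(jp)
  expect_equal(back$summaries$pre$max_step_off, s$max_step_off, tolerance = 1e-9)
  csv <- utils::read.csv(cp)
  expect_true(all(c("state", "metric", "value") %in% names(csv)))
  expect_equal(csv$value[csv$metric == "total_gap_area"], 12.5)
})
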