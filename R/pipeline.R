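# End-to-end analysis: mirror template -> virtual reduction -> fracture
# lines -> displacement profiles -> summaries, total gap area, grading,
# reduction percentages -- assembled into a reproducible report.

.default_thresholds <- list(
  hu_threshold = 226, min_voxels = 50, rms_max = 2, resample_step = 0.5,
  adjacency_tol = 2, sphere_band = 2.5, raster_step = 0.1, n_samples = 5000,
  slice_thickness = 2)

#' Analyse a fractured joint against its mirrored intact side
#'
#' Runs the full 3D measurement method: mirrors the intact contralateral
#' mesh into a template, virtually reduces each preoperative fragment onto
#' it by ICP, extracts fracture lines on the articular surface in reduced
#' pose, computes per-point step-off/gap profiles and summaries and the
#' projected total gap area, and (when a postoperative model is supplied)
#' matches fragments into the postoperative state and grades the reduction.
#'
#' @param pre Preoperative `fragment_set` (displaced pose).
#' @param intact Intact contralateral `frac_mesh`.
#' @param landmarks A `landmark_set` (for the standardized gap-area view).
#' @param post Optional postoperative `frac_mesh` (whole model).
#' @param symmetry_plane Optional midsagittal `frac_plane`; fitted from the
#'   intact mesh when omitted.
#' @param midline_hint Point on the pelvic midline, used to orient the view.
#' @param region Optional `articular_region`; fitted to the template when
#'   omitted.
#' @param criteria `"3dct"`, `"matta"` or `"both"`.
#' @param seed RNG seed (surface sampling in ICP).
#' @param include_peripheral Include peripheral lines in the gap area.
#' @param thresholds Named list overriding entries of the defaults:
#'   `rms_max` (mm), `resample_step` (mm), `adjacency_tol` (mm),
#'   `sphere_band` (mm), `raster_step` (mm), `n_samples`, `slice_thickness`.
#' @return A `frac_report` list: `summaries`, `gap_area`, `grading`,
#'   `reduction_pct`, `overall_reduction_pct`, `reduction` (registration
#'   table), `slice_2d`, `provenance`; plus (as attributes) the `profiles`
#'   and `lines` tibbles for inspection.
#' @export
analyze_fracture <- function(pre, intact, landmarks = NULL, post = NULL,
                             symmetry_plane = NULL,
                             midline_hint = c(0, 0, 0), region = NULL,
                             criteria = c("both", "3dct", "matta"),
                             seed = 1, include_peripheral = FALSE,
                             thresholds = list()) {
  criteria <- match.arg(criteria)
  th <- utils::modifyList(.default_thresholds, thresholds)
  bad <- names(th)[!vapply(th, function(v) is.numeric(v) && v > 0, TRUE)]
  if (length(bad)) .stop_schema(paste0("thresholds must be positive: ",
                                       paste(bad, collapse = ", ")))
  set.seed(seed)

  template <- build_mirror_template(intact, symmetry_plane)
  if (is.null(region)) region <- fit_articular(template, band = th$sphere_band)

  reduction <- reduce_fragments(pre, template, rms_max = th$rms_max,
                                n_samples = th$n_samples)
  red_tf <- reduction_transforms(reduction)
  reduced <- fragment_set(lapply(names(pre$meshes), function(id)
    transform_mesh(pre$meshes[[id]], red_tf[[id]])), "pre")

  lines <- extract_fracture_lines(reduced, region, template,
                                  resample_step = th$resample_step,
                                  adjacency_tol = th$adjacency_tol)
  if (nrow(lines) == 0) .stop_invalid("no fracture lines found on the articular surface")

  pre_poses <- lapply(red_tf, invert_transform)
  prof_pre <- displacement_profile(lines, pre_poses, region)
  sum_pre <- summarize_displacement(prof_pre, "pre")

  view <- NULL; area_pre <- NULL
  if (!is.null(landmarks)) {
    view <- standard_view(landmarks, midline_hint)
    area_pre <- total_gap_area(lines, pre_poses, view,
                               include_peripheral = include_peripheral,
                               raster_step = th$raster_step)
  }

  slice2d <- bind_rows(lapply(c("axial", "coronal", "sagittal"), function(ax)
    mutate(slice_2d_measurement(prof_pre, ax, th$slice_thickness),
           state = "pre", .before = 1)))

  matching <- NULL; prof_post <- NULL; sum_post <- NULL; area_post <- NULL
  if (!is.null(post)) {
    matching <- match_pre_to_post(pre, post, init_transforms = red_tf,
                                  rms_max = th$rms_max,
                                  n_samples = th$n_samples)
    match_tf <- reduction_transforms(matching)
    post_poses <- setNames(lapply(names(red_tf), function(id)
      compose_transforms(match_tf[[id]], invert_transform(red_tf[[id]]))),
      names(red_tf))
    prof_post <- displacement_profile(lines, post_poses, region)
    sum_post <- summarize_displacement(prof_post, "post")
    if (!is.null(view))
      area_post <- total_gap_area(lines, post_poses, view,
                                  include_peripheral = include_peripheral,
                                  raster_step = th$raster_step)
    slice2d <- bind_rows(slice2d,
      bind_rows(lapply(c("axial", "coronal", "sagittal"), function(ax)
        mutate(slice_2d_measurement(prof_post, ax, th$slice_thickness),
               state = "post", .before = 1))))
  }

  # grade the assessment state: postoperative when given, else preoperative
  gs <- sum_post %||% sum_pre
  ga <- if (!is.null(post)) area_post else area_pre
  grading <- list()
  if (criteria %in% c("both", "matta")) {
    grading$matta <- list(
      gap = as.character(matta_grade(gs$max_gap)),
      step_off = as.character(matta_grade(gs$max_step_off)),
      overall = as.character(matta_grade(max(gs$max_gap, gs$max_step_off))))
  }
  if (criteria %in% c("both", "3dct") && !is.null(ga)) {
    g3 <- grade_3dct(gs$max_gap, gs$max_step_off, ga$area)
    grading$criteria_3dct <- setNames(as.character(g3$category), g3$parameter)
  }

  reduction_pct <- NULL; overall <- NULL
  if (!is.null(sum_post)) {
    reduction_pct <- list(
      mean_step_off = residual_pct(sum_pre$mean_step_off, sum_post$mean_step_off),
      mean_gap = residual_pct(sum_pre$mean_gap, sum_post$mean_gap))
    if (!is.null(area_pre) && !is.null(area_post) && area_pre$area > 0)
      reduction_pct$total_gap_area <- residual_pct(area_pre$area, area_post$area)
    overall <- overall_reduction(unlist(reduction_pct))
  }

  config <- list(criteria = criteria, seed = seed,
                 include_peripheral = include_peripheral, thresholds = th)
  provenance <- list(
    package_version = as.character(utils::packageVersion("acefrac")),
    config = config,
    config_hash = digest::digest(config),
    fragments = names(pre$meshes),
    seed = seed)

  report <- structure(list(
    summaries = list(pre = as.list(sum_pre[, 1:7]),
                     post = if (!is.null(sum_post)) as.list(sum_post[, 1:7])),
    gap_area = list(pre = if (!is.null(area_pre)) area_pre$area,
                    post = if (!is.null(area_post)) area_post$area),
    grading = grading,
    reduction_pct = reduction_pct,
    overall_reduction_pct = overall,
    reduction = as.list(reduction[, c("fragment_id", "rms", "rms_init",
                                      "iterations", "reduced")]),
    matching = if (!is.null(matching))
      as.list(matching[, c("fragment_id", "rms", "iterations", "matched")]),
    slice_2d = as.list(slice2d),
    provenance = provenance), class = "frac_report")
  attr(report, "profiles") <- list(pre = prof_pre, post = prof_post)
  attr(report, "lines") <- lines
  attr(report, "view") <- view
  attr(report, "gap_area_result") <- list(pre = area_pre, post = area_post)
  report
}

#' @export
print.frac_report <- function(x, ...) {
  cat("3D fracture measurement report\n")
  for (state in intersect(c("pre", "post"), names(x$summaries))) {
    s <- x$summaries[[state]]
    if (is.null(s)) next
    cat(sprintf("  %s: max step-off %.2f mm, max gap %.2f mm, mean step-off %.2f mm, mean gap %.2f mm\n",
                state, s$max_step_off, s$max_gap, s$mean_step_off, s$mean_gap))
    if (!is.null(x$gap_area[[state]]))
      cat(sprintf("       total gap area %.1f mm^2\n", x$gap_area[[state]]))
  }
  if (!is.null(x$grading$matta))
    cat("  Matta: ", paste(names(x$grading$matta),
                           unlist(x$grading$matta), sep = "=", collapse = ", "), "\n")
  if (!is.null(x$grading$criteria_3dct))
    cat("  3DCT: ", paste(names(x$grading$criteria_3dct),
                          unlist(x$grading$criteria_3dct), sep = "=",
                          collapse = ", "), "\n")
  if (!is.null(x$overall_reduction_pct))
    cat(sprintf("  overall reduction: residual %.1f%% of initial displacement\n",
                x$overall_reduction_pct))
  invisible(x)
}

#' @export
glance.frac_report <- function(x, ...) {
  s <- x$summaries
  tibble(
    pre_max_step_off = s$pre$max_step_off, pre_max_gap = s$pre$max_gap,
    post_max_step_off = s$post$max_step_off %||% NA_real_,
    post_max_gap = s$post$max_gap %||% NA_real_,
    pre_gap_area = x$gap_area$pre %||% NA_real_,
    post_gap_area = x$gap_area$post %||% NA_real_,
    overall_reduction_pct = x$overall_reduction_pct %||% NA_real_)
}

.known_config_keys <- c("input", "phantom", "thresholds", "criteria", "seed",
                        "include_peripheral", "midline_hint", "output")

#' Run the measurement pipeline from a configuration
#'
#' The configuration (YAML path or list) either names input files
#' (`input: pre: [paths], intact: path, landmarks: path, post: path`,
#' optionally `volume_pre` to segment a NIfTI instead of reading meshes) or
#' requests a synthetic phantom (`phantom: seed: 7, n_fragments: 2, ...`).
#' Unknown keys and non-positive thresholds are rejected before any
#' computation. Identical configuration and inputs give identical reports.
#'
#' @param config YAML file path or configuration list.
#' @return A `frac_report` (see [analyze_fracture()]).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown)) .stop_schema(paste0("unknown config key(s): ",
                                           paste(unknown, collapse = ", ")))
  th <- config$thresholds %||% list()
  badth <- setdiff(names(th), names(.default_thresholds))
  if (length(badth)) .stop_schema(paste0("unknown threshold(s): ",
                                         paste(badth, collapse = ", ")))
  if (any(!vapply(th, function(v) is.numeric(v) && v > 0, TRUE)))
    .stop_schema("thresholds must be positive numbers")
  seed <- config$seed %||% 1

  if (!is.null(config$phantom)) {
    ph_args <- config$phantom
    ph_seed <- ph_args$seed %||% seed
    ph_args$seed <- NULL
    disp <- random_displacements(
      n_fragments = ph_args$n_fragments %||% 2,
      radius = ph_args$radius %||% 27,
      cup_centre_x = ph_args$cup_centre_x %||% 40, seed = ph_seed)
    ph <- do.call(make_phantom, c(ph_args, list(displacements = disp)))
    pre <- ph$pre; intact <- ph$intact; landmarks <- ph$landmarks
    post <- NULL
    symmetry_plane <- frac_plane(c(0, 0, 0), c(1, 0, 0))
    region <- ph$region
  } else if (!is.null(config$input)) {
    inp <- config$input
    if (!is.null(inp$volume_pre)) {
      vol <- read_volume(inp$volume_pre)
      pre <- segment_fragments(vol, th$hu_threshold %||% 226,
                               th$min_voxels %||% 50, source = "pre")
    } else {
      pre <- fragment_set(lapply(inp$pre, read_mesh), "pre")
    }
    intact <- read_mesh(inp$intact)
    landmarks <- if (!is.null(inp$landmarks)) read_landmarks(inp$landmarks)
    post <- if (!is.null(inp$post)) read_mesh(inp$post)
    symmetry_plane <- NULL
    region <- NULL
  } else .stop_schema("config needs either an 'input' or a 'phantom' section")

  report <- analyze_fracture(
    pre, intact, landmarks = landmarks, post = post,
    symmetry_plane = symmetry_plane, region = region,
    midline_hint = as.numeric(config$midline_hint %||% c(0, 0, 0)),
    criteria = config$criteria %||% "both", seed = seed,
    include_peripheral = isTRUE(config$include_peripheral),
    thresholds = th[setdiff(names(th), c("hu_threshold", "min_voxels"))])
  if (!is.null(config$output)) {
    write_report(report, config$output$json %||% "report.json",
                 csv_path = config$output$csv)
  }
  report
}
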