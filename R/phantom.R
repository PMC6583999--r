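# Synthetic validation phantom: a hemispherical articular cup (acetabulum
# analog) fractured into 2-3 fragments by planar cuts through the apex, with
# exactly known per-fragment rigid displacements, a mirror-symmetric intact
# contralateral cup, landmarks on a known plane, a voxelized pseudo-CT, and
# synthetic rater tables. Ground truth is computed analytically from the
# applied transforms, so the full pipeline can be validated without any
# patient data.

.grid_mesh <- function(P) {
  # P: nu x nv x 3 array of grid points -> triangulated frac_mesh
  nu <- dim(P)[1]; nv <- dim(P)[2]
  verts <- cbind(as.vector(P[, , 1]), as.vector(P[, , 2]), as.vector(P[, , 3]))
  idx <- function(i, j) i + (j - 1L) * nu
  i <- rep(seq_len(nu - 1), nv - 1)
  j <- rep(seq_len(nv - 1), each = nu - 1)
  f1 <- cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
  f2 <- cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
  triangle_mesh(verts, rbind(f1, f2))
}

.cup_point <- function(centre, r, theta, phi) {
  # cup axis +x (opening lateral); phi measured around x from +y to +z
  cbind(centre[1] - r * cos(theta),
        centre[2] + r * sin(theta) * cos(phi),
        centre[3] + r * sin(theta) * sin(phi))
}

.theta_max <- function(phi, rim_mod_rad, phi0 = pi / 4) {
  # rim-height variation mixing the 2nd and 3rd azimuthal harmonics, like
  # the irregular saddle shape of a real acetabular rim. The mix matters
  # for identifiability of the azimuth under surface registration: a pure
  # 1st harmonic is absorbable by tilting the cup axis, and a pure k-th
  # harmonic leaves a residual k-fold rotational symmetry.
  pi / 2 - rim_mod_rad * (2 - cos(2 * (phi - phi0)) - cos(3 * (phi - phi0))) / 4
}

.cup_patch <- function(centre, r, phi_range, rim_mod_rad, edge) {
  # spherical patch r = const, theta in [0, theta_max(phi)]
  arc_u <- r * pi / 2
  nu <- max(3L, ceiling(arc_u / edge) + 1L)
  nv <- max(3L, ceiling(r * abs(diff(phi_range)) / edge) + 1L)
  u <- seq(0, 1, length.out = nu)
  phi <- seq(phi_range[1], phi_range[2], length.out = nv)
  P <- array(0, c(nu, nv, 3))
  for (j in seq_len(nv)) {
    th <- u * .theta_max(phi[j], rim_mod_rad)
    P[, j, ] <- .cup_point(centre, r, th, phi[j])
  }
  P
}

.rim_band <- function(centre, r_in, r_out, phi_range, rim_mod_rad, edge) {
  nu <- max(2L, ceiling((r_out - r_in) / edge) + 1L)
  nv <- max(3L, ceiling(r_out * abs(diff(phi_range)) / edge) + 1L)
  rr <- seq(r_in, r_out, length.out = nu)
  phi <- seq(phi_range[1], phi_range[2], length.out = nv)
  P <- array(0, c(nu, nv, 3))
  for (j in seq_len(nv)) {
    th <- .theta_max(phi[j], rim_mod_rad)
    P[, j, ] <- .cup_point(centre, rr, rep(th, nu), phi[j])
  }
  P
}

.cut_face <- function(centre, r_in, r_out, phi, rim_mod_rad, edge) {
  thm <- .theta_max(phi, rim_mod_rad)
  nu <- max(3L, ceiling(r_out * thm / edge) + 1L)
  nv <- max(2L, ceiling((r_out - r_in) / edge) + 1L)
  th <- seq(0, thm, length.out = nu)
  rr <- seq(r_in, r_out, length.out = nv)
  P <- array(0, c(nu, nv, 3))
  for (j in seq_len(nv)) P[, j, ] <- .cup_point(centre, rr[j], th, phi)
  P
}

.orient_patch <- function(mesh, dir_fun) {
  # flip a parametric patch so its face normals follow the outward field
  fn <- face_normals(mesh)
  want <- dir_fun(fn$centroids)
  if (sum(rowSums(fn$normals * want) * fn$areas) < 0)
    mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

.cup_shell <- function(centre, radius, thickness, phi_range, rim_mod_rad,
                       edge, cut_faces = TRUE, fragment_id = NULL) {
  ri <- radius - thickness
  radial <- function(p) sweep(p, 2, centre)
  parts <- list(
    .orient_patch(.grid_mesh(.cup_patch(centre, radius, phi_range, rim_mod_rad, edge)),
                  function(p) radial(p)),
    .orient_patch(.grid_mesh(.cup_patch(centre, ri, phi_range, rim_mod_rad, edge)),
                  function(p) -radial(p)),
    .orient_patch(.grid_mesh(.rim_band(centre, ri, radius, phi_range, rim_mod_rad, edge)),
                  function(p) matrix(c(1, 0, 0), nrow(p), 3, byrow = TRUE)))
  if (cut_faces) {
    phi_dir <- function(phi) c(0, -sin(phi), cos(phi)) # d(point)/d(phi) direction
    parts <- c(parts, list(
      .orient_patch(.grid_mesh(.cut_face(centre, ri, radius, phi_range[1], rim_mod_rad, edge)),
                    function(p) matrix(-phi_dir(phi_range[1]), nrow(p), 3, byrow = TRUE)),
      .orient_patch(.grid_mesh(.cut_face(centre, ri, radius, phi_range[2], rim_mod_rad, edge)),
                    function(p) matrix(phi_dir(phi_range[2]), nrow(p), 3, byrow = TRUE))))
  }
  m <- merge_meshes(parts, fragment_id)
  merge_vertices(m, 1e-7)
}

.sector_ranges <- function(n_fragments) {
  if (n_fragments == 1) list(c(-pi / 2, 3 * pi / 2))
  else if (n_fragments == 2) list(c(-pi / 2, pi / 2), c(pi / 2, 3 * pi / 2))
  else if (n_fragments == 3) list(c(-pi / 2, pi / 2), c(pi / 2, pi), c(pi, 3 * pi / 2))
  else .stop_invalid("n_fragments must be 1, 2 or 3")
}

.phantom_landmarks <- function(centre) {
  landmark_set(list(
    aiis = centre + c(0, 35, 15),
    foramen_inferolateral = centre + c(0, -20, -25),
    ramus_superior_prominence = centre + c(0, -28, 22)))
}

#' Generate a fractured articular-cup phantom with known ground truth
#'
#' The fractured (right) side is a hemispherical shell of the given radius
#' and wall thickness centred at `(cup_centre_x, 0, 0)`, opening along +x
#' (laterally, away from the midsagittal plane x = 0); the intact
#' contralateral side is its exact mirror image. The shell is cut into
#' `n_fragments` sectors by planar cuts through the apex and each fragment is
#' displaced by the supplied rigid transform. The rim height varies smoothly
#' with azimuth by up to `rim_mod_deg` (default 10 degrees, about 4.7 mm of
#' rim-height variation -- the scale seen on real acetabular rims; set 0 for
#' a perfect hemisphere). This irregular rim is what makes rotation about
#' the cup axis identifiable to surface registration, exactly as the
#' irregular anatomy does clinically. Landmarks sit on the rim plane
#' x = `cup_centre_x`, whose normal is the cup axis.
#'
#' Ground truth (fracture lines at the cut meridians of the articular
#' surface, and their exact displacement profiles and summaries) is computed
#' analytically from the applied transforms without any registration.
#'
#' @param radius Outer cup radius, mm (default 27, adult acetabulum scale).
#' @param thickness Shell wall thickness, mm (default 4).
#' @param n_fragments 1, 2 or 3 fragments.
#' @param displacements Named list (`fragment_1`, ...) of `frac_rigid`
#'   applied displacements; missing entries mean identity.
#' @param post_displacements Optional residual transforms defining a
#'   postoperative state (same convention).
#' @param edge_length Target mesh edge length, mm (default 0.5).
#' @param rim_mod_deg Azimuthal rim-height modulation, degrees (default 4).
#' @param cup_centre_x Lateral offset of the cup centre, mm.
#' @param resample_step Truth fracture-line resampling step, mm.
#' @return A `frac_phantom` list: `pre` (`fragment_set`), `post` (or NULL),
#'   `intact` (contralateral `frac_mesh`), `fractured_side` (unfractured
#'   right-side cup, for reference), `landmarks`, `region` (articular
#'   sphere), `truth` (lines, profile, summary, per-state), `params`.
#' @export
make_phantom <- function(radius = 27, thickness = 4, n_fragments = 2,
                         displacements = NULL, post_displacements = NULL,
                         edge_length = 0.5, rim_mod_deg = 10,
                         cup_centre_x = 40, resample_step = 0.5) {
  if (thickness <= 0 || radius <= thickness)
    .stop_invalid("need radius > thickness > 0")
  centre <- c(cup_centre_x, 0, 0)
  rim_mod <- rim_mod_deg * pi / 180
  ri <- radius - thickness
  sectors <- .sector_ranges(n_fragments)
  ids <- paste0("fragment_", seq_len(n_fragments))

  reduced <- lapply(seq_len(n_fragments), function(i)
    .cup_shell(centre, radius, thickness, sectors[[i]], rim_mod, edge_length,
               cut_faces = n_fragments > 1, fragment_id = ids[i]))
  names(reduced) <- ids

  full_tf <- function(given) {
    tf <- setNames(rep(list(rigid_transform()), n_fragments), ids)
    for (nm in names(given)) {
      if (!nm %in% ids) .stop_invalid(paste0("unknown fragment in displacements: ", nm))
      tf[[nm]] <- given[[nm]]
    }
    tf
  }
  pre_tf <- full_tf(displacements %||% list())
  pre <- fragment_set(lapply(ids, function(id)
    transform_mesh(reduced[[id]], pre_tf[[id]])), "pre")

  post <- NULL; post_tf <- NULL
  if (!is.null(post_displacements)) {
    post_tf <- full_tf(post_displacements)
    post <- fragment_set(lapply(ids, function(id)
      transform_mesh(reduced[[id]], post_tf[[id]])), "post")
  }

  intact_right <- .cup_shell(centre, radius, thickness, c(-pi / 2, 3 * pi / 2),
                             rim_mod, edge_length, cut_faces = FALSE,
                             fragment_id = "intact_right")
  midsagittal <- frac_plane(c(0, 0, 0), c(1, 0, 0))
  intact <- transform_mesh(intact_right, mirror_transform(midsagittal))
  intact$fragment_id <- "intact"

  region <- articular_sphere(centre, ri)

  # truth fracture lines: articular meridians at the cut azimuths
  cut_phis <- if (n_fragments == 1) numeric() else
    sort(unique(vapply(sectors, `[`, 0, 1)))
  pair_at <- function(phi) {
    # fragments whose sector boundary touches this azimuth
    touch <- which(vapply(sectors, function(s)
      any(abs(((s - phi + pi) %% (2 * pi)) - pi) < 1e-9), TRUE))
    sort(touch)
  }
  truth_lines <- NULL
  if (length(cut_phis) > 0) {
    rows <- lapply(seq_along(cut_phis), function(q) {
      phi <- cut_phis[q]
      pr <- pair_at(phi)
      thm <- .theta_max(phi, rim_mod)
      np <- max(2L, ceiling(ri * thm / resample_step) + 1L)
      pts <- .cup_point(centre, ri, seq(0, thm, length.out = np), phi)
      tibble(line_id = paste0("truth_cut_", q),
             fragment_id = ids[pr[1]],
             adjacent_fragment_id = ids[pr[2]],
             articular = TRUE,
             length_mm = ri * thm,
             points = list(pts))
    })
    truth_lines <- bind_rows(rows)
  }

  truth_state <- function(tf) {
    if (is.null(truth_lines)) return(NULL)
    prof <- displacement_profile(truth_lines, tf, region)
    list(profile = prof, summary = summarize_displacement(prof))
  }
  truth <- list(lines = truth_lines,
                transforms = pre_tf, post_transforms = post_tf,
                pre = truth_state(pre_tf),
                post = if (!is.null(post_tf)) truth_state(post_tf) else NULL)

  structure(list(pre = pre, post = post, intact = intact,
                 fractured_side = intact_right,
                 reduced_fragments = fragment_set(reduced, "pre"),
                 landmarks = .phantom_landmarks(centre), region = region,
                 truth = truth,
                 params = list(radius = radius, thickness = thickness,
                               n_fragments = n_fragments,
                               edge_length = edge_length,
                               rim_mod_deg = rim_mod_deg,
                               cup_centre_x = cup_centre_x)),
            class = "frac_phantom")
}

#' Flat-plate phantom with a planar articular facet
#'
#' A rectangular plate (articular surface the plane z = 0, normal +z) cut by
#' the plane x = 0 into two fragments. On a flat facet a pure normal offset
#' is pure step-off and a pure tangential offset is pure gap, so displacement
#' decomposition can be checked exactly.
#'
#' @param half_width Plate half-width, mm (plate spans +/- this in x and y).
#' @param thickness Plate thickness, mm.
#' @param displacements Named list (`fragment_1`, `fragment_2`) of applied
#'   `frac_rigid` transforms.
#' @param edge_length Mesh edge length, mm.
#' @param resample_step Truth line resampling step, mm.
#' @return A `frac_phantom`-like list (no intact side or landmarks): `pre`,
#'   `reduced_fragments`, `region`, `truth`.
#' @export
make_flat_phantom <- function(half_width = 20, thickness = 4,
                              displacements = NULL, edge_length = 0.5,
                              resample_step = 0.5) {
  ids <- c("fragment_1", "fragment_2")
  box <- function(x0, x1, id) {
    xs <- seq(x0, x1, length.out = max(2L, ceiling((x1 - x0) / edge_length) + 1L))
    ys <- seq(-half_width, half_width,
              length.out = max(2L, ceiling(2 * half_width / edge_length) + 1L))
    zs <- c(-thickness, 0)
    g <- function(a, b, fixed, axis) {
      P <- array(0, c(length(a), length(b), 3))
      ax <- setdiff(1:3, axis)
      for (j in seq_along(b)) {
        P[, j, ax[1]] <- a
        P[, j, ax[2]] <- b[j]
        P[, j, axis] <- fixed
      }
      P
    }
    const_dir <- function(d) function(p) matrix(d, nrow(p), 3, byrow = TRUE)
    parts <- list(
      .orient_patch(.grid_mesh(g(xs, ys, 0, 3)), const_dir(c(0, 0, 1))),
      .orient_patch(.grid_mesh(g(xs, ys, -thickness, 3)), const_dir(c(0, 0, -1))),
      .orient_patch(.grid_mesh(g(xs, zs, -half_width, 2)), const_dir(c(0, -1, 0))),
      .orient_patch(.grid_mesh(g(xs, zs, half_width, 2)), const_dir(c(0, 1, 0))),
      .orient_patch(.grid_mesh(g(ys, zs, x0, 1)), const_dir(c(-1, 0, 0))),
      .orient_patch(.grid_mesh(g(ys, zs, x1, 1)), const_dir(c(1, 0, 0))))
    m <- merge_meshes(parts, id)
    merge_vertices(m, 1e-7)
  }
  reduced <- list(fragment_1 = box(-half_width, 0, ids[1]),
                  fragment_2 = box(0, half_width, ids[2]))
  tf <- setNames(rep(list(rigid_transform()), 2), ids)
  for (nm in names(displacements %||% list())) tf[[nm]] <- displacements[[nm]]
  pre <- fragment_set(lapply(ids, function(id)
    transform_mesh(reduced[[id]], tf[[id]])), "pre")
  region <- articular_plane(c(0, 0, 0), c(0, 0, 1))
  np <- max(2L, ceiling(2 * half_width / resample_step) + 1L)
  truth_lines <- tibble(
    line_id = "truth_cut_1", fragment_id = ids[1],
    adjacent_fragment_id = ids[2], articular = TRUE,
    length_mm = 2 * half_width,
    points = list(cbind(0, seq(-half_width, half_width, length.out = np), 0)))
  prof <- displacement_profile(truth_lines, tf, region)
  structure(list(pre = pre, post = NULL, intact = NULL,
                 reduced_fragments = fragment_set(reduced, "pre"),
                 landmarks = NULL, region = region,
                 truth = list(lines = truth_lines, transforms = tf,
                              pre = list(profile = prof,
                                         summary = summarize_displacement(prof))),
                 params = list(half_width = half_width, thickness = thickness,
                               edge_length = edge_length)),
            class = "frac_phantom")
}

#' Random phantom displacements in a validation range
#'
#' Draws, for each fragment, a pure-translation displacement whose component
#' along the local articular normal (radial direction at the fragment's
#' mid-sector meridian) has magnitude in `normal_range` and whose tangential
#' component has magnitude in `tangential_range`, with random signs and
#' tangential direction.
#'
#' @param n_fragments Number of fragments.
#' @param normal_range Normal-component magnitude range, mm (default c(2, 8)).
#' @param tangential_range Tangential magnitude range, mm (default c(2, 20)).
#' @param radius,cup_centre_x Cup geometry (to locate radial directions).
#' @param seed Optional RNG seed.
#' @return Named list of `frac_rigid` translations.
#' @export
random_displacements <- function(n_fragments = 2, normal_range = c(2, 8),
                                 tangential_range = c(2, 20), radius = 27,
                                 cup_centre_x = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  centre <- c(cup_centre_x, 0, 0)
  sectors <- .sector_ranges(n_fragments)
  out <- list()
  for (i in seq_len(n_fragments)) {
    phi_mid <- mean(sectors[[i]])
    th_mid <- pi / 4
    p_mid <- drop(.cup_point(centre, radius, th_mid, phi_mid))
    u_n <- drop(.unit(centre - p_mid))            # articular normal
    a <- drop(.unit(stats::rnorm(3)))
    u_t <- drop(.unit(a - sum(a * u_n) * u_n))    # random tangential direction
    mag_n <- runif(1, normal_range[1], normal_range[2]) * sample(c(-1, 1), 1)
    mag_t <- runif(1, tangential_range[1], tangential_range[2])
    out[[paste0("fragment_", i)]] <- rigid_transform(diag(3),
                                                     mag_n * u_n + mag_t * u_t)
  }
  out
}

#' Voxelize meshes into a pseudo-CT volume
#'
#' Solid voxelization by ray parity: voxels whose centre lies inside any of
#' the (closed) meshes get `bone_hu`, all others `background_hu`.
#'
#' @param meshes A `frac_mesh`, `fragment_set`, or list of meshes.
#' @param spacing Voxel spacing, mm (scalar or length 3).
#' @param bone_hu,background_hu Intensity values (default 700 / 0).
#' @param margin Padding around the joint bounding box, mm.
#' @return A `frac_volume`.
#' @export
voxelize <- function(meshes, spacing = 1, bone_hu = 700, background_hu = 0,
                     margin = 3) {
  if (inherits(meshes, "frac_mesh")) meshes <- list(meshes)
  if (inherits(meshes, "fragment_set")) meshes <- meshes$meshes
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(spacing <= 0)) .stop_invalid("spacing must be positive")
  if (length(meshes) == 0 || all(vapply(meshes, function(m) nrow(m$vertices), 0) == 0)) {
    dims <- c(8L, 8L, 8L)
    return(voxel_volume(array(background_hu, dims), spacing, c(0, 0, 0)))
  }
  allv <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  lo <- apply(allv, 2, min) - margin
  hi <- apply(allv, 2, max) + margin
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  occ <- array(FALSE, dims)
  for (m in meshes) {
    occ <- occ | .voxelize_mesh(m$vertices, m$faces, lo, spacing, dims)
  }
  voxel_volume(array(ifelse(occ, bone_hu, background_hu), dims), spacing, lo)
}

#' Synthetic two-or-more-rater measurement table
#'
#' Emulates independent observers re-measuring the same subjects:
#' `value[i, j] = true_values[i] + rater_bias[j] + N(0, rater_noise_sd)`.
#'
#' @param true_values Per-subject true values.
#' @param rater_bias Per-rater systematic bias (length = number of raters).
#' @param rater_noise_sd Measurement noise SD (>= 0).
#' @param seed Optional RNG seed for reproducibility.
#' @return n x k numeric matrix with columns `rater_1`, ...
#' @export
make_rater_table <- function(true_values, rater_bias = c(0, 0),
                             rater_noise_sd = 0, seed = NULL) {
  if (rater_noise_sd < 0) .stop_invalid("rater_noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- length(true_values); k <- length(rater_bias)
  m <- outer(as.numeric(true_values), rep(1, k)) +
    outer(rep(1, n), as.numeric(rater_bias)) +
    matrix(rnorm(n * k, 0, rater_noise_sd), n, k)
  colnames(m) <- paste0("rater_", seq_len(k))
  m
}

#' @export
print.frac_phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d fragment(s), radius %.1f mm, thickness %.1f mm\n",
              length(x$pre$meshes), x$params$radius %||% NA,
              x$params$thickness %||% NA))
  invisible(x)
}
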