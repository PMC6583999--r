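# Fracture lines along articular fragment edges, per-point displacement
# profiles (3D step-off / gap), summaries, and a 2D CT-slice measurement
# emulator for the underestimation comparison.

#' Spherical articular region
#'
#' The articular surface modelled as a band around a sphere (the acetabular
#' cup). Faces belong to the region when their centroid lies within `band` mm
#' of the sphere and their normal is near-radial; the articular normal at a
#' point is the radial direction towards the centre (outward from bone into
#' the joint space).
#'
#' @param centre Sphere centre (mm).
#' @param radius Articular radius (mm).
#' @param band Half-width of the band, mm (default 2.5).
#' @return An `articular_region` object.
#' @export
articular_sphere <- function(centre, radius, band = 2.5) {
  structure(list(type = "sphere", centre = drop(.as_pts(centre)),
                 radius = radius, band = band), class = "articular_region")
}

#' Planar articular region
#'
#' A flat articular facet (used by the flat-patch phantom for exact
#' decomposition checks).
#'
#' @param point Point on the facet plane (mm).
#' @param normal Outward articular normal.
#' @param band Half-width of the band, mm.
#' @return An `articular_region` object.
#' @export
articular_plane <- function(point, normal, band = 2.5) {
  structure(list(type = "plane", plane = frac_plane(point, normal),
                 band = band), class = "articular_region")
}

#' Articular surface normal at points
#' @param region An `articular_region`.
#' @param pts n x 3 points (mm).
#' @return n x 3 unit normals.
#' @export
region_normal <- function(region, pts) {
  pts <- .as_pts(pts)
  if (region$type == "sphere") {
    .unit(matrix(region$centre, nrow(pts), 3, byrow = TRUE) - pts)
  } else {
    matrix(region$plane$normal, nrow(pts), 3, byrow = TRUE)
  }
}

#' Distance of points to the articular surface
#' @param region An `articular_region`.
#' @param pts n x 3 points.
#' @return Unsigned distances (mm).
#' @export
region_distance <- function(region, pts) {
  pts <- .as_pts(pts)
  if (region$type == "sphere") {
    abs(euclidean_distance(pts, region$centre) - region$radius)
  } else {
    abs(plane_distance(region$plane, pts))
  }
}

.region_faces <- function(region, mesh, max_normal_angle = 40) {
  fn <- face_normals(mesh)
  within <- region_distance(region, fn$centroids) <= region$band
  nr <- region_normal(region, fn$centroids)
  align <- abs(rowSums(fn$normals * nr)) >= cos(max_normal_angle * pi / 180)
  within & align
}

#' Submesh of a fragment's articular surface
#' @param mesh A `frac_mesh`.
#' @param region An `articular_region`.
#' @return A `frac_mesh` restricted to articular faces (possibly empty).
#' @export
articular_submesh <- function(mesh, region) {
  keep <- .region_faces(region, mesh)
  m <- mesh
  m$faces <- mesh$faces[keep, , drop = FALSE]
  m
}

#' Fit the articular sphere of a cup template
#'
#' Algebraic sphere fit to all vertices, then iteratively refit on the inner
#' distance cluster so the articular (concave) radius is recovered rather
#' than a compromise between inner and outer shell surfaces.
#'
#' @param template Cup `frac_mesh` (e.g. the mirrored intact template).
#' @param band Band half-width for the returned region, mm.
#' @return An `articular_region` (sphere).
#' @export
fit_articular <- function(template, band = 2.5) {
  p <- template$vertices
  fit_once <- function(p) {
    A <- cbind(2 * p, 1)
    b <- rowSums(p^2)
    x <- solve(crossprod(A), crossprod(A, b))
    ctr <- x[1:3]
    r <- sqrt(x[4] + sum(ctr^2))
    list(centre = ctr, radius = r)
  }
  f <- fit_once(p)
  for (i in 1:3) {
    d <- euclidean_distance(p, f$centre)
    thr <- (stats::quantile(d, 0.05) + stats::quantile(d, 0.95)) / 2
    inner <- p[d <= thr, , drop = FALSE]
    if (nrow(inner) < 10) break
    f <- fit_once(inner)
  }
  articular_sphere(f$centre, f$radius, band)
}

.chain_edges <- function(edges) {
  # order boundary edges into polylines (vertex index paths)
  if (nrow(edges) == 0) return(list())
  verts <- sort(unique(as.vector(edges)))
  adj <- new.env(hash = TRUE)
  for (i in seq_len(nrow(edges))) {
    a <- as.character(edges[i, 1]); b <- as.character(edges[i, 2])
    assign(a, c(get0(a, adj, ifnotfound = integer()), edges[i, 2]), adj)
    assign(b, c(get0(b, adj, ifnotfound = integer()), edges[i, 1]), adj)
  }
  visited_edge <- new.env(hash = TRUE)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  deg <- vapply(verts, function(v) length(get0(as.character(v), adj)), 0L)
  paths <- list()
  walk <- function(start) {
    path <- start
    repeat {
      cur <- path[length(path)]
      nbrs <- get0(as.character(cur), adj, ifnotfound = integer())
      nxt <- NA_integer_
      for (nb in nbrs) {
        if (is.null(get0(ekey(cur, nb), visited_edge))) { nxt <- nb; break }
      }
      if (is.na(nxt)) break
      assign(ekey(cur, nxt), TRUE, visited_edge)
      path <- c(path, nxt)
    }
    path
  }
  for (v in verts[deg == 1]) {
    p <- walk(v)
    if (length(p) >= 2) paths[[length(paths) + 1]] <- p
  }
  for (v in verts) { # remaining cycles
    nbrs <- get0(as.character(v), adj, ifnotfound = integer())
    if (any(vapply(nbrs, function(nb) is.null(get0(ekey(v, nb), visited_edge)), TRUE))) {
      p <- walk(v)
      if (length(p) >= 2) paths[[length(paths) + 1]] <- p
    }
  }
  paths
}

#' Resample a polyline at uniform arc length
#' @param pts Ordered n x 3 polyline points.
#' @param step Maximum spacing, mm.
#' @return Resampled m x 3 matrix (consecutive spacing <= `step`).
#' @export
resample_polyline <- function(pts, step = 0.5) {
  pts <- .as_pts(pts)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L == 0) return(pts[1, , drop = FALSE])
  n <- max(2L, ceiling(L / step) + 1L)
  si <- seq(0, L, length.out = n)
  cbind(stats::approx(s, pts[, 1], si)$y,
        stats::approx(s, pts[, 2], si)$y,
        stats::approx(s, pts[, 3], si)$y)
}

#' Extract fracture lines along articular fragment edges
#'
#' Fragments must be in reduced pose. For each fragment the articular
#' submesh is taken, its boundary edges are chained into polylines, edges
#' lying on the template's natural articular perimeter (the acetabular rim)
#' are removed, and the remaining curves are resampled at `resample_step`.
#' Each line is assigned to the nearest other fragment within
#' `adjacency_tol` (interior line) or to none (peripheral edge).
#'
#' @param fragments A `fragment_set` in reduced pose.
#' @param region An `articular_region` (e.g. from [fit_articular()]).
#' @param template Optional template `frac_mesh` whose articular perimeter is
#'   excluded from the fracture lines (recommended; without it rim edges are
#'   kept).
#' @param resample_step Resampling step, mm (default 0.5).
#' @param adjacency_tol Interior-line adjacency tolerance, mm (default 2).
#' @param rim_tol Distance below which a boundary edge counts as rim, mm.
#' @param min_length Minimum line length kept, mm.
#' @return A tibble: `line_id`, `fragment_id`, `adjacent_fragment_id` (NA for
#'   peripheral lines), `articular`, `length_mm`, `points` (list of matrices).
#' @export
extract_fracture_lines <- function(fragments, region, template = NULL,
                                   resample_step = 0.5, adjacency_tol = 2,
                                   rim_tol = 1.5, min_length = 3) {
  rim_pts <- NULL
  if (!is.null(template)) {
    tsub <- articular_submesh(template, region)
    te <- boundary_edges(tsub)
    if (nrow(te) > 0)
      rim_pts <- (tsub$vertices[te[, 1], , drop = FALSE] +
                  tsub$vertices[te[, 2], , drop = FALSE]) / 2
  }
  art <- lapply(fragments$meshes, articular_submesh, region = region)
  rows <- list()
  for (id in names(fragments$meshes)) {
    sub <- art[[id]]
    if (nrow(sub$faces) == 0) {
      warn(paste0("fragment ", id, " has no articular faces; no fracture line"))
      next
    }
    be <- boundary_edges(sub)
    if (nrow(be) == 0) next
    if (!is.null(rim_pts)) {
      mid <- (sub$vertices[be[, 1], , drop = FALSE] +
              sub$vertices[be[, 2], , drop = FALSE]) / 2
      d <- RANN::nn2(rim_pts, mid, k = 1)$nn.dists[, 1]
      be <- be[d > rim_tol, , drop = FALSE]
    }
    if (nrow(be) == 0) next
    for (path in .chain_edges(be)) {
      pts <- sub$vertices[path, , drop = FALSE]
      L <- sum(sqrt(rowSums(diff(pts)^2)))
      if (L < min_length) next
      rows[[length(rows) + 1]] <- tibble(
        fragment_id = id, length_mm = L,
        points = list(resample_polyline(pts, resample_step)))
    }
  }
  if (length(rows) == 0)
    return(tibble(line_id = character(), fragment_id = character(),
                  adjacent_fragment_id = character(), articular = logical(),
                  length_mm = numeric(), points = list()))
  out <- bind_rows(rows)
  # per-point adjacency: nearest other fragment's articular surface within
  # tolerance; a chained boundary polyline that borders several neighbours
  # (fracture lines meeting at a junction) is split into one line per
  # neighbour run
  art_pts <- lapply(art, function(a) {
    used <- unique(as.vector(a$faces))
    a$vertices[used, , drop = FALSE]
  })
  split_rows <- list()
  for (i in seq_len(nrow(out))) {
    own <- out$fragment_id[i]
    others <- setdiff(names(fragments$meshes), own)
    pts <- out$points[[i]]
    if (length(others) == 0) {
      nearest <- rep(NA_character_, nrow(pts))
    } else {
      dmat <- vapply(others, function(o) {
        if (nrow(art_pts[[o]]) == 0) return(rep(Inf, nrow(pts)))
        RANN::nn2(art_pts[[o]], pts, k = 1)$nn.dists[, 1]
      }, numeric(nrow(pts)))
      dmat <- matrix(dmat, nrow = nrow(pts))
      best <- max.col(-dmat)
      nearest <- ifelse(dmat[cbind(seq_len(nrow(pts)), best)] <= adjacency_tol,
                        others[best], NA_character_)
    }
    same <- function(a, b) (is.na(a) & is.na(b)) |
      (!is.na(a) & !is.na(b) & a == b)
    run <- cumsum(c(TRUE, !same(nearest[-1], nearest[-length(nearest)])))
    for (r in unique(run)) {
      sel <- which(run == r)
      if (length(sel) < 2) next
      p <- pts[sel, , drop = FALSE]
      L <- sum(sqrt(rowSums(diff(p)^2)))
      if (L < min_length) next
      split_rows[[length(split_rows) + 1]] <- tibble(
        fragment_id = own, adjacent_fragment_id = nearest[sel[1]],
        articular = TRUE, length_mm = L, points = list(p))
    }
  }
  if (length(split_rows) == 0)
    return(tibble(line_id = character(), fragment_id = character(),
                  adjacent_fragment_id = character(), articular = logical(),
                  length_mm = numeric(), points = list()))
  out <- bind_rows(split_rows)
  out$line_id <- paste0("line_", seq_len(nrow(out)))
  out[, c("line_id", "fragment_id", "adjacent_fragment_id", "articular",
          "length_mm", "points")]
}

.measured_lines <- function(lines) {
  # interior lines measured once per unordered fragment pair: the smaller
  # fragment id owns the pair's lines, unless only the larger id produced any
  keep <- rep(TRUE, nrow(lines))
  interior <- !is.na(lines$adjacent_fragment_id)
  if (any(interior)) {
    pair <- ifelse(interior,
                   paste(pmin(lines$fragment_id, lines$adjacent_fragment_id),
                         pmax(lines$fragment_id, lines$adjacent_fragment_id)),
                   NA_character_)
    for (pk in unique(pair[interior])) {
      sel <- which(!is.na(pair) & pair == pk)
      owner <- min(lines$fragment_id[sel])
      keep[sel] <- lines$fragment_id[sel] == owner
    }
  }
  lines[keep, , drop = FALSE]
}

#' Per-point displacement profile of fracture lines
#'
#' Correspondence is transform-based: a reduced-pose line point `p` sits at
#' `T_own(p)` in the displaced state, where `T_own` is the inverse of the
#' fragment's reduction transform. Interior lines measure the relative
#' inter-fragment displacement `T_own(p) - T_adj(p)`; peripheral lines
#' measure `T_own(p) - p` against the reduced reference. The displacement is
#' decomposed against the articular normal of the reduced template at `p`.
#' Interior lines are measured once per unordered fragment pair.
#'
#' @param lines Fracture-line tibble from [extract_fracture_lines()].
#' @param poses Named list (by fragment id) of `frac_rigid` transforms
#'   mapping reduced pose to displaced pose.
#' @param region The `articular_region` providing template normals.
#' @return A `frac_profile` tibble: one row per line point with the reduced
#'   position (`x`,`y`,`z`), displaced own position (`px`,`py`,`pz`),
#'   displacement (`dx`,`dy`,`dz`), normal (`nx`,`ny`,`nz`), arc length
#'   `s_mm`, and `step_off`, `gap`, `step_signed`, `displacement` (mm).
#' @export
displacement_profile <- function(lines, poses, region) {
  lines <- .measured_lines(lines)
  rows <- list()
  for (i in seq_len(nrow(lines))) {
    own <- lines$fragment_id[i]
    adj <- lines$adjacent_fragment_id[i]
    if (is.null(poses[[own]])) .stop_invalid(paste0("missing pose for ", own))
    p <- lines$points[[i]]
    own_pos <- transform_points(poses[[own]], p)
    ref_pos <- if (!is.na(adj)) {
      if (is.null(poses[[adj]])) .stop_invalid(paste0("missing pose for ", adj))
      transform_points(poses[[adj]], p)
    } else p
    d <- own_pos - ref_pos
    n <- region_normal(region, p)
    dec <- decompose_displacement(d, n)
    seg <- sqrt(rowSums(diff(p)^2))
    rows[[length(rows) + 1]] <- tibble(
      line_id = lines$line_id[i], fragment_id = own,
      adjacent_fragment_id = adj,
      s_mm = c(0, cumsum(seg)),
      x = p[, 1], y = p[, 2], z = p[, 3],
      px = own_pos[, 1], py = own_pos[, 2], pz = own_pos[, 3],
      dx = d[, 1], dy = d[, 2], dz = d[, 3],
      nx = n[, 1], ny = n[, 2], nz = n[, 3],
      step_off = dec$step_off, gap = dec$gap,
      step_signed = dec$step_signed, displacement = dec$displacement)
  }
  if (length(rows) == 0) .stop_invalid("no fracture lines to profile")
  out <- bind_rows(rows)
  class(out) <- c("frac_profile", class(out))
  out
}

#' Summarise a displacement profile
#'
#' Maximum and mean 3D step-off and gap over all resampled line points
#' (uniform arc-length weighting: lines are resampled at a fixed step, so the
#' point-wise mean is the arc-length-weighted mean).
#'
#' @param profile A `frac_profile`.
#' @param state Optional state label (`"pre"`/`"post"`).
#' @return One-row tibble: `max_step_off`, `mean_step_off`, `max_gap`,
#'   `mean_gap` (mm), `n_points`, `n_lines` and `state` if given.
#' @export
summarize_displacement <- function(profile, state = NULL) {
  if (nrow(profile) == 0) .stop_invalid("empty displacement profile")
  out <- tibble(
    max_step_off = max(profile$step_off), mean_step_off = mean(profile$step_off),
    max_gap = max(profile$gap), mean_gap = mean(profile$gap),
    n_points = nrow(profile), n_lines = length(unique(profile$line_id)))
  if (!is.null(state)) out <- mutate(out, state = state, .before = 1)
  out
}

#' Emulated 2D CT-slice measurement
#'
#' Emulates reading the maximum gap and step-off from a stack of 2D CT
#' slices: line points are binned into slices of the given thickness along
#' the axis, each point's 3D step-off and gap component vectors are projected
#' into the slice plane, and the maximum over slices is reported. Because a
#' projection cannot exceed the vector norm, the 2D values never exceed their
#' 3D counterparts.
#'
#' @param profile A `frac_profile`.
#' @param axis `"axial"` (z stack), `"coronal"` (y) or `"sagittal"` (x).
#' @param slice_thickness Slice thickness, mm (default 2).
#' @return One-row tibble: `axis`, `max_step_2d`, `max_gap_2d`, `n_slices`.
#' @export
slice_2d_measurement <- function(profile, axis = c("axial", "coronal", "sagittal"),
                                 slice_thickness = 2) {
  axis <- match.arg(axis)
  if (slice_thickness <= 0) .stop_invalid("slice_thickness must be positive")
  ax <- switch(axis, axial = 3L, coronal = 2L, sagittal = 1L)
  pos <- as.matrix(profile[, c("px", "py", "pz")])[, ax]
  d <- as.matrix(profile[, c("dx", "dy", "dz")])
  n <- as.matrix(profile[, c("nx", "ny", "nz")])
  svec <- profile$step_signed * n
  gvec <- d - svec
  svec[, ax] <- 0 # in-plane projection
  gvec[, ax] <- 0
  step2d <- sqrt(rowSums(svec^2))
  gap2d <- sqrt(rowSums(gvec^2))
  centres <- seq(min(pos) + slice_thickness / 2 - slice_thickness,
                 max(pos) + slice_thickness, by = slice_thickness)
  best_s <- 0; best_g <- 0; nsl <- 0L; hit <- FALSE
  for (z0 in centres) {
    inslice <- abs(pos - z0) <= slice_thickness / 2
    if (!any(inslice)) next
    hit <- TRUE; nsl <- nsl + 1L
    best_s <- max(best_s, max(step2d[inslice]))
    best_g <- max(best_g, max(gap2d[inslice]))
  }
  if (!hit) warn("no fracture-line point intersects any slice")
  tibble(axis = axis, max_step_2d = best_s, max_gap_2d = best_g,
         n_slices = nsl)
}

#' Plot a displacement profile
#'
#' Step-off and gap against arc length, one panel per fracture line.
#'
#' @param object A `frac_profile`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.frac_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("line_id", "s_mm", "step_off", "gap")],
    c("step_off", "gap"), names_to = "metric", values_to = "mm")
  ggplot2::ggplot(long, ggplot2::aes(.data$s_mm, .data$mm,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~line_id, scales = "free_x") +
    ggplot2::labs(x = "arc length along fracture line (mm)",
                  y = "displacement (mm)", colour = NULL)
}
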