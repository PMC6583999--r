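# Triangle surface meshes (mm units) and the mesh operations the pipeline
# needs: cleaning, areas/volumes, normals, sampling, boundary extraction.

#' Triangle surface mesh
#'
#' Vertices are in millimetres; faces are 1-based vertex index triples.
#' Degenerate (zero-area) faces are dropped at construction.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of vertex indices (1-based).
#' @param fragment_id Optional label identifying the fragment.
#' @return A `frac_mesh` object.
#' @export
triangle_mesh <- function(vertices, faces, fragment_id = NULL) {
  vertices <- .as_pts(vertices)
  faces <- as.matrix(faces)
  if (ncol(faces) != 3) .stop_invalid("faces must have 3 columns")
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    .stop_invalid("face indices out of range")
  m <- structure(list(vertices = vertices, faces = faces,
                      fragment_id = fragment_id), class = "frac_mesh")
  drop_degenerate_faces(m)
}

#' @export
print.frac_mesh <- function(x, ...) {
  cat(sprintf("<mesh%s> %d vertices, %d faces, area %.1f mm^2\n",
              if (is.null(x$fragment_id)) "" else paste0(" ", x$fragment_id),
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

.face_cross <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Remove zero-area faces
#' @param mesh A `frac_mesh`.
#' @param tol Area tolerance (mm^2).
#' @return The cleaned mesh.
#' @export
drop_degenerate_faces <- function(mesh, tol = 1e-12) {
  if (nrow(mesh$faces) == 0) return(mesh)
  area2 <- 0.5 * sqrt(rowSums(.face_cross(mesh)^2))
  mesh$faces <- mesh$faces[area2 > tol, , drop = FALSE]
  mesh
}

#' Merge duplicate vertices
#'
#' Vertices closer than `tol` (snapped to a grid of that pitch) are merged and
#' faces reindexed; collapsed faces are dropped.
#'
#' @param mesh A `frac_mesh`.
#' @param tol Merge tolerance in mm (default 1e-6).
#' @return The welded mesh.
#' @export
merge_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  idx <- match(key, key)                 # first occurrence representative
  keep <- sort(unique(idx))
  remap <- match(idx, keep)
  f <- matrix(remap[mesh$faces], ncol = 3)
  ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  triangle_mesh(v[keep, , drop = FALSE], f[ok, , drop = FALSE],
                mesh$fragment_id)
}

#' Total surface area of a mesh
#' @param mesh A `frac_mesh`.
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(0)
  sum(0.5 * sqrt(rowSums(.face_cross(mesh)^2)))
}

#' Enclosed volume of a closed mesh
#' @param mesh A closed, consistently oriented `frac_mesh`.
#' @return Volume in mm^3 (absolute value of the signed divergence sum).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  abs(sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
          a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
          a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6)
}

#' Per-face unit normals and areas
#' @param mesh A `frac_mesh`.
#' @return List with `normals` (m x 3), `areas` (mm^2), `centroids` (m x 3).
#' @export
face_normals <- function(mesh) {
  cr <- .face_cross(mesh)
  nn <- sqrt(rowSums(cr^2))
  v <- mesh$vertices; f <- mesh$faces
  centroids <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
                v[f[, 3], , drop = FALSE]) / 3
  list(normals = cr / pmax(nn, 1e-300), areas = nn / 2, centroids = centroids)
}

#' Area-weighted vertex normals
#' @param mesh A `frac_mesh`.
#' @return n x 3 matrix of unit normals (zero rows for unused vertices).
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)
  w <- fn$normals * fn$areas
  out <- matrix(0, nrow(mesh$vertices), 3)
  for (k in 1:3) {
    for (cc in 1:3)
      out[, cc] <- out[, cc] +
        unname(tapply(w[, cc], factor(mesh$faces[, k], levels = seq_len(nrow(mesh$vertices))),
                      sum, default = 0))
  }
  n <- sqrt(rowSums(out^2))
  out / pmax(n, 1e-300)
}

#' Apply a spatial transform to a mesh
#' @param mesh A `frac_mesh`.
#' @param transform A `frac_transform`.
#' @return The transformed mesh. Reflections flip face orientation to keep
#'   outward normals outward.
#' @export
transform_mesh <- function(mesh, transform) {
  mesh$vertices <- transform_points(transform, mesh$vertices)
  if (transform$kind == "reflection")
    mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

#' Uniform surface point sample
#'
#' Area-weighted triangle choice with uniform barycentric placement.
#'
#' @param mesh A `frac_mesh`.
#' @param n Number of points.
#' @return n x 3 matrix of points on the surface (mm). Uses the current RNG
#'   stream; seed control belongs to the caller.
#' @export
sample_surface <- function(mesh, n = 5000) {
  fn <- face_normals(mesh)
  if (nrow(mesh$faces) == 0) .stop_invalid("cannot sample an empty mesh")
  idx <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = fn$areas)
  r1 <- sqrt(runif(n)); r2 <- runif(n)
  w0 <- 1 - r1; w1 <- r1 * (1 - r2); w2 <- r1 * r2
  v <- mesh$vertices; f <- mesh$faces[idx, , drop = FALSE]
  w0 * v[f[, 1], , drop = FALSE] + w1 * v[f[, 2], , drop = FALSE] +
    w2 * v[f[, 3], , drop = FALSE]
}

#' Boundary edges of a mesh
#'
#' Edges referenced by exactly one face; empty for a closed surface.
#'
#' @param mesh A `frac_mesh`.
#' @return Two-column integer matrix of vertex index pairs.
#' @export
boundary_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  once <- names(tab)[tab == 1]
  e[key %in% once, , drop = FALSE]
}

#' Combine meshes into one
#' @param meshes List of `frac_mesh` objects.
#' @param fragment_id Label for the combined mesh.
#' @return A single `frac_mesh`.
#' @export
merge_meshes <- function(meshes, fragment_id = NULL) {
  off <- 0L
  vs <- list(); fs <- list()
  for (m in meshes) {
    vs[[length(vs) + 1]] <- m$vertices
    fs[[length(fs) + 1]] <- m$faces + off
    off <- off + nrow(m$vertices)
  }
  triangle_mesh(do.call(rbind, vs), do.call(rbind, fs), fragment_id)
}

#' Set of fracture fragments
#'
#' @param meshes List of `frac_mesh` objects with distinct `fragment_id`s.
#' @param source One of `"pre"`, `"post"`, `"intact"`.
#' @return A `fragment_set`.
#' @export
fragment_set <- function(meshes, source = c("pre", "post", "intact")) {
  source <- match.arg(source)
  ids <- vapply(meshes, function(m) as.character(m$fragment_id %||% ""), "")
  if (any(ids == "") || anyDuplicated(ids))
    .stop_invalid("every fragment needs a unique fragment_id")
  if (any(vapply(meshes, function(m) nrow(m$vertices) == 0, TRUE)))
    .stop_invalid("empty fragment mesh")
  structure(list(meshes = setNames(meshes, ids), source = source),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment set, %s> %d fragments: %s\n", x$source,
              length(x$meshes), paste(names(x$meshes), collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
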