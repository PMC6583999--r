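# Readers and writers: STL (ASCII + binary), PLY (ASCII), NIfTI volumes,
# JSON landmarks and fracture lines, JSON/CSV measurement reports.
# STL and PLY carry no unit metadata; coordinates are taken to be millimetres.

.required_landmarks <- c("aiis", "foramen_inferolateral", "ramus_superior_prominence")

#' Read a triangle mesh (STL or PLY)
#'
#' Binary and ASCII STL are auto-detected. Duplicate vertices are merged
#' within `merge_tol` and degenerate faces dropped. STL/PLY files carry no
#' units; coordinates are interpreted as millimetres.
#'
#' @param path File path.
#' @param format `"auto"`, `"stl"` or `"ply"`.
#' @param fragment_id Optional fragment label; defaults to the file stem.
#' @param merge_tol Vertex merge tolerance, mm.
#' @return A `frac_mesh`.
#' @export
read_mesh <- function(path, format = c("auto", "stl", "ply"),
                      fragment_id = NULL, merge_tol = 1e-6) {
  format <- match.arg(format)
  if (!file.exists(path)) .stop_format(paste0("no such file: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("stl", "ply")) ext else
      .stop_format(paste0("cannot infer mesh format from extension: ", path))
  }
  fragment_id <- fragment_id %||% tools::file_path_sans_ext(basename(path))
  mesh <- if (format == "stl") .read_stl(path) else .read_ply(path)
  mesh$fragment_id <- fragment_id
  mesh <- merge_vertices(mesh, merge_tol)
  if (nrow(mesh$vertices) == 0) .stop_format(paste0("empty mesh: ", path))
  mesh
}

#' @noRd
.read_stl <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  hdr <- readBin(con, "raw", min(84, sz))
  binary <- FALSE
  if (sz >= 84) {
    ntri <- readBin(hdr[81:84], "integer", 1, size = 4, endian = "little")
    binary <- sz == 84 + 50 * as.numeric(ntri)
  }
  if (binary) {
    ntri <- readBin(hdr[81:84], "integer", 1, size = 4, endian = "little")
    raw <- readBin(con, "raw", 50 * ntri)
    close(con)
    m <- matrix(raw, nrow = 50)
    tri <- vapply(seq_len(ntri), function(i)
      readBin(m[1:48, i], "numeric", 12, size = 4, endian = "little"),
      numeric(12))
    tri <- t(tri) # ntri x 12: normal, v1, v2, v3
    verts <- rbind(tri[, 4:6, drop = FALSE], tri[, 7:9, drop = FALSE],
                   tri[, 10:12, drop = FALSE])
    ord <- as.vector(t(matrix(seq_len(3 * ntri), ntri, 3)))
    verts <- verts[ord, , drop = FALSE]
    faces <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
    return(triangle_mesh(verts, faces))
  }
  close(con)
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    .stop_format(paste0("corrupt ASCII STL (", length(vl), " vertex lines): ", path))
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) {
    v <- suppressWarnings(as.numeric(p[2:4]))
    if (any(is.na(v))) .stop_format(paste0("unparseable vertex line in ", path))
    v
  }))
  faces <- matrix(seq_len(nrow(nums)), ncol = 3, byrow = TRUE)
  triangle_mesh(nums, faces)
}

#' @noRd
.read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) == 0 || txt[1] != "ply") .stop_format(paste0("not a PLY file: ", path))
  endh <- match("end_header", txt)
  if (is.na(endh)) .stop_format(paste0("PLY missing end_header: ", path))
  hdr <- txt[seq_len(endh)]
  if (!any(grepl("^format ascii", hdr)))
    .stop_format(paste0("only ASCII PLY supported: ", path))
  nv <- as.integer(sub("element vertex\\s+", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face\\s+", "", grep("^element face", hdr, value = TRUE)))
  if (length(nv) != 1 || length(nf) != 1)
    .stop_format(paste0("PLY must declare vertex and face elements: ", path))
  body <- txt[(endh + 1):length(txt)]
  vrows <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- do.call(rbind, lapply(vrows, function(p) as.numeric(p[1:3])))
  frows <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(frows, function(p) {
    k <- as.integer(p[1])
    if (k != 3) .stop_format("only triangle faces supported in PLY")
    as.integer(p[2:4]) + 1L
  }))
  triangle_mesh(verts, faces)
}

#' Write a triangle mesh
#'
#' @param mesh A `frac_mesh`.
#' @param path Output path.
#' @param format `"auto"` (from extension), `"stl"` or `"ply"`.
#' @param binary Write binary STL (ignored for PLY).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "ply"),
                       binary = FALSE) {
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  if (format == "stl") {
    fn <- face_normals(mesh)$normals
    if (binary) {
      con <- file(path, "wb"); on.exit(close(con))
      writeBin(raw(80), con)
      writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
      for (i in seq_len(nrow(f))) {
        writeBin(as.numeric(c(fn[i, ], t(v[f[i, ], ]))), con, size = 4,
                 endian = "little")
        writeBin(as.integer(0), con, size = 2, endian = "little")
      }
    } else {
      out <- c("solid acefrac",
               unlist(lapply(seq_len(nrow(f)), function(i) c(
                 sprintf("  facet normal %.9g %.9g %.9g", fn[i, 1], fn[i, 2], fn[i, 3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g",
                         v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
                 "    endloop", "  endfacet"))),
               "endsolid acefrac")
      writeLines(out, path)
    }
  } else if (format == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(v)),
             "property float x", "property float y", "property float z",
             paste("element face", nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    writeLines(c(hdr,
                 sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
                 sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)),
               path)
  } else .stop_format(paste0("unknown mesh format: ", format))
  invisible(path)
}

#' Voxel volume in Hounsfield-like units
#'
#' @param data 3D numeric array.
#' @param spacing Voxel spacing, mm (length 3).
#' @param origin World position of voxel (1,1,1) centre, mm.
#' @return A `frac_volume`.
#' @export
voxel_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3) .stop_format("volume must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    .stop_invalid("spacing must be 3 positive values (mm)")
  if (spacing[3] > 2)
    warn(sprintf("slice thickness %.3g mm exceeds 2 mm", spacing[3]))
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "frac_volume")
}

#' @export
print.frac_volume <- function(x, ...) {
  cat(sprintf("<volume> %s voxels, spacing (%.3g, %.3g, %.3g) mm\n",
              paste(dim(x$data), collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' World coordinates of voxel indices
#' @param volume A `frac_volume`.
#' @param ijk n x 3 matrix of 1-based voxel indices.
#' @return n x 3 world coordinates (mm).
#' @export
voxel_to_world <- function(volume, ijk) {
  ijk <- .as_pts(ijk)
  sweep(sweep(ijk - 1, 2, volume$spacing, "*"), 2, volume$origin, "+")
}

#' Read a NIfTI volume
#'
#' Accepts 3D scalar volumes only. Spacing is taken from the NIfTI header;
#' the world origin from the affine translation.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @return A `frac_volume` (axis-aligned world frame, mm).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3) .stop_format(sprintf("expected a 3D volume, got %dD", length(d)))
  pix <- RNifti::pixdim(img)
  aff <- RNifti::xform(img)
  voxel_volume(array(as.numeric(img), dim = d), spacing = pix[1:3],
               origin = aff[1:3, 4])
}

#' Write a volume to NIfTI
#' @param volume A `frac_volume`.
#' @param path Output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  aff <- diag(4)
  diag(aff)[1:3] <- volume$spacing
  aff[1:3, 4] <- volume$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Named anatomical landmarks
#'
#' Requires the three landmarks defining the standardized acetabular view:
#' the anterior inferior iliac spine (`aiis`), the lowest/most lateral point
#' of the obturator foramen (`foramen_inferolateral`) and the most prominent
#' point of the superior pubic ramus (`ramus_superior_prominence`).
#'
#' @param points Named list or named n x 3 matrix of points (mm).
#' @return A `landmark_set` (named list of length-3 numeric vectors).
#' @export
landmark_set <- function(points) {
  if (is.matrix(points))
    points <- setNames(lapply(seq_len(nrow(points)), function(i) points[i, ]),
                       rownames(points))
  missing <- setdiff(.required_landmarks, names(points))
  if (length(missing) > 0)
    .stop_schema(paste0("missing required landmark(s): ",
                        paste(missing, collapse = ", ")))
  points <- lapply(points, function(p) drop(.as_pts(p)))
  pm <- do.call(rbind, points[.required_landmarks])
  d <- as.matrix(stats::dist(pm))
  if (min(d[upper.tri(d)]) <= 5)
    .stop_schema("required landmarks must be more than 5 mm apart")
  structure(points, class = "landmark_set")
}

#' Read landmarks from JSON
#'
#' Expected schema: `{"units":"mm","space":"LPS","points":{"aiis":[x,y,z],...}}`.
#' Units other than mm (or a missing units field) are refused.
#'
#' @param path JSON file.
#' @return A `landmark_set`.
#' @export
read_landmarks <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$units, "mm"))
    .stop_schema("landmark file must declare units: \"mm\"")
  if (is.null(doc$points)) .stop_schema("landmark file has no \"points\" field")
  landmark_set(lapply(doc$points, as.numeric))
}

#' Write landmarks to JSON
#' @param landmarks A `landmark_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(list(units = "mm", space = "LPS",
                            points = lapply(unclass(landmarks), as.numeric)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read fracture-line polylines from JSON
#'
#' Each line: `{"fragment_id": "...", "adjacent_fragment_id": "..."|null,
#' "articular": true, "points": [[x,y,z],...]}` with a top-level
#' `units: "mm"` header.
#'
#' @param path JSON file.
#' @return A fracture-line tibble (see [extract_fracture_lines()]).
#' @export
read_fracture_lines <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$units, "mm"))
    .stop_schema("fracture-line file must declare units: \"mm\"")
  lines <- doc$lines
  if (is.null(lines)) .stop_schema("fracture-line file has no \"lines\" field")
  tibble(
    line_id = vapply(seq_along(lines), function(i)
      lines[[i]]$line_id %||% paste0("line_", i), ""),
    fragment_id = vapply(lines, function(l) l$fragment_id %||%
                           .stop_schema("line missing fragment_id"), ""),
    adjacent_fragment_id = vapply(lines, function(l)
      if (is.null(l$adjacent_fragment_id)) NA_character_
      else l$adjacent_fragment_id, ""),
    articular = vapply(lines, function(l) isTRUE(l$articular %||% TRUE), TRUE),
    points = lapply(lines, function(l) {
      p <- do.call(rbind, lapply(l$points, as.numeric))
      if (is.null(p) || nrow(p) < 2)
        .stop_schema("each fracture line needs at least 2 points")
      p
    })
  )
}

#' Write fracture lines to JSON
#' @param lines Fracture-line tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fracture_lines <- function(lines, path) {
  out <- lapply(seq_len(nrow(lines)), function(i) list(
    line_id = lines$line_id[i],
    fragment_id = lines$fragment_id[i],
    adjacent_fragment_id = if (is.na(lines$adjacent_fragment_id[i])) NULL
                           else lines$adjacent_fragment_id[i],
    articular = lines$articular[i],
    points = apply(lines$points[[i]], 1, as.numeric, simplify = FALSE)))
  jsonlite::write_json(list(units = "mm", space = "LPS", lines = out), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a measurement report to JSON (and optionally CSV)
#'
#' @param report A `frac_report` from [run_pipeline()] / [analyze_fracture()].
#' @param path JSON output path.
#' @param csv_path Optional CSV path: one row per (state, metric) plus the
#'   grading and reduction rows.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, csv_path = NULL) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  if (!is.null(csv_path)) {
    long <- report_table(report)
    utils::write.csv(long, csv_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON measurement report
#' @param path JSON report path.
#' @return A `frac_report` list.
#' @export
read_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "frac_report")
}

#' Long-format table of a measurement report
#' @param report A `frac_report`.
#' @return A tibble with columns `state`, `metric`, `value`.
#' @export
report_table <- function(report) {
  rows <- list()
  for (state in intersect(c("pre", "post"), names(report$summaries))) {
    s <- report$summaries[[state]]
    for (m in c("max_step_off", "mean_step_off", "max_gap", "mean_gap"))
      rows[[length(rows) + 1]] <- tibble(state = state, metric = m,
                                         value = as.numeric(s[[m]]))
    rows[[length(rows) + 1]] <- tibble(state = state, metric = "total_gap_area",
                                       value = as.numeric(report$gap_area[[state]]))
  }
  if (!is.null(report$reduction_pct)) {
    for (m in names(report$reduction_pct))
      rows[[length(rows) + 1]] <- tibble(state = "post", metric = paste0("residual_pct_", m),
                                         value = as.numeric(report$reduction_pct[[m]]))
  }
  bind_rows(rows)
}
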