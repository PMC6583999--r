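# Total gap area: orthographic projection of the displaced fracture-line
# pairs onto the standardized landmark-defined plane; area of the union of
# the ribbons between each line's two displaced copies.

#' Standardized acetabular view from landmarks
#'
#' The plane through the anterior inferior iliac spine, the inferolateral
#' foramen point and the superior ramus prominence; the view direction is
#' the plane normal oriented away from the pelvic midline (lateral view,
#' looking into the cup).
#'
#' @param landmarks A `landmark_set` with the three required landmarks.
#' @param midline_hint A point on the pelvic midline (mm), used only to
#'   orient the normal.
#' @return A `frac_view`: `plane`, plus in-plane basis vectors `e1`, `e2`
#'   (right-handed with the normal).
#' @export
standard_view <- function(landmarks, midline_hint = c(0, 0, 0)) {
  lm <- lapply(.required_landmarks, function(nm) landmarks[[nm]])
  pl <- plane_from_points(lm[[1]], lm[[2]], lm[[3]])
  centroid <- colMeans(do.call(rbind, lm))
  outward <- centroid - drop(.as_pts(midline_hint))
  if (sum(pl$normal * outward) < 0)
    pl <- frac_plane(pl$point, -pl$normal)
  e1 <- drop(.unit(lm[[2]] - lm[[1]]))
  e1 <- drop(.unit(e1 - sum(e1 * pl$normal) * pl$normal))
  e2 <- .cross3(pl$normal, e1)
  structure(list(plane = pl, e1 = e1, e2 = e2), class = "frac_view")
}

#' Orthographic projection of points into a view
#' @param view A `frac_view`.
#' @param pts n x 3 points (mm).
#' @return n x 2 in-plane coordinates (mm).
#' @export
project_to_view <- function(view, pts) {
  pts <- .as_pts(pts)
  rel <- sweep(pts, 2, view$plane$point)
  cbind(rel %*% view$e1, rel %*% view$e2)
}

.poly_area_signed <- function(p) {
  n <- length(p$x)
  0.5 * sum(p$x * c(p$y[-1], p$y[1]) - c(p$x[-1], p$x[1]) * p$y)
}

.union_area <- function(polys) {
  if (length(polys) == 0) return(0)
  acc <- polyclip::polysimplify(polys[1], filltype = "nonzero")
  if (length(polys) > 1)
    for (i in 2:length(polys)) {
      cleaned <- polyclip::polysimplify(polys[i], filltype = "nonzero")
      acc <- polyclip::polyclip(acc, cleaned, op = "union",
                                fillA = "nonzero", fillB = "nonzero")
    }
  sum(vapply(acc, .poly_area_signed, 0))
}

.raster_area <- function(polys, step) {
  if (length(polys) == 0) return(0)
  xs <- unlist(lapply(polys, `[[`, "x")); ys <- unlist(lapply(polys, `[[`, "y"))
  gx <- seq(min(xs) - step, max(xs) + step, by = step)
  gy <- seq(min(ys) - step, max(ys) + step, by = step)
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  inside <- rep(FALSE, nrow(grid))
  for (p in polys) {
    # even-odd point-in-polygon
    nv <- length(p$x)
    cx <- p$x; cy <- p$y
    wn <- rep(0L, nrow(grid))
    j <- nv
    for (i in seq_len(nv)) {
      crosses <- ((cy[i] > grid[, 2]) != (cy[j] > grid[, 2]))
      xint <- (cx[j] - cx[i]) * (grid[, 2] - cy[i]) / (cy[j] - cy[i]) + cx[i]
      wn <- wn + as.integer(crosses & (grid[, 1] < xint))
      j <- i
    }
    inside <- inside | (wn %% 2L == 1L)
  }
  sum(inside) * step^2
}

.ribbon_polys <- function(lines, poses, view, include_peripheral) {
  lines <- .measured_lines(lines)
  polys <- list()
  for (i in seq_len(nrow(lines))) {
    own <- lines$fragment_id[i]
    adj <- lines$adjacent_fragment_id[i]
    if (is.na(adj) && !include_peripheral) next
    p <- lines$points[[i]]
    a <- transform_points(poses[[own]], p)
    b <- if (!is.na(adj)) transform_points(poses[[adj]], p) else p
    pa <- project_to_view(view, a)
    pb <- project_to_view(view, b)
    ring <- rbind(pa, pb[nrow(pb):1, , drop = FALSE])
    if (max(abs(pa - pb)) < 1e-9) next # coincident copies: zero ribbon
    polys[[length(polys) + 1]] <- list(x = ring[, 1], y = ring[, 2],
                                       line_id = lines$line_id[i])
  }
  polys
}

#' Total gap area in the standardized view
#'
#' Each interior fracture line's two displaced copies (own and adjacent
#' fragment poses applied to the same reduced-pose line) are orthographically
#' projected onto the view plane; the ribbon between them is polygonised and
#' the area of the union of all ribbons is returned, so overlapping ribbons
#' at fracture junctions are counted once. Displacement purely along the view
#' direction (pure step-off) projects to zero width: this is deliberately a
#' gap metric.
#'
#' @param lines Fracture-line tibble (reduced pose).
#' @param poses Named list of reduced -> displaced `frac_rigid` transforms.
#' @param view A `frac_view` from [standard_view()].
#' @param include_peripheral Include peripheral (wall-edge) lines, measured
#'   against the reduced reference (default FALSE: interior lines only).
#' @param method `"polygon"` (exact union) or `"raster"` (grid fallback).
#' @param raster_step Raster cell size, mm (default 0.1).
#' @return A `gap_area_result`: list with `area` (mm^2), `regions` (list of
#'   ribbon polygons, in-plane mm), `method`.
#' @export
total_gap_area <- function(lines, poses, view, include_peripheral = FALSE,
                           method = c("polygon", "raster"), raster_step = 0.1) {
  method <- match.arg(method)
  if (raster_step <= 0) .stop_invalid("raster_step must be positive")
  polys <- .ribbon_polys(lines, poses, view, include_peripheral)
  area <- if (length(polys) == 0) 0
  else if (method == "polygon") {
    tryCatch(.union_area(polys), error = function(e) {
      warn(paste0("polygon union failed (", conditionMessage(e),
                  "); falling back to rasterization"))
      .raster_area(polys, raster_step)
    })
  } else .raster_area(polys, raster_step)
  structure(list(area = area, regions = polys, method = method),
            class = "gap_area_result")
}

#' @export
print.gap_area_result <- function(x, ...) {
  cat(sprintf("<total gap area> %.2f mm^2 (%d ribbon(s), %s method)\n",
              x$area, length(x$regions), x$method))
  invisible(x)
}

#' Plot the projected gap regions
#' @param object A `gap_area_result`.
#' @param ... Ignored.
#' @return A ggplot object (in-plane mm, fixed aspect).
#' @export
autoplot.gap_area_result <- function(object, ...) {
  df <- bind_rows(lapply(object$regions, function(p)
    tibble(x = p$x, y = p$y, line_id = p$line_id)))
  if (nrow(df) == 0) df <- tibble(x = numeric(), y = numeric(), line_id = character())
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$line_id,
                                   fill = .data$line_id)) +
    ggplot2::geom_polygon(alpha = 0.5, colour = "grey30") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "view plane e1 (mm)", y = "view plane e2 (mm)",
                  fill = "fracture line",
                  title = sprintf("total gap area %.1f mm²", object$area))
}
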