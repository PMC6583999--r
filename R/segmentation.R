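# CT-like volume -> per-fragment surface meshes: HU thresholding,
# 26-connected component labelling, iso-surfacing of the binary mask.

#' Threshold a volume at a bone HU value
#'
#' Returns the binary mask `HU >= hu_threshold`. 226 HU is the conventional
#' preset bone threshold of clinical segmentation software.
#'
#' @param volume A `frac_volume`.
#' @param hu_threshold Threshold in HU (default 226).
#' @return Logical 3D array with the volume's dimensions.
#' @export
threshold_bone <- function(volume, hu_threshold = 226) {
  mask <- volume$data >= hu_threshold
  if (!any(mask)) warn("empty segmentation: no voxel reaches the bone threshold")
  mask
}

#' Label fracture fragments in a binary mask
#'
#' 26-connected components, relabelled 1..K by descending voxel count.
#' Components smaller than `min_voxels` are discarded (label 0).
#'
#' @param mask Logical 3D array.
#' @param min_voxels Minimum component size (voxels, default 50).
#' @return Integer array of labels (0 = background).
#' @export
label_fragments <- function(mask, min_voxels = 50) {
  lab <- .label_components_26(as.logical(mask), as.integer(dim(mask)))
  if (max(lab) == 0) return(lab)
  counts <- tabulate(lab)
  keep <- which(counts >= min_voxels)
  ord <- keep[order(counts[keep], decreasing = TRUE)]
  remap <- integer(length(counts))
  remap[ord] <- seq_along(ord)
  out <- array(0L, dim = dim(mask))
  nz <- lab != 0L
  out[nz] <- remap[lab[nz]]
  out
}

#' Taubin (lambda-mu) mesh smoothing
#'
#' Two-step low-pass smoothing that damps high-frequency surface noise (the
#' voxel staircase of a binary iso-surface) with very little volume
#' shrinkage, unlike plain Laplacian smoothing.
#'
#' @param mesh A `frac_mesh`.
#' @param iterations Number of lambda/mu passes (default 40).
#' @param lambda Positive smoothing step (default 0.8).
#' @param mu Negative un-shrinking step (default -0.83).
#' @return The smoothed mesh (same topology).
#' @export
taubin_smooth <- function(mesh, iterations = 40, lambda = 0.8, mu = -0.83) {
  f <- mesh$faces
  if (nrow(f) == 0 || iterations <= 0) return(mesh)
  e <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)],
                    f[, 2:1], f[, 3:2], f[, c(1, 3)]))
  n <- nrow(mesh$vertices)
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1, dims = c(n, n))
  W <- Matrix::Diagonal(x = 1 / pmax(Matrix::rowSums(A), 1)) %*% A
  v <- mesh$vertices
  for (it in seq_len(iterations)) {
    v <- v + lambda * (as.matrix(W %*% v) - v)
    v <- v + mu * (as.matrix(W %*% v) - v)
  }
  mesh$vertices <- v
  mesh
}

#' Extract a surface mesh for one labelled fragment
#'
#' Iso-surface of the fragment occupancy at the 0.5 level (marching
#' tetrahedra), mapped to world millimetres via the volume's spacing and
#' origin, then Taubin-smoothed. The raw binary iso-surface is a voxel
#' staircase whose area overestimates a smooth surface by tens of percent;
#' Taubin smoothing removes that jaggedness while preserving enclosed
#' volume, leaving both area and volume within a few percent of the
#' analytic values for smooth phantoms. Set `smooth_iterations = 0` for the
#' raw staircase surface. The field is padded with background so fragments
#' touching the volume border still close.
#'
#' @param labels Integer label array (from [label_fragments()]) or logical mask.
#' @param label Which label to surface (ignored for logical masks).
#' @param volume The source `frac_volume` (for spacing/origin), or `NULL` to
#'   use index coordinates.
#' @param fragment_id Label for the output mesh.
#' @param smooth_iterations Taubin iterations (default 40).
#' @return A closed `frac_mesh` in world mm.
#' @export
mask_to_mesh <- function(labels, label = 1L, volume = NULL, fragment_id = NULL,
                         smooth_iterations = 40) {
  occ <- if (is.logical(labels)) labels else labels == label
  if (!any(occ)) .stop_invalid(paste0("label ", label, " not present in mask"))
  d <- dim(occ)
  pad <- array(0, d + 4L)
  pad[3:(d[1] + 2), 3:(d[2] + 2), 3:(d[3] + 2)] <- as.numeric(occ)
  surf <- .mt_isosurface(as.numeric(pad), as.integer(dim(pad)), 0.5)
  v <- surf$vertices - 2 # padded grid coordinate -> 0-based voxel index
  if (!is.null(volume)) {
    v <- sweep(sweep(v, 2, volume$spacing, "*"), 2, volume$origin, "+")
  }
  mesh <- merge_vertices(triangle_mesh(v, surf$faces, fragment_id), 1e-9)
  taubin_smooth(mesh, smooth_iterations)
}

#' Segment a volume into fracture fragment meshes
#'
#' Convenience wrapper: threshold, label, mesh each fragment.
#'
#' @param volume A `frac_volume`.
#' @param hu_threshold Bone threshold, HU.
#' @param min_voxels Minimum fragment size, voxels.
#' @param source Provenance tag for the fragment set.
#' @return A `fragment_set`; empty list if nothing segments.
#' @export
segment_fragments <- function(volume, hu_threshold = 226, min_voxels = 50,
                              source = "pre") {
  mask <- threshold_bone(volume, hu_threshold)
  lab <- label_fragments(mask, min_voxels)
  k <- max(lab)
  if (k == 0) .stop_invalid("no fragments above min_voxels")
  meshes <- lapply(seq_len(k), function(i)
    mask_to_mesh(lab, i, volume, fragment_id = paste0("fragment_", i)))
  fragment_set(meshes, source)
}
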