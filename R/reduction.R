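# Virtual anatomical reduction: mirror the intact contralateral side as a
# template and rigidly register each displaced fragment to it (ICP), then
# match preoperative fragments into the postoperative model.

#' Mirror an intact hemipelvis into a reduction template
#'
#' Reflects the intact contralateral mesh across the midsagittal symmetry
#' plane so it overlays the fractured side and can serve as the reduction
#' template.
#'
#' @param intact_mesh Intact contralateral `frac_mesh`.
#' @param symmetry_plane A `frac_plane`; when `NULL`, a least-squares
#'   symmetry plane is fitted to `fit_to` (or to `intact_mesh`).
#' @param fit_to Optional full-pelvis mesh to fit the symmetry plane on.
#' @return The mirrored `frac_mesh` (face orientation corrected).
#' @export
build_mirror_template <- function(intact_mesh, symmetry_plane = NULL,
                                  fit_to = NULL) {
  if (nrow(intact_mesh$vertices) == 0) .stop_invalid("empty intact mesh")
  if (is.null(symmetry_plane))
    symmetry_plane <- fit_symmetry_plane(fit_to %||% intact_mesh)
  out <- transform_mesh(intact_mesh, mirror_transform(symmetry_plane))
  out$fragment_id <- paste0(intact_mesh$fragment_id %||% "intact", "_mirrored")
  out
}

#' Least-squares symmetry plane of a mesh
#'
#' Starts from the centroid and each principal axis, keeps the axis whose
#' reflection best maps the surface onto itself, then refines normal and
#' offset by Nelder-Mead on the mean nearest-neighbour distance between a
#' surface sample and its reflection.
#'
#' @param mesh A `frac_mesh` with approximate bilateral symmetry.
#' @param n_samples Surface sample size.
#' @return A `frac_plane`.
#' @export
fit_symmetry_plane <- function(mesh, n_samples = 2000) {
  pts <- sample_surface(mesh, n_samples)
  ctr <- colMeans(pts)
  pc <- eigen(stats::cov(pts), symmetric = TRUE)$vectors
  score <- function(normal, offset) {
    pl <- frac_plane(ctr + offset * normal, normal)
    refl <- transform_points(mirror_transform(pl), pts)
    mean(RANN::nn2(pts, refl, k = 1)$nn.dists)
  }
  best <- which.min(vapply(1:3, function(i) score(pc[, i], 0), 0))
  n0 <- pc[, best]
  # refine: normal perturbed in its tangent basis + offset along normal
  tb <- pc[, setdiff(1:3, best)]
  obj <- function(par) {
    n <- drop(.unit(n0 + tb %*% par[1:2]))
    score(n, par[3])
  }
  opt <- stats::optim(c(0, 0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-8))
  n <- drop(.unit(n0 + tb %*% opt$par[1:2]))
  frac_plane(ctr + opt$par[3] * n, n)
}

.target_cache <- function(target) {
  list(vertices = target$vertices, normals = vertex_normals(target))
}

.p2pl_step <- function(src, q, nq) {
  # one linearized point-to-plane solve: x = [omega; t]
  cx <- cbind(src[, 2] * nq[, 3] - src[, 3] * nq[, 2],
              src[, 3] * nq[, 1] - src[, 1] * nq[, 3],
              src[, 1] * nq[, 2] - src[, 2] * nq[, 1])
  A <- cbind(cx, nq)
  b <- -rowSums((src - q) * nq)
  x <- tryCatch(solve(crossprod(A), crossprod(A, b)),
                error = function(e) matrix(0, 6, 1))
  w <- x[1:3]; t <- x[4:6]
  th <- sqrt(sum(w^2))
  R <- if (th < 1e-12) diag(3) else {
    a <- w / th
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  rigid_transform(R, t)
}

#' Rigid ICP registration of a point sample onto a target surface
#'
#' Point-to-plane ICP: correspondences are nearest target vertices (with
#' area-weighted vertex normals); each iteration solves the linearized
#' point-to-plane system and composes an exact rigid update. The worst
#' `1 - trim` fraction of correspondences is discarded each iteration, which
#' suppresses the pull of surface regions with no counterpart on the target
#' (fracture surfaces, hardware).
#'
#' @param source A `frac_mesh` or an n x 3 point matrix.
#' @param target Target `frac_mesh`.
#' @param init Initial `frac_rigid` (default identity).
#' @param max_iter Iteration cap.
#' @param tol Stop when trimmed RMS improves by less than this (mm).
#' @param n_samples Number of surface sample points when `source` is a mesh.
#' @param trim Fraction of best correspondences kept (default 1: no
#'   trimming). Lower values suppress the pull of regions with no true
#'   counterpart, at the price of also discarding genuinely misfitting
#'   regions that carry registration signal.
#' @return List: `transform` (`frac_rigid`, source -> target), `rms` (mm,
#'   trimmed point-to-surface RMS), `iterations`, `converged`, `rms_init`.
#' @export
icp_register <- function(source, target, init = rigid_transform(),
                         max_iter = 50, tol = 1e-6, n_samples = 5000,
                         trim = 1) {
  pts <- if (inherits(source, "frac_mesh")) {
    if (nrow(source$vertices) <= n_samples) source$vertices
    else sample_surface(source, n_samples)
  } else .as_pts(source)
  if (nrow(pts) < 3) .stop_invalid("ICP needs at least 3 source points")
  sv <- svd(sweep(pts, 2, colMeans(pts)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) .stop_invalid("ICP source points are collinear")
  tc <- .target_cache(target)

  eval_rms <- function(tf) {
    cur <- transform_points(tf, pts)
    nn <- RANN::nn2(tc$vertices, cur, k = 1)
    q <- tc$vertices[nn$nn.idx[, 1], , drop = FALSE]
    nq <- tc$normals[nn$nn.idx[, 1], , drop = FALSE]
    resid <- abs(rowSums((cur - q) * nq)) # point-to-plane residual
    keep <- order(resid)[seq_len(max(3, floor(trim * length(resid))))]
    list(rms = sqrt(mean(resid[keep]^2)), keep = keep, cur = cur,
         q = q, nq = nq)
  }

  tf <- init
  st <- eval_rms(tf)
  rms_init <- st$rms
  best <- list(tf = tf, rms = st$rms)
  iters <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iters <- it
    inc <- .p2pl_step(st$cur[st$keep, , drop = FALSE],
                      st$q[st$keep, , drop = FALSE],
                      st$nq[st$keep, , drop = FALSE])
    cand <- compose_transforms(inc, tf)
    st2 <- eval_rms(cand)
    if (st2$rms <= best$rms) best <- list(tf = cand, rms = st2$rms)
    if (abs(st$rms - st2$rms) < tol) {
      tf <- cand; st <- st2; converged <- TRUE; break
    }
    tf <- cand; st <- st2
  }
  list(transform = best$tf, rms = best$rms, iterations = iters,
       converged = converged, rms_init = rms_init)
}

.fit_sphere_centre <- function(p) {
  A <- cbind(2 * p, 1)
  x <- solve(crossprod(A), crossprod(A, rowSums(p^2)))
  x[1:3]
}

.cup_axis <- function(template, region) {
  # opening direction of the cup: from the mean articular point towards the
  # sphere centre, negated (the apex lies opposite the opening)
  art <- articular_submesh(template, region)
  used <- unique(as.vector(art$faces))
  if (length(used) < 3) return(NULL)
  drop(.unit(region$centre - colMeans(art$vertices[used, , drop = FALSE])))
}

#' Virtually reduce fracture fragments onto a mirrored template
#'
#' Registers each displaced fragment to the mirrored intact template. A
#' near-hemispherical joint surface makes rotation about the cup axis a
#' weakly constrained mode of surface registration, so each fragment is
#' registered from several initial rotations about the template's cup axis
#' (`multistart_deg`) and the pose with the lowest final RMS wins. A
#' fragment whose post-registration RMS exceeds `rms_max` is flagged
#' unreduced (non-anatomic template fit) rather than silently reported.
#'
#' @param fragments A `fragment_set` in displaced (fractured) pose.
#' @param template Mirrored intact template `frac_mesh`.
#' @param rms_max RMS flag threshold, mm (default 2).
#' @param region Optional `articular_region` of the template (fitted when
#'   omitted); defines the cup centre and axis for the multistart rotations.
#' @param multistart_deg Azimuthal start angles about the cup axis, degrees.
#' @param polish_trim Trim fraction for the final polish: once a fragment
#'   sits close to the template, the worst-fitting residuals belong to its
#'   fracture surfaces (which have no counterpart on the intact template),
#'   and discarding them sharpens the pose estimate.
#' @param ... Passed to [icp_register()].
#' @return A tibble: `fragment_id`, `transform` (list of `frac_rigid`,
#'   displaced -> reduced), `rms`, `rms_init`, `iterations`, `converged`,
#'   `reduced` (logical flag).
#' @export
reduce_fragments <- function(fragments, template, rms_max = 2, region = NULL,
                             multistart_deg = seq(-150, 180, by = 30),
                             polish_trim = 0.9, ...) {
  if (is.null(region)) region <- fit_articular(template)
  axis <- .cup_axis(template, region)
  inits <- list(rigid_transform())
  dots <- list(...)
  n_samples <- dots$n_samples %||% 5000
  dots$n_samples <- NULL
  rows <- lapply(names(fragments$meshes), function(id) {
    mesh <- fragments$meshes[[id]]
    pts <- if (nrow(mesh$vertices) <= n_samples) mesh$vertices
           else sample_surface(mesh, n_samples)
    # one shared sample: candidate RMS values are directly comparable; the
    # exploration phase runs on a subsample for speed
    coarse <- pts[sample.int(nrow(pts), min(1500, nrow(pts))), , drop = FALSE]
    # centring start: move the fragment's own fitted sphere centre onto the
    # template's articular centre, so the azimuthal multistart explores
    # rotation with the radial placement already roughly right
    starts <- inits
    ctr_fit <- tryCatch(.fit_sphere_centre(coarse), error = function(e) NULL)
    if (!is.null(axis)) {
      t0 <- if (is.null(ctr_fit)) rigid_transform()
            else rigid_transform(diag(3), region$centre - ctr_fit)
      for (ang in multistart_deg)
        starts[[length(starts) + 1]] <-
          compose_transforms(rotation_about(axis, ang, region$centre), t0)
    }
    fits <- lapply(starts, function(init)
      do.call(icp_register, c(list(coarse, template, init = init,
                                   max_iter = 15, trim = 1), dots)))
    top <- order(vapply(fits, `[[`, 0, "rms"))[seq_len(min(2, length(fits)))]
    refined <- lapply(fits[top], function(f)
      do.call(icp_register, c(list(pts, template, init = f$transform,
                                   trim = 1), dots)))
    fit <- refined[[which.min(vapply(refined, `[[`, 0, "rms"))]]
    fit2 <- do.call(icp_register,
                    c(list(pts, template, init = fit$transform,
                           trim = polish_trim), dots))
    tibble(fragment_id = id, transform = list(fit2$transform),
           rms = fit2$rms, rms_init = fits[[1]]$rms_init,
           iterations = fit2$iterations, converged = fit2$converged,
           reduced = fit2$rms <= rms_max)
  })
  out <- bind_rows(rows)
  if (any(!out$reduced))
    warn(paste0("fragment(s) flagged unreduced (RMS > ", rms_max, " mm): ",
                paste(out$fragment_id[!out$reduced], collapse = ", ")))
  out
}

#' Match preoperative fragments into the postoperative model
#'
#' Registers each preoperative fragment to the postoperative surface model,
#' initialized from the virtual-reduction transforms (the reduced pose is the
#' natural starting estimate for the surgically reduced position).
#'
#' @param pre_fragments Preoperative `fragment_set` (displaced pose).
#' @param post_model Postoperative `frac_mesh` (whole model).
#' @param init_transforms Named list of `frac_rigid` (displaced -> reduced)
#'   used as initialization, e.g. `reduction$transform` named by fragment.
#' @param rms_max Flag threshold, mm.
#' @param ... Passed to [icp_register()].
#' @return Tibble like [reduce_fragments()], with `matched` instead of
#'   `reduced`; `transform` maps displaced pre pose -> postoperative pose.
#' @export
match_pre_to_post <- function(pre_fragments, post_model,
                              init_transforms = NULL, rms_max = 2, ...) {
  rows <- lapply(names(pre_fragments$meshes), function(id) {
    init <- init_transforms[[id]] %||% rigid_transform()
    fit <- icp_register(pre_fragments$meshes[[id]], post_model, init = init, ...)
    tibble(fragment_id = id, transform = list(fit$transform),
           rms = fit$rms, rms_init = fit$rms_init,
           iterations = fit$iterations, converged = fit$converged,
           matched = fit$rms <= rms_max)
  })
  out <- bind_rows(rows)
  if (any(!out$matched))
    warn(paste0("fragment(s) flagged unmatched (RMS > ", rms_max, " mm): ",
                paste(out$fragment_id[!out$matched], collapse = ", ")))
  out
}

#' Extract the named list of transforms from a reduction table
#' @param reduction Tibble from [reduce_fragments()] or [match_pre_to_post()].
#' @return Named list of `frac_rigid` transforms.
#' @export
reduction_transforms <- function(reduction) {
  setNames(reduction$transform, reduction$fragment_id)
}
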