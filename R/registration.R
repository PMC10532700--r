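#' Hyperparameters for masked rigid registration
#'
#' Defaults follow the coarse whole-pelvis stage; `fine_registration_params()`
#' returns the fragment-stage set (translation scale 1/500, maximum step 0.7,
#' minimum step 1e-4). The scales divide the gradient components inside the
#' optimizer (ITK regular-step convention), so a small translation scale
#' makes millimetre translations move as fast as radian-scale rotations.
#'
#' @param iterations Maximum optimizer iterations.
#' @param translation_scale,rotation_scale Parameter scales.
#' @param max_step,min_step Initial and terminal step lengths.
#' @param sampling Fraction of in-mask voxels used by the metric (a
#'   deterministic stride, so results stay reproducible); 1 = all.
#' @return List of class `registration_params`.
#' @export
registration_params <- function(iterations = 200, translation_scale = 1 / 2000,
                                rotation_scale = 1, max_step = 1,
                                min_step = 0.001, sampling = 1) {
  stopifnot(iterations > 0, max_step > min_step, min_step > 0,
            sampling > 0, sampling <= 1)
  structure(list(iterations = as.integer(iterations),
                 translation_scale = translation_scale,
                 rotation_scale = rotation_scale,
                 max_step = max_step, min_step = min_step,
                 sampling = sampling),
            class = "registration_params")
}

#' @rdname registration_params
#' @param ... Overrides passed on to [registration_params()].
#' @export
fine_registration_params <- function(...) {
  args <- list(translation_scale = 1 / 500, max_step = 0.7, min_step = 1e-4)
  do.call(registration_params, utils::modifyList(args, list(...)))
}

#' Normalized correlation between two volumes under a mask
#'
#' Pearson correlation of the intensities over the in-mask voxels. Both
#' volumes must live on a common grid.
#'
#' @param fixed,moving [volume()]s on the same grid.
#' @param mask A [label_volume()] (non-zero = in mask) on the same grid;
#'   `NULL` uses all voxels.
#' @return Scalar in `[-1, 1]`.
#' @export
normalized_correlation <- function(fixed, moving, mask = NULL) {
  stopifnot(all(vol_shape(fixed) == vol_shape(moving)))
  sel <- if (is.null(mask)) TRUE else mask$values > 0
  f <- fixed$values[sel]
  m <- moving$values[sel]
  if (length(f) == 0) stop("mask is empty")
  if (stats::sd(f) == 0 || stats::sd(m) == 0)
    stop("constant intensities within the mask; correlation is undefined")
  stats::cor(f, m)
}

# metric value for parameter vector p (versor + translation about `center`):
# correlation between fixed values at `pts` and moving sampled at T(p) %*% pts
ncc_objective <- function(p, center, fixed_vals, pts, moving, outside) {
  tr <- rt_from_params(p, center)
  cpp_ncc_metric(fixed_vals, pts, moving$values, moving$spacing,
                 moving$origin, moving$axes, unclass(tr), outside)
}

#' Masked rigid registration
#'
#' Finds the rigid transform mapping fixed-image coordinates into
#' moving-image coordinates that maximizes the normalized correlation
#' between the fixed intensities inside `mask` and the moving intensities
#' sampled at the transformed positions. The optimizer is a regular-step
#' gradient descent on a versor + translation parameterization (rotation
#' center = mask centroid): the gradient (central finite differences) is
#' divided by the parameter scales, steps move along the normalized scaled
#' gradient, the step length starts at `max_step` and is halved whenever
#' the gradient direction reverses, and iteration stops at `min_step` or
#' the iteration cap. With full sampling the procedure is deterministic.
#'
#' @param fixed Fixed [volume()]; the metric is evaluated on its grid.
#' @param moving Moving [volume()], sampled with trilinear interpolation.
#' @param mask [label_volume()] on the fixed grid restricting the metric.
#' @param params A [registration_params()].
#' @param init Initial [rigid_transform()] (fixed world to moving world).
#' @return List: `transform` (the optimized [rigid_transform()]),
#'   `converged` (step length fell below `min_step`), `metric` (final
#'   correlation), `metric_init`, `trace` (per-iteration correlation),
#'   `iterations`.
#' @export
register_rigid <- function(fixed, moving, mask, params = registration_params(),
                           init = rigid_transform()) {
  lin <- which(mask$values > 0)
  if (length(lin) == 0) stop("registration mask is empty")
  if (params$sampling < 1) {
    stride <- max(1L, round(1 / params$sampling))
    lin <- lin[seq(1L, length(lin), by = stride)]
  }
  pts <- voxel_centers(fixed, lin)
  fixed_vals <- fixed$values[lin]
  if (stats::sd(fixed_vals) == 0)
    stop("constant intensities within the mask; metric is undefined")
  center <- colMeans(pts)
  outside <- min(moving$values)
  obj <- function(p) ncc_objective(p, center, fixed_vals, pts, moving, outside)

  p <- rt_to_params(init, center)
  scales <- c(rep(params$rotation_scale, 3), rep(params$translation_scale, 3))
  delta <- c(rep(1e-4, 3), rep(0.05, 3))  # finite-difference step per parameter
  step <- params$max_step
  metric_init <- obj(p)
  value <- metric_init
  p_best <- p
  v_best <- value
  prev_tg <- NULL
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(params$iterations)) {
    g <- vapply(1:6, function(i) {
      dp <- numeric(6); dp[i] <- delta[i]
      (obj(p + dp) - obj(p - dp)) / (2 * delta[i])
    }, numeric(1))
    tg <- g / scales
    gn <- sqrt(sum(tg^2))
    if (!is.finite(gn) || gn < 1e-12) { converged <- TRUE; break }
    if (!is.null(prev_tg) && sum(tg * prev_tg) < 0) step <- step / 2
    if (step < params$min_step) { converged <- TRUE; break }
    # ascent on the correlation
    p <- p + step * tg / gn
    value <- obj(p)
    if (value > v_best) { v_best <- value; p_best <- p }
    prev_tg <- tg
    trace <- c(trace, value)
  }
  list(transform = rt_from_params(p_best, center), converged = converged,
       metric = v_best, metric_init = metric_init, trace = trace,
       iterations = length(trace))
}

#' Orient osteotomy normals toward the joint center
#'
#' Approximates the joint center `C` as the mean of the four plane centers
#' and flips any normal for which `(C - P_j) . N_j < 0`, so all normals
#' point toward the fragment. Centers are unchanged; already-inward normals
#' make the operation idempotent. A plane whose center coincides with `C`
#' along its normal (dot exactly 0) is left as-is with a warning.
#'
#' @param planes List of 4 [plane()]s.
#' @return List of 4 oriented [plane()]s, with the approximated joint
#'   center attached as attribute `joint_center`.
#' @export
orient_planes <- function(planes) {
  stopifnot(length(planes) == 4)
  centers <- t(vapply(planes, function(p) p$center, numeric(3)))
  C <- colMeans(centers)
  out <- lapply(planes, function(p) {
    d <- sum((C - p$center) * p$normal)
    if (d == 0) {
      warning("joint center lies exactly on a plane; normal left unchanged")
      p
    } else if (d < 0) plane(p$center, -p$normal) else p
  })
  attr(out, "joint_center") <- C
  out
}

#' Build the fragment mask from the oriented cut planes
#'
#' A voxel of `coarse_mask` belongs to the fragment iff for every plane the
#' dot product of the vector from the plane center to the voxel center with
#' the (joint-center-oriented) plane normal is strictly positive. Voxels
#' lying exactly on a plane are excluded by the strict inequality.
#'
#' @param coarse_mask Binary [label_volume()] (e.g. the pelvis mask).
#' @param planes List of 4 oriented [plane()]s (see [orient_planes()]).
#' @return Binary [label_volume()] on the same grid, a subset of
#'   `coarse_mask`.
#' @export
build_fragment_mask <- function(coarse_mask, planes) {
  stopifnot(length(planes) == 4)
  lin <- which(coarse_mask$values > 0)
  if (length(lin) == 0) stop("coarse mask is empty")
  pts <- voxel_centers(coarse_mask, lin)
  keep <- rep(TRUE, length(lin))
  for (p in planes)
    keep <- keep & (plane_signed(pts, p) > 0)
  if (!any(keep)) stop("fragment mask is empty")
  vals <- array(0L, vol_shape(coarse_mask))
  vals[lin[keep]] <- 1L
  label_volume(vals, coarse_mask$spacing, coarse_mask$origin,
               coarse_mask$axes, labels = c(0L, 1L))
}

#' Quantify fragment repositioning by two-stage masked registration
#'
#' Stage one (coarse) registers the whole pelvis: the preoperative CT is
#' the fixed image, the postoperative CT the moving image, and the metric
#' is restricted to the preoperative pelvis mask, yielding `T1`, the
#' pre-to-post scan alignment. Stage two (fine) builds the fragment mask in
#' the postoperative frame — the coarse mask carried over by `T1`
#' intersected with the positive side of all four oriented cut planes —
#' and registers the fragment only (fixed image: postoperative CT),
#' yielding the residual fragment motion `T2` in the postoperative frame.
#' The total fragment map is `T2 o T1`.
#'
#' @param pre,post Pre- and postoperative CT [volume()]s (HU).
#' @param planes List of 4 [plane()]s detected in the postoperative frame
#'   (orientation is applied internally).
#' @param pelvis_mask Binary [label_volume()] of the pelvis on the `pre`
#'   grid (from the binary segmenter or the phantom oracle).
#' @param coarse_params,fine_params [registration_params()] for the two
#'   stages.
#' @param post_bone_mask Optional binary mask on the `post` grid; its
#'   centroid initializes the coarse translation and it restricts the fine
#'   mask to postoperative bone (default: a `bone_hu_threshold` threshold
#'   of the postoperative image, metal excluded).
#' @param bone_hu_threshold Bone threshold (HU) used when no postoperative
#'   bone mask is supplied.
#' @param cut_margin Voxels within this distance (mm) of a detected cut
#'   plane are excluded from the fine-stage mask: the tissue there is
#'   callus, remodelled after the intervention, and carries no pre/post
#'   correspondence.
#' @return List: `T1`, `T2`, `total` (= `T2 o T1`), `fragment_mask`
#'   (postoperative frame), and `report` (per-stage convergence flags and
#'   metric traces).
#' @export
quantify_repositioning <- function(pre, post, planes, pelvis_mask,
                                   coarse_params = registration_params(),
                                   fine_params = fine_registration_params(),
                                   post_bone_mask = NULL,
                                   bone_hu_threshold = 300,
                                   cut_margin = 3) {
  # coarse initialization: align bone centroids
  fixed_lin <- which(pelvis_mask$values > 0)
  fixed_centroid <- colMeans(voxel_centers(pelvis_mask, fixed_lin))
  moving_centroid <- if (!is.null(post_bone_mask)) {
    colMeans(voxel_centers(post_bone_mask, which(post_bone_mask$values > 0)))
  } else {
    thr <- stats::quantile(post$values, 0.85)
    lin <- which(post$values >= thr)
    colMeans(voxel_centers(post, lin))
  }
  init <- rigid_transform(diag(3), moving_centroid - fixed_centroid)
  coarse <- register_rigid(pre, post, pelvis_mask, coarse_params, init)
  T1 <- coarse$transform

  planes <- orient_planes(planes)
  # the fragment region is isolated inside the postoperative bone: the
  # voxels the fragment vacated hold soft tissue/callus and the voxels it
  # newly occupies were not bone preoperatively, so the postoperative
  # pelvis segmentation (oracle mask or HU threshold, metal excluded) is
  # the right support for the plane rule
  post_bone <- if (!is.null(post_bone_mask)) post_bone_mask$values > 0
               else post$values > bone_hu_threshold & post$values <= 2500
  post_bone_lab <- label_volume(array(as.integer(post_bone), vol_shape(post)),
                                post$spacing, post$origin, post$axes,
                                labels = c(0L, 1L))
  fragment_mask <- build_fragment_mask(post_bone_lab, planes)
  if (cut_margin > 0) {
    lin <- which(fragment_mask$values > 0)
    pts <- voxel_centers(fragment_mask, lin)
    keep <- rep(TRUE, length(lin))
    for (p in planes) keep <- keep & abs(plane_signed(pts, p)) > cut_margin
    if (sum(keep) > 100) {  # keep the exclusion only if enough bone remains
      vals <- array(0L, vol_shape(fragment_mask))
      vals[lin[keep]] <- 1L
      fragment_mask <- label_volume(vals, fragment_mask$spacing,
                                    fragment_mask$origin, fragment_mask$axes,
                                    labels = c(0L, 1L))
    }
  }

  # fine-stage initialization: T1 aligns the fixed bone, but the fragment
  # itself has moved, so align the fragment centroids (the plane rule gives
  # the preoperative fragment region through T1) and pick the best of a
  # small deterministic set of rotational seeds by metric value
  T1i <- rt_inverse(T1)
  planes_pre_frame <- lapply(planes, function(p)
    plane(rt_apply(T1i, p$center),
          as.numeric(rt_rotation(T1i) %*% p$normal)))
  pre_frag <- tryCatch(build_fragment_mask(pelvis_mask, planes_pre_frame),
                       error = function(e) NULL)
  frag_lin <- which(fragment_mask$values > 0)
  c_post <- colMeans(voxel_centers(fragment_mask, frag_lin))
  init0 <- if (!is.null(pre_frag)) {
    c_pre <- colMeans(voxel_centers(pre_frag, which(pre_frag$values > 0)))
    shift <- c_pre - rt_apply(T1i, c_post)
    rt_compose(rigid_transform(diag(3), shift), T1i)
  } else T1i
  seed_moves <- list(rigid_transform())
  for (ax in 1:3) for (ang in c(-20, -10, 10, 20))
    seed_moves <- c(seed_moves, list(rt_axis_angle(diag(3)[, ax], ang,
                                                   center = c_post)))
  for (ax in 1:3) for (d in c(-6, 6)) {
    tr <- numeric(3); tr[ax] <- d
    seed_moves <- c(seed_moves, list(rigid_transform(diag(3), tr)))
  }
  candidates <- c(list(T1i),
                  lapply(seed_moves, function(mv) rt_compose(init0, mv)))
  stride <- max(1L, round(1 / fine_params$sampling))
  lin_s <- frag_lin[seq(1L, length(frag_lin), by = stride)]
  pts_s <- voxel_centers(post, lin_s)
  fv_s <- post$values[lin_s]
  outside <- min(pre$values)
  seed_metric <- vapply(candidates, function(cand)
    cpp_ncc_metric(fv_s, pts_s, pre$values, pre$spacing, pre$origin,
                   pre$axes, unclass(cand), outside), numeric(1))
  # optimize from the best-scoring starts and keep the best final metric
  top <- order(-seed_metric)[1:3]
  fits <- lapply(candidates[top], function(init_fine)
    register_rigid(post, pre, fragment_mask, fine_params, init = init_fine))
  fine <- fits[[which.max(vapply(fits, `[[`, numeric(1), "metric"))]]
  total <- rt_inverse(fine$transform)      # pre -> post fragment map
  T2 <- rt_compose(total, rt_inverse(T1))  # residual in the post frame
  list(T1 = T1, T2 = T2, total = total, fragment_mask = fragment_mask,
       report = list(
         coarse = coarse[c("converged", "metric", "metric_init", "iterations")],
         fine = fine[c("converged", "metric", "metric_init", "iterations")],
         coarse_trace = coarse$trace, fine_trace = fine$trace))
}
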