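#' Configuration for the synthetic CT phantom
#'
#' The phantom emulates the cropped hip frame the pipeline operates on: a
#' smooth bone-like body (union of overlapping ellipsoids) on a soft-tissue
#' background, cut by four planes that isolate a closed lateral fragment
#' around a joint center, a rigid repositioning of that fragment, callus-like
#' labelled shells straddling each cut, metal-density screw capsules running
#' from the fixed bone into the repositioned fragment, and an optional
#' whole-body rigid offset between the pre- and postoperative scan frames
#' (the patient is never positioned identically twice).
#'
#' Defaults mirror the cropped imaging frame of the target intervention:
#' a 128 mm field of view sampled at 1 mm in a 128^3 grid, cortical-bone
#' intensity on a soft-tissue background in Hounsfield units, metal well
#' above the 2500 HU implant threshold, fragment rotations up to 15 degrees
#' and translations up to 10 mm.
#'
#' @param shape Grid shape (3 integers).
#' @param spacing Voxel size in mm (scalar or length 3).
#' @param bone_hu,soft_hu,metal_hu Intensities (HU); must satisfy
#'   `metal_hu > 2500 > bone_hu > soft_hu`.
#' @param noise_sd Additive Gaussian noise (HU), independent per scan.
#' @param texture_amp_hu Amplitude (HU) of the smooth trabecular-like
#'   intensity texture inside bone; the texture field is anchored to the
#'   anatomy, so it travels with the fragment when it is repositioned.
#' @param texture_wavelength_mm Length-2 range of texture wavelengths (mm).
#' @param n_screws Number of screw implants in the postoperative scan.
#' @param callus_thickness Total thickness (mm) of the labelled shell
#'   straddling each cut plane.
#' @param callus_hu_delta Intensity elevation (HU) applied on the shells.
#' @param rotation_deg,translation_mm Length-2 ranges (or scalar maxima)
#'   from which the fragment rotation angle (deg) and translation magnitude
#'   (mm) are drawn uniformly.
#' @param global_rotation_deg,global_translation_mm Ranges for the
#'   whole-body scan-frame offset, drawn the same way.
#' @param fragment_transform,global_transform Optional explicit 4x4
#'   [rigid_transform()]s overriding the sampled ones.
#' @param screw_radius Screw shaft radius (mm).
#' @param screw_length Length-2 range of screw lengths (mm).
#' @param screw_min_spacing Minimum distance between screw axes (mm).
#' @param seed Integer seed; identical configs with identical seeds generate
#'   bit-identical phantoms.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(128, 128, 128), spacing = 1,
                           bone_hu = 700, soft_hu = 50, metal_hu = 3000,
                           noise_sd = 20, texture_amp_hu = 100,
                           texture_wavelength_mm = c(8, 14), n_screws = 4,
                           callus_thickness = 6, callus_hu_delta = 150,
                           rotation_deg = c(5, 15), translation_mm = c(3, 10),
                           global_rotation_deg = c(2, 5),
                           global_translation_mm = c(2, 5),
                           fragment_transform = NULL, global_transform = NULL,
                           screw_radius = 2, screw_length = c(40, 80),
                           screw_min_spacing = 6, seed = 1L) {
  as_range <- function(x) if (length(x) == 1L) c(0, x) else sort(as.numeric(x))
  cfg <- list(shape = as.integer(rep_len(shape, 3)),
              spacing = rep_len(as.numeric(spacing), 3),
              bone_hu = bone_hu, soft_hu = soft_hu, metal_hu = metal_hu,
              noise_sd = noise_sd, texture_amp_hu = texture_amp_hu,
              texture_wavelength_mm = as_range(texture_wavelength_mm),
              n_screws = as.integer(n_screws),
              callus_thickness = callus_thickness,
              callus_hu_delta = callus_hu_delta,
              rotation_deg = as_range(rotation_deg),
              translation_mm = as_range(translation_mm),
              global_rotation_deg = as_range(global_rotation_deg),
              global_translation_mm = as_range(global_translation_mm),
              fragment_transform = fragment_transform,
              global_transform = global_transform,
              screw_radius = screw_radius,
              screw_length = as_range(screw_length),
              screw_min_spacing = screw_min_spacing,
              seed = as.integer(seed))
  if (!(cfg$metal_hu > 2500 && 2500 > cfg$bone_hu && cfg$bone_hu > cfg$soft_hu))
    stop("intensities must satisfy metal_hu > 2500 > bone_hu > soft_hu")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  if (any(cfg$shape <= 0)) stop("shape must be positive")
  class(cfg) <- "phantom_config"
  cfg
}

# -- analytic scene helpers (all take an n x 3 point matrix, anatomy frame) --

ellipsoid_q <- function(pts, e) {
  q <- sweep(pts, 2, e$center, `-`)
  q <- sweep(q, 2, e$semi, `/`)
  rowSums(q^2)
}

# partial-volume-like occupancy: 1 deep inside, 0 outside, with a smooth
# transition about 1.5 mm wide at the surface (CT point-spread analogue);
# occupancy >= 0.5 is exactly the classic q <= 1 inside test
body_fraction <- function(pts, ellipsoids, edge_w = 0.08) {
  f <- rep(0, nrow(pts))
  for (e in ellipsoids)
    f <- pmax(f, pmin(1, pmax(0, (1 - ellipsoid_q(pts, e)) / edge_w + 0.5)))
  f
}

body_inside <- function(pts, ellipsoids) {
  inside <- rep(FALSE, nrow(pts))
  for (e in ellipsoids) inside <- inside | (ellipsoid_q(pts, e) <= 1)
  inside
}

capsule_inside <- function(pts, a, b, radius) {
  ab <- b - a
  len2 <- sum(ab^2)
  q <- sweep(pts, 2, a, `-`)
  t <- pmin(1, pmax(0, drop(q %*% ab) / len2))
  d2 <- rowSums((q - outer(t, ab))^2)
  d2 <= radius^2
}

random_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

runif_range <- function(r) stats::runif(1, r[1], r[2])

sample_rigid <- function(angle_range, trans_range, center) {
  rt_axis_angle(random_unit(), runif_range(angle_range), center = center,
                translation = random_unit() * runif_range(trans_range))
}

#' Generate a synthetic pre/post CT pair with full ground truth
#'
#' @param config A [phantom_config()].
#' @return A list with elements `pre` and `post` ([volume()]s in HU) and
#'   `truth`, which records: `planes` (four cut planes in the postoperative
#'   scan frame, inward unit normals), `planes_pre` (the same planes in the
#'   preoperative frame), `fragment_transform` (total pre-scan to post-scan
#'   fragment map), `global_transform` (whole-body scan offset),
#'   `fragment_local` (fragment motion relative to the fixed bone),
#'   `fragment_label` (preoperative-frame fragment mask),
#'   `post_fragment_label` (the repositioned fragment in the postoperative
#'   frame),
#'   `cut_labels` (postoperative-frame labels 1-4), `pre_bone_mask` /
#'   `post_bone_mask` (binary pelvis masks), `screws` (per screw: unit
#'   `direction` pointing toward the head, `entry` point at the head-end
#'   tip, `head`/`tip` axis endpoints, `length`, `radius`, all in the
#'   postoperative frame), `joint_center`, `seed` and `config`.
#' @export
make_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  sh <- config$shape; sp <- config$spacing
  origin <- -(sh - 1) * sp / 2  # grid centered on the anatomy frame origin
  extent <- sh * sp
  scale <- min(extent) / 128    # geometry constants are stated for a 128 mm frame
  grid_idx <- arrayInd(seq_len(prod(sh)), sh) - 1
  pts <- sweep(sweep(grid_idx, 2, sp, `*`), 2, origin, `+`)

  jit <- function(n, a) stats::runif(n, -a, a)
  ellipsoids <- list(
    list(center = c(0, 0, 5) * scale + jit(3, 3 * scale),
         semi = c(46, 40, 42) * scale + jit(3, 3 * scale)),
    list(center = c(8, -6, -28) * scale + jit(3, 3 * scale),
         semi = c(26, 24, 26) * scale + jit(3, 2 * scale)),
    list(center = c(-6, 6, 30) * scale + jit(3, 3 * scale),
         semi = c(30, 26, 24) * scale + jit(3, 2 * scale))
  )
  body <- body_inside(pts, ellipsoids)

  # trabecular/cortical-like intensity texture, anchored to the anatomy
  # frame; multi-scale (fine trabecular detail plus coarse marrow/cortex
  # structure) so image registration has capture range at several scales
  lam_fine <- config$texture_wavelength_mm
  lambdas <- c(stats::runif(2, lam_fine[1], lam_fine[2]),
               stats::runif(1, 2 * lam_fine[2], 4 * lam_fine[2]),
               stats::runif(1, 4 * lam_fine[2], 8 * lam_fine[2]))
  tex_waves <- lapply(lambdas, function(lambda)
    list(k = random_unit() * 2 * pi / lambda, phase = stats::runif(1, 0, 2 * pi)))
  texture_at <- function(p) {
    out <- 0
    for (w in tex_waves) out <- out + sin(drop(p %*% w$k) + w$phase)
    config$texture_amp_hu * out / 2
  }

  # draw four cut planes isolating a closed lateral fragment around C
  m_canon <- rbind(c(0.1, -0.1, 1),      # supraacetabular (superior)
                   c(-0.85, 0.25, 0.45), # retroacetabular
                   c(-0.45, 0.25, -0.85),# ischial
                   c(-0.7, -0.65, -0.2)) # pubic
  voxvol <- prod(sp)
  min_frag <- max(200, round(8000 * scale^3 / voxvol))
  min_band <- max(40, round(150 * scale^3 / voxvol))
  planes_pre <- NULL; fragment <- NULL; bands <- NULL
  for (attempt in seq_len(20)) {
    C <- c(22, -4, -4) * scale + jit(3, 4 * scale)
    pl <- vector("list", 4)
    for (j in 1:4) {
      m <- m_canon[j, ] + jit(3, 0.15)
      m <- m / sqrt(sum(m^2))
      d <- stats::runif(1, 13, 19) * scale
      pl[[j]] <- plane(C + d * m, -m)  # normal points inward, toward C
    }
    sgn <- vapply(pl, function(p) plane_signed(pts, p), numeric(nrow(pts)))
    frag <- body & sgn[, 1] > 0 & sgn[, 2] > 0 & sgn[, 3] > 0 & sgn[, 4] > 0
    if (sum(frag) < min_frag) next
    # fragment must be interior to the grid (closed piece, 2-voxel margin)
    fr_idx <- grid_idx[frag, , drop = FALSE]
    if (any(fr_idx < 2) || any(sweep(fr_idx, 2, sh - 3) > 0)) next
    t2 <- config$callus_thickness / 2
    bnd <- vector("list", 4)
    ok <- TRUE
    for (j in 1:4) {
      near_face <- rep(TRUE, nrow(pts))
      for (k in setdiff(1:4, j))
        near_face <- near_face & sgn[, k] > -config$callus_thickness
      bnd[[j]] <- body & abs(sgn[, j]) <= t2 & near_face
      if (sum(bnd[[j]]) < min_band) { ok <- FALSE; break }
    }
    if (!ok) next
    planes_pre <- pl; fragment <- frag
    bands <- bnd; signed <- sgn
    break
  }
  if (is.null(planes_pre))
    stop("failed to isolate a closed fragment after 20 plane draws")

  frag_centroid <- colMeans(pts[fragment, , drop = FALSE])
  Tfrag <- if (!is.null(config$fragment_transform))
    as_rigid_transform(config$fragment_transform)
  else sample_rigid(config$rotation_deg, config$translation_mm, frag_centroid)
  Tglob <- if (!is.null(config$global_transform))
    as_rigid_transform(config$global_transform)
  else sample_rigid(config$global_rotation_deg, config$global_translation_mm,
                    c(0, 0, 0))

  # screws: head in the fixed bone above the supraacetabular cut, tip inside
  # the repositioned fragment
  frag_centroid_post <- rt_apply(Tfrag, frag_centroid)
  top_z <- function(x, y) {
    z <- -Inf
    for (e in ellipsoids) {
      r2 <- 1 - ((x - e$center[1]) / e$semi[1])^2 - ((y - e$center[2]) / e$semi[2])^2
      if (r2 > 0) z <- max(z, e$center[3] + e$semi[3] * sqrt(r2))
    }
    z
  }
  seg_dist <- function(a1, b1, a2, b2) {
    # min distance between two segments (dense parametric scan is plenty here)
    t1 <- seq(0, 1, length.out = 25)
    p1 <- outer(t1, b1 - a1) + matrix(a1, 25, 3, byrow = TRUE)
    t2 <- seq(0, 1, length.out = 25)
    p2 <- outer(t2, b2 - a2) + matrix(a2, 25, 3, byrow = TRUE)
    min(sqrt(outer(rowSums(p1^2), rowSums(p2^2), `+`) - 2 * p1 %*% t(p2)))
  }
  screws <- list()
  if (config$n_screws > 0) {
    half <- extent / 2 - 2 * sp
    for (i in seq_len(config$n_screws)) {
      placed <- FALSE
      for (try in seq_len(200)) {
        xy <- C[1:2] + stats::runif(2, -20, 20) * scale
        zt <- top_z(xy[1], xy[2])
        if (!is.finite(zt)) next
        h <- c(xy, zt - 1 * scale)
        target <- frag_centroid_post + jit(3, 12 * scale)
        u <- target - h
        u <- u / sqrt(sum(u^2))
        if (u[3] > -0.2) next  # head must sit above the tip
        len <- min(runif_range(config$screw_length) * scale,
                   sqrt(sum((target - h)^2)) + 10 * scale)
        tip <- h + len * u
        if (any(abs(tip) > half) || any(abs(h) > half)) next
        clash <- FALSE
        for (s in screws)
          if (seg_dist(h, tip, s$head_anat, s$tip_anat) < config$screw_min_spacing) {
            clash <- TRUE; break
          }
        if (clash) next
        screws[[i]] <- list(head_anat = h, tip_anat = tip, dir_anat = u,
                            length = len, radius = config$screw_radius)
        placed <- TRUE
        break
      }
      if (!placed) stop("failed to place screw ", i,
                        " with the requested minimum spacing")
    }
  }

  # --- render the two scans ---
  band_label <- integer(nrow(pts))
  band_min <- rep(Inf, nrow(pts))
  for (j in 1:4) {
    hit <- bands[[j]] & abs(signed[, j]) < band_min
    band_label[hit] <- j
    band_min[hit] <- abs(signed[hit, j])
  }

  pre_frac <- body_fraction(pts, ellipsoids)
  pre_vals <- config$soft_hu +
    (config$bone_hu + texture_at(pts) - config$soft_hu) * pre_frac

  Gi <- rt_inverse(Tglob)
  pts_post <- rt_apply(Gi, pts)           # post grid point in anatomy frame
  pts_frag <- rt_apply(rt_inverse(Tfrag), pts_post)
  body_post <- body_inside(pts_post, ellipsoids)
  sgn_post <- vapply(planes_pre, function(p) plane_signed(pts_post, p),
                     numeric(nrow(pts)))
  frag_at_post <- body_post & sgn_post[, 1] > 0 & sgn_post[, 2] > 0 &
    sgn_post[, 3] > 0 & sgn_post[, 4] > 0
  moved_frag <- body_inside(pts_frag, ellipsoids)
  sgn_frag <- vapply(planes_pre, function(p) plane_signed(pts_frag, p),
                     numeric(nrow(pts)))
  moved_frag <- moved_frag & sgn_frag[, 1] > 0 & sgn_frag[, 2] > 0 &
    sgn_frag[, 3] > 0 & sgn_frag[, 4] > 0
  bone_post <- (body_post & !frag_at_post) | moved_frag
  # smooth occupancy for the fixed bone and the moved fragment separately;
  # the fragment carries its own texture pattern along with the motion
  fixed_frac <- body_fraction(pts_post, ellipsoids)
  fixed_frac[frag_at_post] <- 0
  frag_frac <- body_fraction(pts_frag, ellipsoids)
  frag_ok <- sgn_frag[, 1] > 0 & sgn_frag[, 2] > 0 & sgn_frag[, 3] > 0 &
    sgn_frag[, 4] > 0
  frag_frac[!frag_ok] <- 0
  post_frac <- pmax(fixed_frac, frag_frac)
  post_tex <- texture_at(pts_post)
  use_frag <- frag_frac > fixed_frac
  post_tex[use_frag] <- texture_at(pts_frag[use_frag, , drop = FALSE])
  post_vals <- config$soft_hu +
    (config$bone_hu + post_tex - config$soft_hu) * post_frac

  # callus shells straddle each (fixed-side) cut plane, bridging the gap
  t2 <- config$callus_thickness / 2
  post_band_label <- integer(nrow(pts))
  post_band_min <- rep(Inf, nrow(pts))
  pre_body_post <- body_post
  for (j in 1:4) {
    near_face <- rep(TRUE, nrow(pts))
    for (k in setdiff(1:4, j))
      near_face <- near_face & sgn_post[, k] > -config$callus_thickness
    bj <- pre_body_post & abs(sgn_post[, j]) <= t2 & near_face
    hit <- bj & abs(sgn_post[, j]) < post_band_min
    post_band_label[hit] <- j
    post_band_min[hit] <- abs(sgn_post[hit, j])
  }
  post_vals <- post_vals + config$callus_hu_delta * (post_band_label > 0)

  metal <- rep(FALSE, nrow(pts))
  for (s in screws)
    metal <- metal | capsule_inside(pts_post, s$head_anat, s$tip_anat, s$radius)
  post_vals[metal] <- config$metal_hu

  if (config$noise_sd > 0) {
    pre_vals <- pre_vals + stats::rnorm(length(pre_vals), 0, config$noise_sd)
    post_vals <- post_vals + stats::rnorm(length(post_vals), 0, config$noise_sd)
  }

  geom <- list(spacing = sp, origin = origin, axes = diag(3))
  mk_vol <- function(v) volume(array(v, sh), sp, origin, diag(3))
  mk_lab <- function(v, labels) label_volume(array(as.integer(v), sh), sp,
                                             origin, diag(3), labels = labels)
  Rg <- rt_rotation(Tglob)
  planes_post <- lapply(planes_pre, function(p)
    plane(rt_apply(Tglob, p$center), as.numeric(Rg %*% p$normal)))
  screws_post <- lapply(screws, function(s) {
    dir_head <- as.numeric(Rg %*% (-s$dir_anat))
    list(direction = dir_head,
         entry = rt_apply(Tglob, s$head_anat - s$radius * s$dir_anat),
         head = rt_apply(Tglob, s$head_anat),
         tip = rt_apply(Tglob, s$tip_anat),
         length = s$length, radius = s$radius)
  })

  truth <- list(
    planes = planes_post,
    planes_pre = planes_pre,
    fragment_transform = rt_compose(Tglob, Tfrag),
    global_transform = Tglob,
    fragment_local = Tfrag,
    fragment_label = mk_lab(fragment, labels = c(0L, 1L)),
    post_fragment_label = mk_lab(moved_frag, labels = c(0L, 1L)),
    cut_labels = mk_lab(post_band_label, labels = 0:4),
    pre_bone_mask = mk_lab(body, labels = c(0L, 1L)),
    post_bone_mask = mk_lab(bone_post & !metal, labels = c(0L, 1L)),
    screws = screws_post,
    joint_center = C,
    seed = config$seed,
    config = config
  )
  list(pre = mk_vol(pre_vals), post = mk_vol(post_vals), truth = truth)
}

#' Surface points of the phantom's preoperative fragment
#'
#' Boundary voxel centers (6-connectivity) of the ground-truth fragment
#' label, used as the corresponding-point set for registration error
#' evaluation.
#'
#' @param truth The `truth` element of a [make_phantom()] result.
#' @param max_points Subsample ceiling (deterministic stride).
#' @return n x 3 matrix of world mm points in the preoperative frame.
#' @export
fragment_surface_points <- function(truth, max_points = 2000) {
  surface_points_of_mask(truth$fragment_label, max_points)
}

surface_points_of_mask <- function(mask_vol, max_points = Inf) {
  m <- mask_vol$values > 0
  sh <- dim(m)
  interior <- m
  shift_and <- function(arr, ax, by) {
    out <- array(FALSE, dim(arr))
    idx_src <- lapply(dim(arr), seq_len)
    idx_dst <- idx_src
    n <- dim(arr)[ax]
    if (by > 0) { idx_dst[[ax]] <- (1 + by):n; idx_src[[ax]] <- 1:(n - by) }
    else { idx_dst[[ax]] <- 1:(n + by); idx_src[[ax]] <- (1 - by):n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(-1, 1))
    interior <- interior & shift_and(m, ax, by)
  boundary <- which(m & !interior)
  if (length(boundary) == 0) boundary <- which(m)
  if (length(boundary) > max_points) {
    stride <- ceiling(length(boundary) / max_points)
    boundary <- boundary[seq(1, length(boundary), by = stride)]
  }
  voxel_centers(mask_vol, boundary)
}

#' Geometric data augmentation
#'
#' Offline augmentation for segmenter training: any combination of vertical
#' flipping, rotation and translation, applied in the given order on the
#' volume's own grid. Flips are exact index reversals (an involution);
#' rotation/translation resample the content about the volume center
#' (trilinear for intensities, nearest-neighbour for labels).
#'
#' @param vol A [volume()] or [label_volume()].
#' @param ops Non-empty subset of `c("flip", "rotate", "translate")`.
#' @param seed Integer seed controlling the sampled angle/offset.
#' @param flip_axis Axis index (1-3) reversed by `"flip"`.
#' @param rotate_deg Maximum rotation magnitude (deg), drawn uniformly.
#' @param translate_mm Maximum per-axis translation (mm), drawn uniformly.
#' @return Augmented volume on the same grid.
#' @export
augment <- function(vol, ops, seed = 1L, flip_axis = 3L, rotate_deg = 10,
                    translate_mm = 10) {
  if (length(ops) == 0) stop("ops must be a non-empty subset")
  ops <- match.arg(ops, c("flip", "rotate", "translate"), several.ok = TRUE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  out <- vol
  for (op in ops) {
    if (op == "flip") {
      idx <- lapply(dim(out$values), seq_len)
      idx[[flip_axis]] <- rev(idx[[flip_axis]])
      out$values <- out$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      if (is_label_volume(out)) storage.mode(out$values) <- "integer"
    } else {
      tr <- if (op == "rotate")
        rt_axis_angle(random_unit(), stats::runif(1, -rotate_deg, rotate_deg),
                      center = vol_center(out))
      else
        rigid_transform(diag(3), stats::runif(3, -translate_mm, translate_mm))
      out <- resample_through(out, tr)
    }
  }
  out
}

vol_center <- function(vol) {
  world_from_voxel(vol, (vol_shape(vol) - 1) / 2)
}

# resample a volume onto its own grid with content moved by `transform`
# (value'(x) = value(transform^-1 x))
resample_through <- function(vol, transform) {
  inv <- rt_inverse(transform)
  world <- voxel_centers(vol)
  src_world <- rt_apply(inv, world)
  src_idx <- voxel_from_world(vol, src_world)
  linear <- !is_label_volume(vol)
  outside <- if (linear) min(vol$values) else 0
  vals <- cpp_sample_volume(vol$values, src_idx, linear, outside)
  out <- vol
  out$values <- array(if (linear) vals else as.integer(round(vals)),
                      dim = vol_shape(vol))
  out
}
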