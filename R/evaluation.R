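#' Anatomical axis convention
#'
#' The package works in a configurable anatomical frame; the default
#' radiological convention is +x = left, +y = posterior, +z = superior.
#' Medial means toward the midsagittal plane (the mid-range of the surface
#' along the left axis).
#'
#' @param left,posterior,superior Unit vectors of the three anatomical
#'   directions in world coordinates.
#' @return List of class `anatomical_axes`.
#' @export
anatomical_axes <- function(left = c(1, 0, 0), posterior = c(0, 1, 0),
                            superior = c(0, 0, 1)) {
  norm1 <- function(v) v / sqrt(sum(v^2))
  structure(list(left = norm1(left), posterior = norm1(posterior),
                 superior = norm1(superior)),
            class = "anatomical_axes")
}

# intersection line of two planes; NULL if near-parallel
plane_intersection_line <- function(p1, p2, tol = 1e-3) {
  l <- c(p1$normal[2] * p2$normal[3] - p1$normal[3] * p2$normal[2],
         p1$normal[3] * p2$normal[1] - p1$normal[1] * p2$normal[3],
         p1$normal[1] * p2$normal[2] - p1$normal[2] * p2$normal[1])
  n <- sqrt(sum(l^2))
  if (n < tol) return(NULL)
  d1 <- sum(p1$normal * p1$center)
  d2 <- sum(p2$normal * p2$center)
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  p0 <- (d1 * cross(p2$normal, l) + d2 * cross(l, p1$normal)) / n^2
  list(point = p0, direction = l / n)
}

#' Osteotomy landmark points
#'
#' Computes the five starting points of the osteotomies on the bone
#' surface: P1 = most superior point where the supraacetabular plane (1)
#' meets the surface; P2 / P3 = most medial points on the intersection
#' lines of planes 1-2 and 2-3; P4 = most anterior point where the ischial
#' plane (3) meets the surface; P5 = most posterior point where the pubic
#' plane (4) meets the surface. Surface-plane intersections are surface
#' points within `tol` of the plane; intersection-line landmarks are
#' clipped to the surface bounding box before taking the extremum.
#'
#' @param planes List of 4 oriented [plane()]s, ordered supraacetabular,
#'   retroacetabular, ischial, pubic.
#' @param surface n x 3 matrix of bone-surface points (world mm).
#' @param axes An [anatomical_axes()].
#' @param tol Surface-plane intersection tolerance (mm); half a voxel
#'   diagonal of the source grid is the natural choice.
#' @return List with `points` (length-5 list of world mm points or `NULL`)
#'   and `failed` (logical length 5).
#' @export
landmark_points <- function(planes, surface, axes = anatomical_axes(),
                            tol = 1) {
  stopifnot(length(planes) == 4)
  surface <- as.matrix(surface)
  if (nrow(surface) == 0) stop("surface point set is empty")
  pts <- vector("list", 5)
  failed <- logical(5)
  x_left <- drop(surface %*% axes$left)
  x_mid <- mean(range(x_left))
  surf_on_plane <- function(j) {
    d <- abs(plane_signed(surface, planes[[j]]))
    surface[d <= tol, , drop = FALSE]
  }
  extremal <- function(p, dir) {
    if (nrow(p) == 0) return(NULL)
    score <- drop(p %*% dir)
    # voxelized surfaces tie frequently; break ties lexicographically so the
    # landmark does not depend on point ordering
    cand <- p[score >= max(score) - 1e-9, , drop = FALSE]
    cand[order(cand[, 1], cand[, 2], cand[, 3])[1], ]
  }
  # single-bracket list assignment: NULL results must not delete elements
  pts[1] <- list(extremal(surf_on_plane(1), axes$superior))
  pts[4] <- list(extremal(surf_on_plane(3), -axes$posterior))
  pts[5] <- list(extremal(surf_on_plane(4), axes$posterior))
  bbox_lo <- apply(surface, 2, min)
  bbox_hi <- apply(surface, 2, max)
  medial_on_line <- function(pa, pb) {
    ln <- plane_intersection_line(planes[[pa]], planes[[pb]])
    if (is.null(ln)) stop("osteotomy planes ", pa, " and ", pb,
                          " are near-parallel; intersection line undefined")
    # clip the line to the surface bounding box (slab intersection)
    t_lo <- -Inf; t_hi <- Inf
    for (ax in 1:3) {
      if (abs(ln$direction[ax]) < 1e-12) {
        if (ln$point[ax] < bbox_lo[ax] || ln$point[ax] > bbox_hi[ax]) next
      } else {
        t1 <- (bbox_lo[ax] - ln$point[ax]) / ln$direction[ax]
        t2 <- (bbox_hi[ax] - ln$point[ax]) / ln$direction[ax]
        t_lo <- max(t_lo, min(t1, t2))
        t_hi <- min(t_hi, max(t1, t2))
      }
    }
    if (!is.finite(t_lo) || !is.finite(t_hi) || t_lo > t_hi) return(NULL)
    slope <- sum(ln$direction * axes$left)
    if (abs(slope) < 1e-9) return(NULL)  # medial extremum degenerate
    m0 <- sum((ln$point - x_mid * axes$left) * axes$left)
    t_star <- min(max(-m0 / slope, t_lo), t_hi)
    ln$point + t_star * ln$direction
  }
  pts[2] <- list(medial_on_line(1, 2))
  pts[3] <- list(medial_on_line(2, 3))
  failed <- vapply(pts, is.null, logical(1))
  list(points = pts, failed = failed)
}

#' Projected in-plane connecting vectors and 2D angles
#'
#' Projects the first four landmark points orthogonally onto the
#' least-squares plane `PL` fitted through them, forms the connecting
#' vectors `V_k = P_{k+1}' - P_k'`, and measures the angles between
#' consecutive vectors: `SR = angle(V1, V2)` and `RI = angle(V2, V3)`.
#'
#' @param points List or 4 x 3 matrix of landmark points P1-P4.
#' @param pl Optional [plane()] to project onto; default the least-squares
#'   fit of the four points.
#' @return List: `projected` (4 x 3), `V` (3 x 3, rows V1-V3), `angles`
#'   (deg, between consecutive V), `SR`, `RI`, `plane`.
#' @export
projected_angles <- function(points, pl = NULL) {
  p <- if (is.list(points)) do.call(rbind, points) else as.matrix(points)
  stopifnot(nrow(p) == 4)
  if (is.null(pl)) pl <- fit_plane(p)
  d <- plane_signed(p, pl)
  proj <- p - outer(d, pl$normal)
  v <- proj[2:4, , drop = FALSE] - proj[1:3, , drop = FALSE]
  vecangle <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na < 1e-12 || nb < 1e-12) return(NA_real_)
    acos(min(1, max(-1, sum(a * b) / (na * nb)))) * 180 / pi
  }
  angles <- c(vecangle(v[1, ], v[2, ]), vecangle(v[2, ], v[3, ]))
  list(projected = proj, V = v, angles = angles,
       SR = angles[1], RI = angles[2], plane = pl)
}

#' Sign-agnostic angle between two plane normals
#'
#' @param n_a,n_b Unit vectors.
#' @return Angle in degrees in `[0, 90]`; opposite normals give 0.
#' @export
normal_angle <- function(n_a, n_b) {
  d <- abs(sum(n_a * n_b)) / sqrt(sum(n_a^2) * sum(n_b^2))
  acos(min(1, d)) * 180 / pi
}

#' Registration error as mean absolute point distance
#'
#' Mean Euclidean distance between the images of the same surface points
#' under two rigid transforms — the mesh-point MAE used to compare an
#' automatic registration against a reference.
#'
#' @param surface_points n x 3 matrix (n >= 1) of world mm points.
#' @param t_a,t_b [rigid_transform()]s to compare.
#' @return MAE in mm.
#' @export
registration_errors <- function(surface_points, t_a, t_b) {
  p <- as.matrix(surface_points)
  if (nrow(p) == 0) stop("empty point set")
  mean(sqrt(rowSums((rt_apply(t_a, p) - rt_apply(t_b, p))^2)))
}

#' Dice coefficient of two binary masks
#'
#' @param a,b Binary [label_volume()]s (or logical/0-1 arrays) on a common
#'   grid.
#' @return `2|A n B| / (|A| + |B|)` in `[0, 1]`; both-empty input is an
#'   error.
#' @export
dice_coefficient <- function(a, b) {
  av <- if (is_volume(a)) a$values > 0 else a > 0
  bv <- if (is_volume(b)) b$values > 0 else b > 0
  stopifnot(all(dim(av) == dim(bv)))
  na <- sum(av); nb <- sum(bv)
  if (na + nb == 0) stop("both masks are empty; Dice is undefined")
  2 * sum(av & bv) / (na + nb)
}

#' Per-screw placement errors
#'
#' Matches automatic detections to reference screws by greedy
#' mutual-nearest entry points (10 mm gate) and reports, per matched pair,
#' the Euclidean head/entry distance and the sign-agnostic 3D angle
#' between the screw axes. Unmatched detections and references are listed
#' separately.
#'
#' @param auto List of detections (each with `entry_point`/`entry` and
#'   `direction`).
#' @param truth List of reference screws (same fields).
#' @param gate_mm Matching gate (mm).
#' @return List: `pairs` (data.frame with indices, `head_mm`, `axis_deg`),
#'   `unmatched_auto`, `unmatched_truth`, and the means `mean_head_mm`,
#'   `mean_axis_deg`.
#' @export
screw_errors <- function(auto, truth, gate_mm = 10) {
  entry_of <- function(s) as.numeric(if (!is.null(s$entry_point)) s$entry_point else s$entry)
  na <- length(auto); nt <- length(truth)
  pairs <- data.frame(auto = integer(0), truth = integer(0),
                      head_mm = numeric(0), axis_deg = numeric(0))
  if (na > 0 && nt > 0) {
    dmat <- matrix(Inf, na, nt)
    for (i in seq_len(na)) for (j in seq_len(nt))
      dmat[i, j] <- sqrt(sum((entry_of(auto[[i]]) - entry_of(truth[[j]]))^2))
    repeat {
      m <- which(dmat == min(dmat), arr.ind = TRUE)[1, , drop = TRUE]
      if (!is.finite(dmat[m[1], m[2]]) || dmat[m[1], m[2]] > gate_mm) break
      i <- m[1]; j <- m[2]
      pairs <- rbind(pairs, data.frame(
        auto = i, truth = j, head_mm = dmat[i, j],
        axis_deg = normal_angle(auto[[i]]$direction, truth[[j]]$direction)))
      dmat[i, ] <- Inf
      dmat[, j] <- Inf
      if (all(!is.finite(dmat))) break
    }
  }
  list(pairs = pairs,
       unmatched_auto = setdiff(seq_len(na), pairs$auto),
       unmatched_truth = setdiff(seq_len(nt), pairs$truth),
       mean_head_mm = if (nrow(pairs)) mean(pairs$head_mm) else NA_real_,
       mean_axis_deg = if (nrow(pairs)) mean(pairs$axis_deg) else NA_real_)
}

#' Compare two landmark sets
#'
#' The geometry of the quantitative plane comparison: 3D distances between
#' corresponding landmarks, 2D angles between corresponding connecting
#' vectors after projecting both sets onto the plane `PL` fitted through
#' the reference P1-P4, absolute SR/RI deviations, and the sign-agnostic
#' 3D angle between the pubic-plane normals.
#'
#' @param auto,ref [landmark_points()] results (or length-5 point lists).
#' @param auto_pubic_normal,ref_pubic_normal Unit normals of the pubic
#'   (fourth) plane from the two solutions.
#' @return List of comparison metrics (all distances mm, angles deg).
#' @export
compare_landmarks <- function(auto, ref, auto_pubic_normal = NULL,
                              ref_pubic_normal = NULL) {
  ap <- if (!is.null(auto$points)) auto$points else auto
  rp <- if (!is.null(ref$points)) ref$points else ref
  dist3d <- vapply(1:5, function(i) {
    if (is.null(ap[[i]]) || is.null(rp[[i]])) return(NA_real_)
    sqrt(sum((ap[[i]] - rp[[i]])^2))
  }, numeric(1))
  pl <- fit_plane(do.call(rbind, rp[1:4]))
  pa <- projected_angles(ap[1:4], pl = pl)
  pr <- projected_angles(rp[1:4], pl = pl)
  v_angles <- vapply(1:3, function(k)
    normal_angle(pa$V[k, ], pr$V[k, ]), numeric(1))
  list(point_dist_mm = dist3d,
       vector_angle_deg = v_angles,
       sr_deviation_deg = abs(pa$SR - pr$SR),
       ri_deviation_deg = abs(pa$RI - pr$RI),
       pubic_normal_angle_deg = if (!is.null(auto_pubic_normal) &&
                                    !is.null(ref_pubic_normal))
         normal_angle(auto_pubic_normal, ref_pubic_normal) else NA_real_)
}

#' Write / read a structured evaluation report
#'
#' Reports serialize to JSON at full precision, so a write-read round trip
#' is lossless.
#'
#' @param report Named list of evaluation results.
#' @param path Output `.json` path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}
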