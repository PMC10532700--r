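#' Parameters for iterative 3D Hough line detection
#'
#' The three knobs of the line detector plus the granularity of the
#' direction discretization. Defaults follow the values found optimal for
#' postoperative screw clouds: at most 6 lines, at least 50 supporting
#' points, 3 mm anchor-plane step width.
#'
#' @param nlines Maximum number of lines to detect.
#' @param minvotes Minimum vote count (and assigned-point count) for a line.
#' @param dx Step width (mm) of the anchor-plane discretization; also used
#'   as the point-to-line assignment radius.
#' @param sphere_level Icosahedron subdivision level for the direction
#'   discretization (level 4 gives about 1.3 degree resolution).
#' @return List of class `hough_params`.
#' @export
hough_params <- function(nlines = 6, minvotes = 50, dx = 3, sphere_level = 4) {
  stopifnot(nlines >= 1, minvotes >= 2, dx > 0, sphere_level >= 0)
  structure(list(nlines = as.integer(nlines), minvotes = as.integer(minvotes),
                 dx = dx, sphere_level = as.integer(sphere_level)),
            class = "hough_params")
}

# hemisphere direction set from a subdivided icosahedron (deterministic)
icosphere_directions <- function(level = 4) {
  cache <- get0("icosphere_cache", envir = .postop3d_env)
  key <- as.character(level)
  if (!is.null(cache[[key]])) return(cache[[key]])
  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  verts <- verts / sqrt(rowSums(verts^2))
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    key_of <- function(p) paste(round(p, 10), collapse = ",")
    vkeys <- apply(verts, 1, key_of)
    lookup <- new.env(parent = emptyenv())
    for (i in seq_along(vkeys)) assign(vkeys[i], i, envir = lookup)
    midpoint <- function(a, b) {
      m <- verts[a, ] + verts[b, ]
      m <- m / sqrt(sum(m^2))
      k <- key_of(m)
      id <- get0(k, envir = lookup)
      if (is.null(id)) {
        verts <<- rbind(verts, m)
        id <- nrow(verts)
        assign(k, id, envir = lookup)
      }
      id
    }
    new_faces <- matrix(0L, nrow(faces) * 4, 3)
    for (f in seq_len(nrow(faces))) {
      a <- faces[f, 1]; b <- faces[f, 2]; c <- faces[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      new_faces[(f - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                              c(c, ca, bc), c(ab, bc, ca))
    }
    faces <- new_faces
  }
  # keep one hemisphere (sign-canonical directions)
  keep <- verts[, 3] > 1e-9 |
    (abs(verts[, 3]) <= 1e-9 & (verts[, 2] > 1e-9 |
                                  (abs(verts[, 2]) <= 1e-9 & verts[, 1] > 0)))
  dirs <- verts[keep, , drop = FALSE]
  cache[[key]] <- dirs
  dirs
}

.postop3d_env <- new.env(parent = emptyenv())
assign("icosphere_cache", new.env(parent = emptyenv()), envir = .postop3d_env)

# deterministic orthonormal basis of the plane orthogonal to each direction
plane_basis <- function(dirs) {
  n <- nrow(dirs)
  u <- matrix(0, n, 3)
  pick <- abs(dirs[, 3]) < 0.9
  ref <- matrix(rep(c(0, 0, 1), n), n, 3, byrow = TRUE)
  ref[!pick, ] <- matrix(c(1, 0, 0), sum(!pick), 3, byrow = TRUE)
  u <- cbind(ref[, 2] * dirs[, 3] - ref[, 3] * dirs[, 2],
             ref[, 3] * dirs[, 1] - ref[, 1] * dirs[, 3],
             ref[, 1] * dirs[, 2] - ref[, 2] * dirs[, 1])
  u <- u / sqrt(rowSums(u^2))
  v <- cbind(dirs[, 2] * u[, 3] - dirs[, 3] * u[, 2],
             dirs[, 3] * u[, 1] - dirs[, 1] * u[, 3],
             dirs[, 1] * u[, 2] - dirs[, 2] * u[, 1])
  list(u = u, v = v)
}

#' Threshold metal implants in a postoperative CT
#'
#' Voxels strictly above the Hounsfield threshold (default 2500 HU, above
#' cortical bone but below metal) form the implant mask; the point cloud of
#' their world-mm voxel centers feeds the line detector.
#'
#' @param post_ct Postoperative CT [volume()] in HU (not normalized).
#' @param hu_threshold Strict lower threshold (HU).
#' @return List: `mask` (binary [label_volume()]) and `cloud` (n x 3 world
#'   mm matrix, possibly with zero rows).
#' @export
threshold_implants <- function(post_ct, hu_threshold = 2500) {
  lin <- which(post_ct$values > hu_threshold)
  vals <- array(0L, vol_shape(post_ct))
  vals[lin] <- 1L
  mask <- label_volume(vals, post_ct$spacing, post_ct$origin, post_ct$axes,
                       labels = c(0L, 1L))
  cloud <- if (length(lin)) voxel_centers(post_ct, lin)
           else matrix(numeric(0), 0, 3)
  list(mask = mask, cloud = cloud)
}

point_line_distance <- function(pts, anchor, direction) {
  q <- sweep(pts, 2, anchor, `-`)
  along <- drop(q %*% direction)
  sqrt(pmax(0, rowSums(q^2) - along^2))
}

# orthogonal least-squares line through a point set (sign-canonical direction)
fit_line <- function(pts) {
  ctr <- colMeans(pts)
  q <- sweep(pts, 2, ctr, `-`)
  ev <- eigen(crossprod(q), symmetric = TRUE)
  d <- ev$vectors[, 1]
  if (d[3] < 0 || (d[3] == 0 && (d[2] < 0 || (d[2] == 0 && d[1] < 0)))) d <- -d
  list(center = ctr, direction = d)
}

#' Iterative 3D Hough transform for line detection
#'
#' Detects straight lines in a 3D point cloud. Directions are discretized
#' on one hemisphere of a subdivided icosahedron; for each direction the
#' points (centered on the cloud centroid) are projected onto the
#' orthogonal anchor plane, discretized with step `dx`, and voted. The
#' transform is applied iteratively: the global vote maximum is taken, the
#' points within `dx` of the candidate line are assigned, the line is
#' refitted by orthogonal regression (for sub-cell accuracy), assigned
#' points are removed, and the procedure repeats until `nlines` lines are
#' found or the best candidate falls below `minvotes` (applied to both the
#' vote count and the refined assigned-point count).
#'
#' @param cloud n x 3 matrix of world mm points.
#' @param params A [hough_params()].
#' @return List of detections sorted by decreasing support, each with
#'   `n_points`, `center` (center of mass of the assigned points) and
#'   `direction` (unit vector, sign-canonical on one hemisphere).
#' @export
hough_lines_3d <- function(cloud, params = hough_params()) {
  cloud <- as.matrix(cloud)
  if (nrow(cloud) == 0) stop("point cloud is empty")
  dirs <- icosphere_directions(params$sphere_level)
  basis <- plane_basis(dirs)
  centroid <- colMeans(cloud)
  pts <- sweep(cloud, 2, centroid, `-`)
  nrad <- max(1L, as.integer(ceiling(max(sqrt(rowSums(pts^2))) / params$dx)) + 1L)
  remaining <- seq_len(nrow(pts))
  out <- list()
  while (length(out) < params$nlines && length(remaining) >= params$minvotes) {
    sub <- pts[remaining, , drop = FALSE]
    best <- cpp_hough_vote(sub, dirs, basis$u, basis$v, params$dx, nrad)
    if (best[4] < params$minvotes) break
    di <- as.integer(best[1])
    d <- dirs[di, ]
    anchor <- best[2] * params$dx * basis$u[di, ] + best[3] * params$dx * basis$v[di, ]
    assigned <- which(point_line_distance(sub, anchor, d) <= params$dx)
    if (length(assigned) < 3) break
    # orthogonal-regression refit, iterated with re-assignment to a fixed
    # point so the result does not depend on the voting-grid alignment
    refit <- fit_line(sub[assigned, , drop = FALSE])
    for (pass in 1:10) {
      reassigned <- which(point_line_distance(sub, refit$center,
                                              refit$direction) <= params$dx)
      if (length(reassigned) < 3) break
      stable <- identical(reassigned, assigned)
      assigned <- reassigned
      refit <- fit_line(sub[assigned, , drop = FALSE])
      if (stable) break
    }
    if (length(assigned) < params$minvotes) break
    out[[length(out) + 1]] <- list(
      n_points = length(assigned),
      center = refit$center + centroid,
      direction = refit$direction)
    remaining <- remaining[-assigned]
  }
  out[order(-vapply(out, `[[`, numeric(1), "n_points"))]
}

#' Orient a line direction toward the screw head
#'
#' Uses the anatomical coordinate convention of the scan: the direction is
#' flipped if its dot product with the head axis is negative, so that it
#' consistently points toward the screw head. An exactly orthogonal
#' direction falls back to the next axis in a fixed order.
#'
#' @param direction Unit vector.
#' @param head_axis Unit vector pointing toward where screw heads sit
#'   (default superior, `c(0, 0, 1)`).
#' @return Unit vector, idempotent under repeated orientation.
#' @export
orient_toward_head <- function(direction, head_axis = c(0, 0, 1)) {
  fallback <- list(head_axis, c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))
  for (ax in fallback) {
    d <- sum(direction * ax)
    if (d > 0) return(direction)
    if (d < 0) return(-direction)
  }
  direction
}

#' Trace a ray to the end of the implant mask (fast voxel traversal)
#'
#' Walks the voxel grid from `start` along `direction` with the
#' Amanatides-Woo stepping scheme, visiting each crossed voxel exactly
#' once, until the contiguous foreground run containing the start voxel
#' ends. Returns the world center of the last foreground voxel — the
#' foreground-to-background switch point, i.e. the screw entry point when
#' the ray starts at the screw's center of mass and points toward its head.
#'
#' @param mask Binary [label_volume()].
#' @param start World mm point inside a foreground voxel.
#' @param direction Unit direction (world mm).
#' @return World mm point with attribute `out_of_field = TRUE` if the ray
#'   left the grid while still in foreground.
#' @export
trace_entry_point <- function(mask, start, direction) {
  sh <- vol_shape(mask)
  idx_c <- voxel_from_world(mask, start)
  ijk <- round(idx_c)
  if (any(ijk < 0) || any(ijk > sh - 1))
    stop("start point lies outside the grid")
  if (mask$values[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1] == 0)
    stop("start point is not inside a foreground voxel")
  # direction in continuous index space
  d_idx <- as.numeric(t(mask$axes) %*% direction) / mask$spacing
  stp <- sign(d_idx)
  t_delta <- ifelse(d_idx != 0, abs(1 / d_idx), Inf)
  # parametric distance to the first boundary crossing per axis
  frac <- idx_c - ijk  # in [-0.5, 0.5]
  t_max <- ifelse(d_idx > 0, (0.5 - frac) / d_idx,
                  ifelse(d_idx < 0, (-0.5 - frac) / d_idx, Inf))
  last_fg <- ijk
  out_of_field <- FALSE
  repeat {
    ax <- which.min(t_max)
    ijk[ax] <- ijk[ax] + stp[ax]
    t_max[ax] <- t_max[ax] + t_delta[ax]
    if (ijk[ax] < 0 || ijk[ax] > sh[ax] - 1) { out_of_field <- TRUE; break }
    if (mask$values[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1] == 0) break
    last_fg <- ijk
  }
  structure(world_from_voxel(mask, last_fg), out_of_field = out_of_field)
}

#' Quantify screw implants in a postoperative CT
#'
#' Composition of the three implant steps: metal thresholding (HU > 2500),
#' iterative 3D Hough line detection, and entry-point tracing by fast voxel
#' traversal, with each line direction oriented toward the screw head via
#' the anatomical head axis. One detection is returned per detected line.
#'
#' @param post_ct Postoperative CT [volume()] in HU.
#' @param params A [hough_params()].
#' @param head_axis Unit vector toward the screw heads (default superior).
#' @param hu_threshold Metal threshold (HU).
#' @return List of `screw_detection` records: `n_points`, `center` (center
#'   of mass of supporting points), `direction` (unit, toward the head),
#'   `entry_point`, `out_of_field`.
#' @export
quantify_screws <- function(post_ct, params = hough_params(),
                            head_axis = c(0, 0, 1), hu_threshold = 2500) {
  thr <- threshold_implants(post_ct, hu_threshold)
  if (nrow(thr$cloud) == 0) return(list())
  lines <- hough_lines_3d(thr$cloud, params)
  lapply(lines, function(ln) {
    dir_head <- orient_toward_head(ln$direction, head_axis)
    entry <- trace_entry_point(thr$mask, ln$center, dir_head)
    structure(list(n_points = ln$n_points, center = ln$center,
                   direction = dir_head,
                   entry_point = as.numeric(entry),
                   out_of_field = isTRUE(attr(entry, "out_of_field"))),
              class = "screw_detection")
  })
}
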