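#' Osteotomy plane
#'
#' A cut plane represented by a center point and a unit normal, both in
#' world millimetres.
#'
#' @param center World mm point.
#' @param normal Direction vector; normalized on construction.
#' @return List of class `cut_plane`.
#' @export
plane <- function(center, normal) {
  normal <- as.numeric(normal)
  n <- sqrt(sum(normal^2))
  if (n < 1e-12) stop("plane normal must be non-zero")
  structure(list(center = as.numeric(center), normal = normal / n),
            class = "cut_plane")
}

#' Signed distance of points to a plane
#'
#' Distance along the plane normal, positive on the side the normal points
#' to.
#'
#' @param pts n x 3 matrix of world mm points.
#' @param p A [plane()].
#' @return Numeric vector of signed distances (mm).
#' @export
plane_signed <- function(pts, p) {
  drop(sweep(pts, 2, p$center, `-`) %*% p$normal)
}

#' Fit a plane to 3D points by PCA
#'
#' The plane center is the centroid of the points; the normal is the
#' eigenvector of the point covariance with the smallest eigenvalue. The
#' sign of the normal is unresolved at this stage (it is fixed later by
#' orienting all four osteotomy normals toward the approximated joint
#' center, see [orient_planes()]).
#'
#' @param points n x 3 matrix of world mm points, n >= 3, not all collinear.
#' @return A [plane()].
#' @examples
#' pts <- cbind(runif(50), runif(50), 5)
#' fit_plane(pts)$normal  # +-(0, 0, 1)
#' @export
fit_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("plane fitting needs at least 3 points")
  ctr <- colMeans(points)
  q <- sweep(points, 2, ctr, `-`)
  ev <- eigen(crossprod(q) / nrow(points), symmetric = TRUE)
  if (ev$values[2] < 1e-12 * max(ev$values[1], 1))
    stop("points are collinear; plane is undefined")
  plane(ctr, ev$vectors[, 3])
}

#' Per-osteotomy cut-region segmentation
#'
#' Produces the labelled cut regions (labels 1-4, one per osteotomy) for a
#' postoperative CT. Two backends exist: `"oracle"` returns the phantom's
#' ground-truth labels (making the downstream geometry testable without
#' trained weights), `"network"` runs a trained multi-class segmenter (see
#' [train_segmenter()]) and takes the argmax over its softmax channels.
#'
#' @param post_ct Postoperative CT [volume()] (cropped frame).
#' @param backend `"oracle"` or `"network"`.
#' @param truth Phantom truth (required for the oracle backend).
#' @param model Trained segmenter handle (required for the network backend).
#' @return A [label_volume()] with labels 0-4 on the `post_ct` grid.
#' @export
segment_cut_regions <- function(post_ct, backend = c("oracle", "network"),
                                truth = NULL, model = NULL) {
  backend <- match.arg(backend)
  if (backend == "oracle") {
    if (is.null(truth)) stop("oracle backend requires phantom truth")
    return(truth$cut_labels)
  }
  if (is.null(model)) stop("network backend requires a trained segmenter")
  segment_with_network(model, post_ct)
}

#' Detect the four osteotomy planes
#'
#' Fits one plane (PCA, [fit_plane()]) to the world coordinates of the
#' voxels of each cut label. Plane fitting operates in world millimetres,
#' so anisotropic voxel spacing does not bias the normals. A cut region
#' with fewer than 3 voxels is flagged as failed; the remaining planes are
#' still returned.
#'
#' @param post_ct Postoperative CT [volume()].
#' @param backend Segmentation backend, see [segment_cut_regions()].
#' @param truth,model Passed to [segment_cut_regions()].
#' @param labels Optional precomputed cut [label_volume()] (skips
#'   segmentation).
#' @return List with `planes` (length-4 list of [plane()] or `NULL`) and
#'   `failed` (logical length 4).
#' @export
detect_planes <- function(post_ct, backend = c("oracle", "network"),
                          truth = NULL, model = NULL, labels = NULL) {
  if (is.null(labels))
    labels <- segment_cut_regions(post_ct, backend, truth = truth, model = model)
  planes <- vector("list", 4)
  failed <- logical(4)
  for (j in 1:4) {
    lin <- which(labels$values == j)
    if (length(lin) < 3) {
      failed[j] <- TRUE
      next
    }
    planes[[j]] <- fit_plane(voxel_centers(labels, lin))
  }
  list(planes = planes, failed = failed)
}
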