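#' 3D scalar volume with world geometry
#'
#' The basic container used throughout the package: a 3D array of scalars
#' (Hounsfield units or integer labels) together with the geometry that maps
#' voxel indices to world coordinates in millimetres. The mapping follows the
#' dominant medical-imaging convention: voxel indices are 0-based and a voxel
#' index maps to the *center* of that voxel,
#' `world = origin + axes %*% (spacing * index)`.
#'
#' @param values 3D numeric array.
#' @param spacing Numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin Numeric length-3, world position (mm) of the center of voxel
#'   `(0,0,0)`.
#' @param axes 3x3 direction matrix with orthonormal columns.
#' @return An object of class `postop_volume`.
#' @examples
#' v <- volume(array(0, c(8, 8, 8)), spacing = c(1, 1, 1))
#' vol_shape(v)
#' @export
volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   axes = diag(3)) {
  dm <- dim(values)
  if (length(dm) != 3L || any(dm <= 0L))
    stop("volume values must be a 3D array with positive dimensions")
  values <- as.vector(values)  # drop any foreign classes/attributes
  dim(values) <- dm
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  axes <- matrix(as.numeric(axes), 3, 3)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite numbers")
  if (max(abs(crossprod(axes) - diag(3))) > 1e-6)
    stop("axes must be orthonormal (columns unit-length and mutually orthogonal)")
  structure(list(values = values, spacing = spacing, origin = origin,
                 axes = axes),
            class = "postop_volume")
}

#' Integer label volume
#'
#' Same geometry as [volume()] but carrying non-negative integer labels.
#' Label 0 is background; for cut-region maps labels 1-4 index the four
#' osteotomies and label 5 marks pelvis bone when used as a binary mask.
#'
#' @inheritParams volume
#' @param labels Integer vector: the declared label set (including 0).
#' @return An object of classes `postop_labels`, `postop_volume`.
#' @export
label_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         axes = diag(3), labels = NULL) {
  v <- volume(values, spacing, origin, axes)
  vals <- v$values
  if (any(vals != round(vals)) || any(vals < 0))
    stop("label volume values must be non-negative integers")
  storage.mode(v$values) <- "integer"
  if (is.null(labels)) labels <- sort(unique(as.integer(vals)))
  labels <- sort(unique(as.integer(labels)))
  if (!all(unique(as.integer(vals)) %in% labels))
    stop("values contain labels outside the declared label set")
  v$labels <- labels
  class(v) <- c("postop_labels", "postop_volume")
  v
}

#' @export
print.postop_volume <- function(x, ...) {
  kind <- if (inherits(x, "postop_labels")) "label volume" else "volume"
  cat(sprintf("postop3d %s: %s voxels, spacing %s mm, origin (%s) mm\n",
              kind, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @rdname volume
#' @param x Object to test / volume whose shape is queried.
#' @export
is_volume <- function(x) inherits(x, "postop_volume")

#' @rdname volume
#' @export
is_label_volume <- function(x) inherits(x, "postop_labels")

#' @rdname volume
#' @export
vol_shape <- function(x) dim(x$values)

#' Map voxel indices to world coordinates (and back)
#'
#' Affine voxel-to-world mapping. Indices are 0-based and refer to voxel
#' centers; indices outside the grid are allowed (the mapping is affine).
#' `voxel_from_world()` is the exact inverse and returns *continuous*
#' (fractional) 0-based indices.
#'
#' @param vol A [volume()].
#' @param index Numeric vector of length 3 or an n x 3 matrix of 0-based
#'   voxel indices.
#' @return For `world_from_voxel`, world mm coordinates (same shape as
#'   input); for `voxel_from_world`, continuous 0-based indices.
#' @examples
#' v <- volume(array(0, c(4, 4, 4)), spacing = c(2, 2, 2), origin = c(10, 0, 0))
#' world_from_voxel(v, c(1, 0, 0))  # (12, 0, 0)
#' @export
world_from_voxel <- function(vol, index) {
  idx <- if (is.matrix(index)) index else matrix(index, ncol = 3)
  w <- sweep(idx, 2, vol$spacing, `*`) %*% t(vol$axes)
  w <- sweep(w, 2, vol$origin, `+`)
  if (is.matrix(index)) w else drop(w)
}

#' @rdname world_from_voxel
#' @param world Numeric vector of length 3 or an n x 3 matrix of world mm
#'   coordinates.
#' @export
voxel_from_world <- function(vol, world) {
  w <- if (is.matrix(world)) world else matrix(world, ncol = 3)
  d <- sweep(w, 2, vol$origin, `-`) %*% vol$axes  # axes orthonormal: inv = t
  idx <- sweep(d, 2, vol$spacing, `/`)
  if (is.matrix(world)) idx else drop(idx)
}

#' World coordinates of every voxel center
#'
#' @param vol A [volume()].
#' @param linear_index Optional integer vector of 1-based linear indices into
#'   the value array; default all voxels (column-major order).
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_centers <- function(vol, linear_index = NULL) {
  sh <- vol_shape(vol)
  if (is.null(linear_index)) linear_index <- seq_len(prod(sh))
  idx <- arrayInd(linear_index, sh) - 1
  world_from_voxel(vol, idx)
}

#' Resample a volume to a new grid shape
#'
#' Resamples onto `target_shape` voxels covering exactly the same physical
#' field of view (spacing is rescaled so that `shape * spacing` is
#' preserved; the world position of the field of view is unchanged). CT
#' intensities use trilinear interpolation; label volumes must use
#' nearest-neighbour.
#'
#' @param vol A [volume()] or [label_volume()].
#' @param target_shape Integer length-3, positive.
#' @param interpolation `"linear"` or `"nearest"`. Defaults to `"nearest"`
#'   for label volumes and `"linear"` otherwise.
#' @return Resampled volume of the same class.
#' @export
resample <- function(vol, target_shape,
                     interpolation = if (is_label_volume(vol)) "nearest" else "linear") {
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape <= 0L))
    stop("target_shape must be three positive integers")
  interpolation <- match.arg(interpolation, c("linear", "nearest"))
  if (is_label_volume(vol) && interpolation != "nearest")
    stop("label volumes must be resampled with nearest-neighbour interpolation")
  sh <- vol_shape(vol)
  new_spacing <- vol$spacing * sh / target_shape
  # voxel-center convention: FOV corner = origin - axes %*% (spacing/2)
  new_origin <- vol$origin + as.numeric(vol$axes %*% ((new_spacing - vol$spacing) / 2))
  # continuous source indices of the target voxel centers
  idx <- arrayInd(seq_len(prod(target_shape)), target_shape) - 1
  world <- sweep(sweep(idx, 2, new_spacing, `*`) %*% t(vol$axes), 2, new_origin, `+`)
  src <- sweep(sweep(world, 2, vol$origin, `-`) %*% vol$axes, 2, vol$spacing, `/`)
  vals <- cpp_sample_volume(vol$values, src, interpolation == "linear", NA_real_)
  # FOV identical up to rounding, so clamp-sampled edges are exact; no NAs expected
  arr <- array(vals, dim = target_shape)
  if (is_label_volume(vol))
    label_volume(arr, new_spacing, new_origin, vol$axes, labels = vol$labels)
  else
    volume(arr, new_spacing, new_origin, vol$axes)
}

#' Crop a volume to a world-space box
#'
#' Retains the voxels whose 0-based indices fall inside the axis-aligned (in
#' index space) box centered on `center` with the given half-extent. Values
#' are copied unchanged, so world coordinates of retained voxels are
#' identical before and after cropping.
#'
#' @param vol A [volume()].
#' @param center World mm point.
#' @param half_extent Numeric length 1 or 3: half-size of the crop box in mm
#'   per axis.
#' @return Cropped volume of the same class.
#' @export
crop_world <- function(vol, center, half_extent) {
  half_extent <- rep_len(as.numeric(half_extent), 3)
  if (any(half_extent <= 0)) stop("half_extent must be positive")
  c_idx <- voxel_from_world(vol, as.numeric(center))
  sh <- vol_shape(vol)
  lo <- pmax(ceiling(c_idx - half_extent / vol$spacing - 1e-9), 0)
  hi <- pmin(floor(c_idx + half_extent / vol$spacing + 1e-9), sh - 1)
  if (any(hi < lo)) stop("crop box does not intersect the volume")
  vals <- vol$values[(lo[1] + 1):(hi[1] + 1),
                     (lo[2] + 1):(hi[2] + 1),
                     (lo[3] + 1):(hi[3] + 1), drop = FALSE]
  new_origin <- world_from_voxel(vol, lo)
  if (is_label_volume(vol))
    label_volume(vals, vol$spacing, new_origin, vol$axes, labels = vol$labels)
  else
    volume(vals, vol$spacing, new_origin, vol$axes)
}

#' Min-max intensity normalization
#'
#' Rescales intensities to `[0, 1]` by the volume's minimum and maximum;
#' geometry is unchanged. Already-normalized input passes through unchanged,
#' so the operation is idempotent.
#'
#' @param vol A [volume()] with non-constant values.
#' @return Normalized volume.
#' @export
normalize_intensity <- function(vol) {
  if (is_label_volume(vol)) stop("normalize_intensity applies to intensity volumes")
  rng <- range(vol$values)
  if (rng[1] == rng[2]) stop("cannot normalize a constant volume")
  out <- vol
  out$values <- (vol$values - rng[1]) / (rng[2] - rng[1])
  out
}
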