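test_that("normalized correlation matches a direct elementwise computation", {
  ph <- small_phantom(seed = 1)
  ph2 <- small_phantom(seed = 3)
  mask <- ph$truth$pre_bone_mask
  got <- normalized_correlation(ph$pre, ph2$pre, mask)
  sel <- mask$values > 0
  f <- as.numeric(ph$pre$values[sel]); m <- as.numeric(ph2$pre$values[sel])
  n <- length(f)
  brute <- (sum(f * m) - sum(f) * sum(m) / n) /
    sqrt((sum(f^2) - sum(f)^2 / n) * (sum(m^2) - sum(m)^2 / n))
  expect_lt(abs(got - brute), 1e-12)
  expect_equal(normalized_correlation(ph$pre, ph$pre, mask), 1, tolerance = 1e-12)
  neg <- ph$pre; neg$values <- -neg$values
  expect_equal(normalized_correlation(ph$pre, neg, mask), -1, tolerance = 1e-12)
  const <- ph$pre; const$values[] <- 3
  expect_error(normalized_correlation(ph$pre, const, mask), "constant")
})

test_that("self-registration stays at the identity", {
  ph <- small_phantom(seed = 1)
  res <- register_rigid(ph$pre, ph$pre, ph$truth$pre_bone_mask,
                        registration_params(iterations = 40, sampling = 0.25))
  expect_lt(sqrt(sum(rt_translation(res$transform)^2)), 0.1)
  expect_lt(rt_rotation_angle(res$transform), 0.1)
})

test_that("a known rigid displacement is recovered from a noise-free phantom", {
  tr <- rt_axis_angle(c(0.2, 0.9, -0.4), 8, center = c(0, 0, 0),
                      translation = c(4, -3, 2))
  ph <- cached_phantom(shape = c(64, 64, 64), spacing = 2, seed = 4,
                       noise_sd = 0, n_screws = 0,
                       fragment_transform = rigid_transform(),
                       global_transform = unclass(tr))
  centroid_of <- function(mask) colMeans(voxel_centers(mask, which(mask$values > 0)))
  init <- rigid_transform(diag(3), centroid_of(ph$truth$post_bone_mask) -
                            centroid_of(ph$truth$pre_bone_mask))
  res <- register_rigid(ph$pre, ph$post, ph$truth$pre_bone_mask,
                        registration_params(sampling = 0.25), init)
  surf <- fragment_surface_points(ph$truth)
  expect_lt(registration_errors(surf, res$transform, tr), 0.5)
  # metric never degrades below its value at the initialization
  expect_gte(res$metric, res$metric_init)
})

test_that("intensities outside the mask do not steer the registration", {
  tr <- rt_axis_angle(c(0, 0, 1), 5, center = c(0, 0, 0),
                      translation = c(3, 1, -2))
  ph <- cached_phantom(shape = c(48, 48, 48), spacing = 2, seed = 6,
                       noise_sd = 0, n_screws = 0,
                       fragment_transform = rigid_transform(),
                       global_transform = unclass(tr))
  params <- registration_params(iterations = 80, sampling = 0.5)
  centroid_of <- function(mask) colMeans(voxel_centers(mask, which(mask$values > 0)))
  init <- rigid_transform(diag(3), centroid_of(ph$truth$post_bone_mask) -
                            centroid_of(ph$truth$pre_bone_mask))
  base <- register_rigid(ph$pre, ph$post, ph$truth$pre_bone_mask, params, init)
  corrupted <- ph$pre
  out_mask <- ph$truth$pre_bone_mask$values == 0
  set.seed(1)
  corrupted$values[out_mask] <- corrupted$values[out_mask] +
    rnorm(sum(out_mask), 0, 300)
  res <- register_rigid(corrupted, ph$post, ph$truth$pre_bone_mask, params, init)
  surf <- fragment_surface_points(ph$truth)
  expect_lt(registration_errors(surf, base$transform, res$transform), 0.2)
})

test_that("orient_planes flips normals toward the joint center and is idempotent", {
  # four planes boxing a cube, outward normals
  centers <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  outward <- centers
  planes <- lapply(1:4, function(i) plane(centers[i, ], outward[i, ]))
  oriented <- orient_planes(planes)
  for (i in 1:4)
    expect_equal(oriented[[i]]$normal, -outward[i, ] / sqrt(sum(outward[i, ]^2)),
                 tolerance = 1e-12)
  twice <- orient_planes(oriented)
  for (i in 1:4) {
    expect_identical(twice[[i]]$normal, oriented[[i]]$normal)
    expect_identical(oriented[[i]]$center, planes[[i]]$center)
  }
  # postcondition on phantom planes
  ph <- small_phantom(seed = 1)
  op <- orient_planes(ph$truth$planes)
  C <- attr(op, "joint_center")
  for (p in op) expect_gt(sum((C - p$center) * p$normal), 0)
})

test_that("fragment mask obeys the strict half-space rule", {
  vals <- array(1L, c(9, 9, 9))
  cube <- label_volume(vals, spacing = c(1, 1, 1), origin = c(-4, -4, -4))
  # single separating plane through the lattice
  pl <- list(plane(c(0.0, 0, 0), c(1, 0, 0)),
             plane(c(-100, 0, 0), c(1, 0, 0)),
             plane(c(0, -100, 0), c(0, 1, 0)),
             plane(c(0, 0, -100), c(0, 0, 1)))
  fm <- build_fragment_mask(cube, pl)
  # voxels with x-center exactly 0 are excluded by strict positivity
  kept <- voxel_centers(fm, which(fm$values > 0))
  expect_true(all(kept[, 1] > 0))
  expect_equal(sum(fm$values), 4 * 9 * 9)
  # permutation invariance
  fm2 <- build_fragment_mask(cube, pl[c(3, 1, 4, 2)])
  expect_identical(fm2$values, fm$values)
  expect_error(build_fragment_mask(cube, list(plane(c(100, 0, 0), c(1, 0, 0)),
                                              pl[[2]], pl[[3]], pl[[4]])),
               "empty")
})

test_that("two-stage repositioning recovers a null fragment motion", {
  ph <- cached_phantom(seed = 8, noise_sd = 0, n_screws = 0,
                       fragment_transform = rigid_transform(),
                       global_transform = unclass(rt_axis_angle(
                         c(1, 1, 0), 3, translation = c(2, -1, 1))))
  det <- detect_planes(ph$post, "oracle", truth = ph$truth)
  repo <- quantify_repositioning(ph$pre, ph$post, det$planes,
                                 ph$truth$pre_bone_mask,
                                 coarse_params = registration_params(sampling = 0.25),
                                 fine_params = fine_registration_params(sampling = 0.25),
                                 post_bone_mask = ph$truth$post_bone_mask)
  expect_lt(sqrt(sum(rt_translation(repo$T2)^2)), 0.3)
  expect_lt(rt_rotation_angle(repo$T2), 0.3)
  surf <- fragment_surface_points(ph$truth)
  expect_lt(registration_errors(surf, repo$total, ph$truth$fragment_transform),
            0.5)
})
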