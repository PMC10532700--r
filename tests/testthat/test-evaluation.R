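sphere_surface <- function(n = 4000, r = 1, seed = 12) {
  set.seed(seed)
  p <- matrix(rnorm(3 * n), ncol = 3)
  p / sqrt(rowSums(p^2)) * r
}

test_that("landmarks on a unit sphere match the analytic circle extrema", {
  surf <- sphere_surface(8000)
  # supraacetabular plane at z = 0: intersection circle is the equator; with
  # superior = +y the most superior point on it is (0, 1, 0)
  planes <- list(plane(c(0, 0, 0), c(0, 0, 1)),
                 plane(c(0, 0, 0), c(1, 0, 0)),
                 plane(c(0, 0, 0), c(0, 1, 0)),
                 plane(c(0.5, 0, 0), c(1, 0, 0)))
  axes <- anatomical_axes(left = c(1, 0, 0), posterior = c(0, 0, 1),
                          superior = c(0, 1, 0))
  lm <- landmark_points(planes, surf, axes, tol = 0.02)
  expect_false(lm$failed[1])
  expect_lt(sqrt(sum((lm$points[[1]] - c(0, 1, 0))^2)), 0.1)
  # pubic plane x = 0.5: most posterior (+z here) point of the circle is
  # (0.5, 0, sqrt(1 - 0.25))
  expect_lt(sqrt(sum((lm$points[[5]] - c(0.5, 0, sqrt(0.75)))^2)), 0.1)
})

test_that("near-parallel planes make the intersection landmarks fail loudly", {
  surf <- sphere_surface(500)
  planes <- list(plane(c(0, 0, 0), c(0, 0, 1)),
                 plane(c(0, 0, 0.1), c(0, 0, 1)),  # parallel to plane 1
                 plane(c(0, 0, 0), c(0, 1, 0)),
                 plane(c(0, 0, 0), c(1, 0, 0)))
  expect_error(landmark_points(planes, surf), "near-parallel")
  # a line whose medial coordinate is constant has no medial extremum
  planes2 <- list(plane(c(0, 0, 0), c(1, 0, 0)),
                  plane(c(0, 0, 0), c(0, 1, 0)),  # intersection = z axis
                  plane(c(0, 0, 0), c(0, 0, 1)),
                  plane(c(0.5, 0, 0), c(1, 0, 0)))
  lm <- landmark_points(planes2, surf)
  expect_true(lm$failed[2])
})

test_that("phantom landmarks sit on the bone surface near their planes", {
  ph <- small_phantom(seed = 1)
  surf <- postop3d:::surface_points_of_mask(ph$truth$post_bone_mask, 6000)
  lm <- landmark_points(orient_planes(ph$truth$planes), surf,
                        tol = sqrt(sum(ph$post$spacing^2)) / 2)
  for (j in c(1, 4, 5)) {
    if (lm$failed[j]) next
    p <- lm$points[[j]]
    plane_j <- ph$truth$planes[[c(1, 1, 2, 3, 4)[j]]]
    expect_lt(abs(sum((p - plane_j$center) * plane_j$normal)),
              sqrt(sum(ph$post$spacing^2)))
  }
})

test_that("landmarks are invariant to surface point ordering", {
  ph <- small_phantom(seed = 1)
  surf <- postop3d:::surface_points_of_mask(ph$truth$post_bone_mask, 4000)
  planes <- orient_planes(ph$truth$planes)
  lm1 <- landmark_points(planes, surf, tol = 2)
  set.seed(22)
  lm2 <- landmark_points(planes, surf[sample(nrow(surf)), ], tol = 2)
  expect_identical(lm1$failed, lm2$failed)
  for (j in 1:5) {
    if (lm1$failed[j]) next
    expect_equal(lm1$points[[j]], lm2$points[[j]], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("projected angles reproduce square geometry and the direct formula", {
  corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  pa <- projected_angles(corners)
  expect_equal(pa$SR, 90, tolerance = 1e-9)
  expect_equal(pa$RI, 90, tolerance = 1e-9)
  # points already on the plane project to themselves
  expect_equal(pa$projected, corners, tolerance = 1e-9, ignore_attr = TRUE)
  set.seed(13)
  pts <- matrix(rnorm(12, sd = 5), 4, 3)
  pa2 <- projected_angles(pts)
  v <- pa2$V
  for (k in 1:2) {
    direct <- acos(sum(v[k, ] * v[k + 1, ]) /
                     sqrt(sum(v[k, ]^2) * sum(v[k + 1, ]^2))) * 180 / pi
    expect_equal(pa2$angles[k], direct, tolerance = 1e-9)
  }
})

test_that("normal_angle is sign-agnostic and exact on known pairs", {
  expect_equal(normal_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(normal_angle(c(0, 0, 1), c(0, 0, -1)), 0)
  expect_equal(normal_angle(c(1, 0, 0), c(1, 1, 0) / sqrt(2)), 45,
               tolerance = 1e-9)
})

test_that("angle measures are invariant under a common rigid transform", {
  set.seed(14)
  pts <- matrix(rnorm(12, sd = 8), 4, 3)
  tr <- random_rigid(15)
  a <- projected_angles(pts)
  b <- projected_angles(rt_apply(tr, pts))
  expect_equal(a$angles, b$angles, tolerance = 1e-9)
  n1 <- rnorm(3); n1 <- n1 / sqrt(sum(n1^2))
  n2 <- rnorm(3); n2 <- n2 / sqrt(sum(n2^2))
  r <- rt_rotation(tr)
  expect_equal(normal_angle(n1, n2),
               normal_angle(as.numeric(r %*% n1), as.numeric(r %*% n2)),
               tolerance = 1e-9)
})

test_that("registration MAE matches per-point brute force", {
  pts <- sphere_surface(1000, r = 40, seed = 16)
  ta <- random_rigid(17)
  tb <- random_rigid(18)
  expect_equal(registration_errors(pts, ta, ta), 0)
  t1 <- rigid_transform(diag(3), c(1, 1, 0))
  t2 <- rigid_transform(diag(3), c(4, 5, 0))
  expect_equal(registration_errors(pts, t1, t2), 5, tolerance = 1e-12)
  brute <- mean(sqrt(rowSums((rt_apply(ta, pts) - rt_apply(tb, pts))^2)))
  expect_lt(abs(registration_errors(pts, ta, tb) - brute), 1e-9)
  expect_error(registration_errors(pts[0, ], ta, tb), "empty")
})

test_that("dice coefficient counts overlap and rejects empty pairs", {
  a <- array(0L, c(5, 5, 8)); a[1:4, , 1:5] <- 1L   # |A| = 100
  b <- array(0L, c(5, 5, 8)); b[1:4, , 3:7] <- 1L   # |B| = 100, overlap 60
  expect_equal(dice_coefficient(a, b), 2 * 60 / 200)
  expect_equal(dice_coefficient(a, a), 1)
  disj <- array(0L, c(5, 5, 8)); disj[5, , 8] <- 1L
  expect_equal(dice_coefficient(a, disj), 0)
  expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
  none <- array(0L, c(5, 5, 8))
  expect_error(dice_coefficient(none, none), "empty")
})

test_that("screw errors match perturbations exactly and gate matching", {
  truth <- list(
    list(direction = c(0, 0, 1), entry = c(0, 0, 10)),
    list(direction = c(0, 1, 0), entry = c(30, 0, 10)))
  expect_equal(screw_errors(truth, truth)$mean_head_mm, 0)
  expect_equal(screw_errors(truth, truth)$mean_axis_deg, 0)
  rot2 <- rt_axis_angle(c(1, 0, 0), 2)
  auto <- list(
    list(direction = as.numeric(rt_rotation(rot2) %*% c(0, 0, 1)),
         entry_point = c(0.5, 0, 10)),
    list(direction = c(0, 1, 0), entry_point = c(300, 0, 0)))  # out of gate
  se <- screw_errors(auto, truth)
  expect_equal(nrow(se$pairs), 1)
  expect_equal(se$pairs$axis_deg[1], 2, tolerance = 1e-6)
  expect_equal(se$unmatched_auto, 2L)
  expect_equal(se$unmatched_truth, 2L)
})

test_that("landmark comparison and report serialization round-trip", {
  set.seed(19)
  ref <- lapply(1:5, function(i) rnorm(3, sd = 10))
  tr <- rt_axis_angle(c(0, 0, 1), 0.5, translation = c(0.3, 0, 0))
  auto <- lapply(ref, function(p) rt_apply(tr, p))
  cmp <- compare_landmarks(auto, ref, auto_pubic_normal = c(0, 0, 1),
                           ref_pubic_normal = c(0, 1, 1) / sqrt(2))
  expect_true(all(cmp$point_dist_mm < 1))
  expect_equal(cmp$pubic_normal_angle_deg, 45, tolerance = 1e-9)
  path <- tempfile(fileext = ".json")
  write_report(cmp, path)
  back <- read_report(path)
  expect_equal(back$point_dist_mm, cmp$point_dist_mm, tolerance = 1e-12)
  expect_equal(back$sr_deviation_deg, cmp$sr_deviation_deg, tolerance = 1e-12)
  unlink(path)
})

test_that("CSV exports flatten reports and screw detections", {
  rep <- list(registration = list(coarse_mae_mm = 1.25),
              screws = list(mean_axis_deg = 0.4, per_screw = c(0.2, 0.6)))
  pr <- tempfile(fileext = ".csv")
  write_report_csv(rep, pr)
  tab <- read.csv(pr)
  expect_setequal(tab$metric, c("registration.coarse_mae_mm",
                                "screws.mean_axis_deg",
                                "screws.per_screw.1", "screws.per_screw.2"))
  expect_equal(tab$value[tab$metric == "screws.per_screw.2"], 0.6)
  det <- list(structure(list(n_points = 12, center = c(1, 2, 3),
                             direction = c(0, 0, 1),
                             entry_point = c(1, 2, 9),
                             out_of_field = FALSE), class = "screw_detection"))
  ps <- tempfile(fileext = ".csv")
  write_screws_csv(det, ps)
  stab <- read.csv(ps)
  expect_equal(stab$entry_z, 9)
  unlink(c(pr, ps))
})
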