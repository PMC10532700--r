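make_capsule_cloud <- function(center, direction, length, radius, step = 0.7) {
  u <- direction / sqrt(sum(direction^2))
  basis <- qr.Q(qr(cbind(u, diag(3)[, 1:2])))[, 2:3]
  g <- expand.grid(t = seq(-length / 2, length / 2, by = step),
                   a = seq(-radius, radius, by = step),
                   b = seq(-radius, radius, by = step))
  g <- g[g$a^2 + g$b^2 <= radius^2, ]
  sweep(outer(g$t, u) + cbind(g$a, g$b) %*% t(basis), 2, center, `+`)
}

test_that("metal thresholding is strict and enumerates voxel centers", {
  vals <- array(0, c(4, 4, 4))
  vals[1, 1, 1] <- 2600; vals[2, 1, 1] <- 2400; vals[3, 1, 1] <- 2500
  v <- volume(vals, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  thr <- threshold_implants(v)
  expect_equal(sum(thr$mask$values), 1)
  expect_equal(nrow(thr$cloud), 1)
  expect_equal(thr$cloud[1, ], c(0, 0, 0))
  # all-soft volume: empty result, no error
  soft <- volume(array(50, c(4, 4, 4)) + runif(64))
  expect_equal(nrow(threshold_implants(soft)$cloud), 0)
  # every above-threshold voxel center appears exactly once
  ph <- small_phantom(seed = 1)
  thr2 <- threshold_implants(ph$post)
  expect_equal(nrow(thr2$cloud), sum(ph$post$values > 2500))
})

test_that("a single noiseless line is recovered exactly by the Hough detector", {
  u <- c(2, -1, 2) / 3
  pts <- outer(seq(-40, 40, length.out = 1000), u) +
    matrix(c(5, 8, -4), 1000, 3, byrow = TRUE)
  det <- hough_lines_3d(pts, hough_params(nlines = 6, minvotes = 50, dx = 3))
  expect_length(det, 1)
  expect_equal(det[[1]]$n_points, 1000)
  # PCA oracle on the full cloud (sign-agnostic)
  pca_dir <- svd(scale(pts, scale = FALSE))$v[, 1]
  expect_angle_lt(det[[1]]$direction, pca_dir, 0.5)
  expect_angle_lt(det[[1]]$direction, u, 0.5)
})

test_that("two parallel capsules are separated and correctly assigned", {
  a <- make_capsule_cloud(c(0, 0, 0), c(0, 0, 1), 50, 2)
  b <- make_capsule_cloud(c(20, 0, 0), c(0, 0, 1), 50, 2)
  cloud <- rbind(a, b)
  det <- hough_lines_3d(cloud, hough_params(nlines = 6, minvotes = 50, dx = 3))
  expect_length(det, 2)
  for (ln in det) expect_angle_lt(ln$direction, c(0, 0, 1), 1)
  centers_x <- sort(vapply(det, function(l) l$center[1], numeric(1)))
  expect_equal(centers_x, c(0, 20), tolerance = 0.5)
  # nearest-line assignment oracle: supports sum to the full cloud
  expect_equal(sum(vapply(det, `[[`, numeric(1), "n_points")), nrow(cloud))
})

test_that("the vote floor suppresses small clouds", {
  set.seed(8)
  pts <- outer(seq(-20, 20, length.out = 30), c(0, 0, 1))
  det <- hough_lines_3d(pts, hough_params(nlines = 6, minvotes = 50, dx = 3))
  expect_length(det, 0)
})

test_that("iterative removal keeps supports disjoint and votes bounded", {
  ph <- study_phantom(seed = 1)
  thr <- threshold_implants(ph$post)
  det <- hough_lines_3d(thr$cloud, hough_params())
  supports <- vapply(det, `[[`, numeric(1), "n_points")
  expect_lte(sum(supports), nrow(thr$cloud))
  expect_true(all(diff(supports) <= 0))  # sorted by decreasing support
  # directions are sign-canonical (stored on one hemisphere)
  for (ln in det) {
    d <- ln$direction
    expect_true(d[3] > 0 || (d[3] == 0 && (d[2] > 0 || (d[2] == 0 && d[1] > 0))))
  }
})

test_that("orient_toward_head flips and is idempotent", {
  expect_equal(orient_toward_head(c(0, 0, -1), c(0, 0, 1)), c(0, 0, 1))
  expect_equal(orient_toward_head(c(0, 0, 1), c(0, 0, 1)), c(0, 0, 1))
  set.seed(9)
  for (i in 1:100) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    once <- orient_toward_head(d, c(0, 0, 1))
    expect_identical(orient_toward_head(once, c(0, 0, 1)), once)
  }
  # orthogonal direction falls back to the next axis in fixed order
  expect_equal(orient_toward_head(c(0, -1, 0), c(0, 0, 1)), c(0, 1, 0))
})

test_that("voxel traversal walks to the end of the foreground run", {
  vals <- array(0L, c(1, 1, 3)); vals[1, 1, ] <- 1L
  col3 <- label_volume(vals, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  entry <- trace_entry_point(col3, c(0, 0, 1), c(0, 0, 1))
  expect_equal(as.numeric(entry), c(0, 0, 2))
  # a capped column ends inside the grid without the flag
  vals4 <- array(0L, c(1, 1, 4)); vals4[1, 1, 1:3] <- 1L
  col4 <- label_volume(vals4, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  entry4 <- trace_entry_point(col4, c(0, 0, 1), c(0, 0, 1))
  expect_equal(as.numeric(entry4), c(0, 0, 2))
  expect_false(attr(entry4, "out_of_field"))
  expect_error(trace_entry_point(col3, c(0, 0, 10), c(0, 0, 1)), "outside")
  vals2 <- array(0L, c(3, 3, 3)); vals2[2, 2, 2] <- 0L; vals2[1, 1, 1] <- 1L
  bg <- label_volume(vals2)
  expect_error(trace_entry_point(bg, c(1, 1, 1), c(0, 0, 1)), "foreground")
  # ray exiting the grid while still foreground sets the flag
  exit <- trace_entry_point(col3, c(0, 0, 1), c(0, 0, -1))
  expect_equal(as.numeric(exit), c(0, 0, 0))
  expect_true(attr(exit, "out_of_field"))
  expect_true(attr(entry, "out_of_field"))  # uncapped column exits at the top
})

test_that("traversal agrees with a dense ray-marching oracle on random capsules", {
  set.seed(10)
  sh <- c(48, 48, 48)
  for (rep in 1:15) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    center <- runif(3, -6, 6)
    len <- runif(1, 18, 34)
    rad <- runif(1, 1.5, 3)
    a <- center - u * len / 2
    b <- center + u * len / 2
    idx <- arrayInd(seq_len(prod(sh)), sh) - 1
    pts <- sweep(idx, 2, c(1, 1, 1), `*`) - 23.5
    ab <- b - a
    tt <- pmin(1, pmax(0, drop(sweep(pts, 2, a) %*% ab) / sum(ab^2)))
    inside <- rowSums((sweep(pts, 2, a) - outer(tt, ab))^2) <= rad^2
    mask <- label_volume(array(as.integer(inside), sh), origin = rep(-23.5, 3))
    got <- trace_entry_point(mask, center, u)
    # oracle: march at 0.05 mm, record the last in-mask sample's voxel
    steps <- seq(0, len, by = 0.05)
    march <- outer(steps, u) + matrix(center, length(steps), 3, byrow = TRUE)
    midx <- round(voxel_from_world(mask, march))
    ok <- midx[, 1] >= 0 & midx[, 2] >= 0 & midx[, 3] >= 0 &
      midx[, 1] < sh[1] & midx[, 2] < sh[2] & midx[, 3] < sh[3]
    fg <- rep(FALSE, nrow(midx))
    fg[ok] <- mask$values[midx[ok, , drop = FALSE] + 1] > 0
    run_end <- if (any(!fg)) min(which(!fg)) - 1 else length(fg)
    oracle <- world_from_voxel(mask, midx[run_end, ])
    expect_lt(sqrt(sum((as.numeric(got) - oracle)^2)),
              sqrt(3) * 1.000001)
  }
})

test_that("end-to-end screw quantification recovers the phantom screws", {
  ph <- study_phantom(seed = 1)
  det <- quantify_screws(ph$post)
  expect_length(det, length(ph$truth$screws))
  se <- screw_errors(det, ph$truth$screws)
  expect_equal(nrow(se$pairs), length(ph$truth$screws))
  expect_lt(se$mean_head_mm, 1.32)
  expect_lt(se$mean_axis_deg, 1.1)
  # no screws -> empty list
  ph0 <- cached_phantom(shape = c(64, 64, 64), spacing = 2, seed = 5,
                        n_screws = 0)
  expect_length(quantify_screws(ph0$post), 0)
})

test_that("a distant additional screw barely changes existing detections", {
  ph <- study_phantom(seed = 1)
  base <- quantify_screws(ph$post)
  far <- ph$post
  # paint an extra axis-aligned capsule far from the others
  idx <- arrayInd(seq_len(prod(vol_shape(far))), vol_shape(far)) - 1
  pts <- sweep(sweep(idx, 2, far$spacing, `*`), 2, far$origin, `+`)
  a <- c(-52, -52, -20); b <- c(-52, -52, 30)
  ab <- b - a
  tt <- pmin(1, pmax(0, drop(sweep(pts, 2, a) %*% ab) / sum(ab^2)))
  inside <- rowSums((sweep(pts, 2, a) - outer(tt, ab))^2) <= 4
  far$values[inside] <- 3000
  more <- quantify_screws(far)
  expect_length(more, length(base) + 1)
  for (bd in base) {
    match_i <- which.min(vapply(more, function(m)
      sum((m$center - bd$center)^2), numeric(1)))
    expect_angle_lt(more[[match_i]]$direction, bd$direction, 0.2)
  }
})

test_that("line detection does not depend on point ordering", {
  a <- make_capsule_cloud(c(0, 0, 0), c(0.3, -0.2, 1), 50, 2)
  b <- make_capsule_cloud(c(25, 5, 0), c(0, 0.1, 1), 50, 2)
  cloud <- rbind(a, b)
  set.seed(21)
  shuffled <- cloud[sample(nrow(cloud)), ]
  p <- hough_params(minvotes = 50, dx = 3)
  d1 <- hough_lines_3d(cloud, p)
  d2 <- hough_lines_3d(shuffled, p)
  expect_length(d2, length(d1))
  for (k in seq_along(d1)) {
    expect_equal(d1[[k]]$n_points, d2[[k]]$n_points)
    expect_lt(normal_angle(d1[[k]]$direction, d2[[k]]$direction), 1e-6)
    expect_equal(d1[[k]]$center, d2[[k]]$center, tolerance = 1e-9)
  }
})
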