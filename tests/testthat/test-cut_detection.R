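test_that("weighted categorical cross-entropy matches hand-computed values", {
  # single voxel, two classes, uniform prediction
  expect_equal(wcce_loss(c(1, 0), c(0.5, 0.5), weights = c(1, 1)),
               -log(0.5), tolerance = 1e-9)
  # perfect prediction collapses to the clipping floor
  expect_lt(wcce_loss(c(0, 1), c(0, 1), weights = c(3, 7)), 1e-5)
  # weighting scales the per-class contributions linearly
  t2 <- rbind(c(1, 0), c(0, 1))
  p2 <- rbind(c(0.8, 0.2), c(0.3, 0.7))
  w <- c(2, 5)
  by_hand <- mean(c(-log(0.8) * 2, -log(0.7) * 5))
  expect_equal(wcce_loss(t2, p2, weights = w), by_hand, tolerance = 1e-9)
  expect_error(wcce_loss(c(1, 0), c(1, 0, 0)), "identical shapes")
})

test_that("unit weights reduce the weighted loss to plain cross-entropy", {
  set.seed(4)
  n <- 50
  p <- matrix(rexp(n * 5), n, 5)
  p <- p / rowSums(p)
  lab <- sample(1:5, n, replace = TRUE)
  tg <- matrix(0, n, 5); tg[cbind(1:n, lab)] <- 1
  plain <- mean(-log(pmax(p[cbind(1:n, lab)], 1e-7)))
  expect_lt(abs(wcce_loss(tg, p, weights = rep(1, 5)) - plain), 1e-9)
})

test_that("default cut-class weights are the published set", {
  # 5-class default emphasises the four thin cut classes over background
  set.seed(5)
  p <- matrix(1 / 5, 1, 5)
  tg <- matrix(c(0, 1, 0, 0, 0), 1)
  expect_equal(wcce_loss(tg, p), -log(0.2) * 270, tolerance = 1e-9)
})

test_that("dice-CE loss interpolates its two endpoint losses", {
  pred <- c(0.5, 0.5)
  tgt <- c(1, 0)
  ce <- -mean(log(c(0.5, 0.5)))
  dice <- 2 * 0.5 / (1 + 1 + 1e-7)
  expect_equal(dice_ce_loss(pred, tgt, alpha = 0), ce, tolerance = 1e-9)
  expect_equal(dice_ce_loss(pred, tgt, alpha = 1), 1 - dice, tolerance = 1e-9)
  expect_equal(dice_ce_loss(pred, tgt, alpha = 0.5),
               0.5 * ce + 0.5 * (1 - dice), tolerance = 1e-9)
  expect_lt(dice_ce_loss(c(0, 1, 1), c(0, 1, 1)), 1e-3)
  expect_error(dice_ce_loss(pred, tgt, alpha = 2), "alpha")
})

test_that("fit_plane recovers exact and noisy planes", {
  set.seed(6)
  flat <- cbind(runif(40, -5, 5), runif(40, -5, 5), 5)
  pl <- fit_plane(flat)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-9)
  expect_equal(pl$center[3], 5, tolerance = 1e-12)
  expect_equal(max(abs(plane_signed(flat, pl))), 0, tolerance = 1e-9)

  n_true <- c(1, 2, 2) / 3
  basis <- qr.Q(qr(cbind(n_true, diag(3)[, 1:2])))[, 2:3]
  uv <- cbind(runif(500, -20, 20), runif(500, -20, 20))
  pts <- uv %*% t(basis) + matrix(rnorm(1500, sd = 0.1), 500, 3)
  est <- fit_plane(pts)
  # independent oracle: SVD of the mean-centered points
  sv <- svd(scale(pts, scale = FALSE))
  expect_angle_lt(est$normal, sv$v[, 3], 1e-6)
  expect_angle_lt(est$normal, n_true, 1)

  expect_equal(fit_plane(rbind(pts, pts))$normal, est$normal,
               tolerance = 1e-12)
  expect_error(fit_plane(pts[1:2, ]), "at least 3")
  line_pts <- outer(1:10, c(1, 1, 1))
  expect_error(fit_plane(line_pts), "collinear")
})

test_that("fit_plane residual geometry is invariant under rigid motion", {
  set.seed(7)
  pts <- cbind(runif(100, -10, 10), runif(100, -10, 10), rnorm(100, sd = 0.3))
  tr <- random_rigid(9)
  before <- sqrt(mean(plane_signed(pts, fit_plane(pts))^2))
  moved <- rt_apply(tr, pts)
  after <- sqrt(mean(plane_signed(moved, fit_plane(moved))^2))
  expect_equal(before, after, tolerance = 1e-6)
})

test_that("oracle-label plane detection recovers phantom planes", {
  ph <- cached_phantom(shape = c(64, 64, 64), spacing = 2, seed = 2,
                       noise_sd = 0)
  det <- detect_planes(ph$post, "oracle", truth = ph$truth)
  expect_false(any(det$failed))
  for (j in 1:4) {
    expect_angle_lt(det$planes[[j]]$normal, ph$truth$planes[[j]]$normal, 2)
    offset <- abs(sum((det$planes[[j]]$center - ph$truth$planes[[j]]$center) *
                        ph$truth$planes[[j]]$normal))
    expect_lt(offset, 2)
  }
})

test_that("an erased cut region is flagged while the others are returned", {
  ph <- small_phantom(seed = 1)
  labels <- ph$truth$cut_labels
  labels$values[labels$values == 2L] <- 0L
  det <- detect_planes(ph$post, labels = labels)
  expect_identical(det$failed, c(FALSE, TRUE, FALSE, FALSE))
  expect_null(det$planes[[2]])
  expect_s3_class(det$planes[[1]], "cut_plane")
})

test_that("plane fitting works in world mm, so anisotropic grids agree", {
  ph <- cached_phantom(shape = c(64, 64, 64), spacing = 2, seed = 2,
                       noise_sd = 0)
  aniso <- resample(ph$truth$cut_labels, c(64, 32, 48), "nearest")
  det_a <- detect_planes(ph$post, labels = aniso)
  det_b <- detect_planes(ph$post, labels = ph$truth$cut_labels)
  for (j in 1:4)
    expect_angle_lt(det_a$planes[[j]]$normal, det_b$planes[[j]]$normal, 3)
})

test_that("oracle segmentation returns the truth labels with a valid codomain", {
  ph <- small_phantom(seed = 1)
  seg <- segment_cut_regions(ph$post, "oracle", truth = ph$truth)
  expect_identical(seg$values, ph$truth$cut_labels$values)
  expect_true(all(seg$values %in% 0:4))
  expect_error(segment_cut_regions(ph$post, "oracle"), "truth")
  expect_error(segment_cut_regions(ph$post, "network"), "trained")
})

test_that("plane recovery degrades gracefully when image noise doubles", {
  err_at <- function(noise) {
    errs <- c()
    for (s in 1:5) {
      ph <- cached_phantom(shape = c(64, 64, 64), spacing = 2,
                           seed = 60 + s, noise_sd = noise)
      det <- detect_planes(ph$post, "oracle", truth = ph$truth)
      for (j in 1:4)
        errs <- c(errs, normal_angle(det$planes[[j]]$normal,
                                     ph$truth$planes[[j]]$normal))
    }
    mean(errs)
  }
  e20 <- err_at(20)
  e40 <- err_at(40)
  expect_lte(e40, 2 * e20 + 1e-9)
})
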