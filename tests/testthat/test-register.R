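tetra <- function() rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.2, 0.3, 1))

test_that("kabsch recovers exact rigid motions in closed form", {
  P <- tetra()
  id <- kabsch(P, P)
  expect_lt(rotation_angle_deg(id), 1e-9)
  expect_lt(max(abs(id$T)), 1e-12)

  lift <- kabsch(P, sweep(P, 2, c(0, 0, 1), "+"))
  expect_lt(rotation_angle_deg(lift), 1e-9)
  expect_equal(lift$T, c(0, 0, 1), tolerance = 1e-12)

  Rz <- rt_axis_rotation("z", 90)
  Q <- P %*% t(Rz$R)
  got <- kabsch(P, Q)
  expect_lt(max(abs(got$R - Rz$R)), 1e-9)
  expect_lt(max(abs(Q - (P %*% t(got$R) + rep(1, 4) %o% got$T))), 1e-9)

  line <- cbind(1:4, 1:4, 1:4)
  expect_error(kabsch(line, line), "collinear")
})

test_that("kabsch beats a brute-force rotation grid search", {
  set.seed(18)
  P <- matrix(runif(30), ncol = 3)
  true_ang <- 35  # on the 5-degree grid
  Q <- P %*% t(rt_axis_rotation("z", true_ang)$R)
  got <- kabsch(P, Q)
  sse <- function(ang) {
    R <- rt_axis_rotation("z", ang)$R
    sum((Q - P %*% t(R))^2)
  }
  grid <- seq(0, 355, by = 5)
  best_grid <- grid[which.min(sapply(grid, sse))]
  expect_equal(best_grid, true_ang)
  # closed form at least as good as the best grid rotation
  fit_sse <- sum((Q - (P %*% t(got$R) + rep(1, 10) %o% got$T))^2)
  expect_lte(fit_sse, min(sapply(grid, sse)) + 1e-12)
})

test_that("feature matching identifies corresponding points", {
  surf <- make_sheep_surface(sheep_params(seed = 3), density = 900)$cloud
  n <- n_points(surf)
  self <- match_features(surf, surf)
  expect_gt(nrow(self), 0.7 * n)
  expect_gt(mean(self$src == self$dst), 0.9)

  rt <- random_rt(4, max_angle_deg = 25, max_trans = 0.2)
  moved <- transform_cloud(surf, rt)
  m <- match_features(surf, moved)
  expect_gt(nrow(m), 100)
  expect_gt(mean(m$src == m$dst), 0.9)  # true map is the identity pairing

  unrelated <- rand_cloud(500, seed = 77)
  u <- match_features(surf, unrelated)
  expect_lt(nrow(u), nrow(m) / 2)
})

test_that("coarse RANSAC recovers transforms and rejects mismatches", {
  set.seed(23)
  src <- point_cloud(matrix(runif(60, -0.5, 0.5), ncol = 3))
  rt <- random_rt(9)
  dst <- transform_cloud(src, rt)
  corr <- data.frame(src = 1:20, dst = 1:20)
  res <- ransac_coarse(src, dst, corr, seed = 5)
  expect_true(res$converged)
  expect_lt(res$k_mse, 1e-18)
  expect_lt(max(abs(res$transform$R - rt$R)), 1e-9)
  expect_lt(max(abs(res$transform$T - rt$T)), 1e-9)

  # 20 true pairs + 10 random mismatches
  corr_bad <- rbind(corr, data.frame(src = 1:10, dst = sample(11:20)))
  res2 <- ransac_coarse(src, dst, corr_bad, seed = 5)
  expect_lt(max(abs(res2$transform$R - rt$R)), 1e-6)
  expect_lt(max(abs(res2$transform$T - rt$T)), 1e-6)
  expect_equal(res2$n_consensus, 20)  # mismatches excluded from consensus

  # all pairs mismatched: best-effort answer flagged as not converged
  corr_rand <- data.frame(src = 1:15, dst = c(8:15, 1:7))
  res3 <- ransac_coarse(src, dst, corr_rand, t_iters = 50, seed = 5)
  expect_false(res3$converged)
  expect_gt(res3$k_mse, 1e-4)

  expect_error(ransac_coarse(src, dst, corr[1:2, ]), "at least 3")
})

test_that("icp converges with a non-increasing objective", {
  surf <- make_sheep_surface(sheep_params(seed = 5), density = 1200)$cloud
  same <- icp(surf, surf)
  expect_true(same$converged)
  expect_lt(same$mse_history[length(same$mse_history)], 1e-12)

  shifted <- transform_cloud(surf, rigid_transform(diag(3), c(0.05, 0, 0)))
  res <- icp(surf, shifted)
  expect_true(res$converged)
  expect_lt(max(abs(res$transform$T - c(0.05, 0, 0))), 1e-6)
  expect_lt(rotation_angle_deg(res$transform), 1e-4)
  expect_true(all(diff(res$mse_history) <= 1e-12))

  # partial overlap: 30% of the source cropped, 10-degree rotation
  rt <- rt_axis_rotation("z", 10)
  dst <- transform_cloud(surf, rt)
  crop <- cloud_subset(surf, surf$points[, 1] > quantile(surf$points[, 1], 0.3))
  res2 <- icp(crop, dst, init = rt_axis_rotation("z", 5))
  err <- rt_compose(rt_invert(rt), res2$transform)
  expect_lt(rotation_angle_deg(err), 0.5)
})

test_that("coarse-then-fine needs fewer icp iterations than cold start", {
  surf <- make_sheep_surface(sheep_params(seed = 8), density = 1200)$cloud
  rt <- rt_axis_rotation("z", 20)
  dst <- transform_cloud(surf, rt)
  corr <- match_features(surf, dst)
  coarse <- ransac_coarse(surf, dst, corr, seed = 2)
  warm <- icp(surf, dst, init = coarse$transform)
  cold <- icp(surf, dst, init = rt_identity())
  expect_true(warm$converged)
  expect_lte(warm$n_iters, cold$n_iters)
})

test_that("three views merge into the reference frame", {
  # aligned views with calibration init: near-identity transforms
  sc <- make_scene(scene = scene_params(noise_sigma = 0, outlier_count = 0,
                                        clutter_count = 0, tilt_deg = 0,
                                        calib_rot_sd_deg = 0,
                                        calib_trans_sd_m = 0),
                   seed = 19)
  views <- lapply(names(sc$views), function(nm) {
    v <- transform_cloud(sc$views[[nm]], sc$cameras[[nm]]$pose, "world")
    cloud_subset(v, v$attrs$label == "body")
  })
  names(views) <- names(sc$views)
  reg <- register_views(views, init = list(side = rt_identity(),
                                           front = rt_identity()))
  for (nm in c("side", "front")) {
    expect_lt(rotation_angle_deg(reg$transforms[[nm]]), 1)
    # point-to-point ICP on disjoint samplings drifts by about the
    # inter-sampling spacing; near-identity at that scale
    expect_lt(sqrt(sum(reg$transforms[[nm]]$T^2)), 6e-3)
  }
  expect_equal(n_points(reg$merged), sum(sapply(views, n_points)))
  expect_equal(sort(unique(reg$merged$attrs$view_id)), 1:3)

  # the no-init path: feature matching + coarse RANSAC on rigidly moved
  # full-overlap views
  base <- views$top
  rt_s <- random_rt(41, 20, 0.2)
  rt_f <- random_rt(42, 20, 0.2)
  views2 <- list(top = base,
                 side = transform_cloud(base, rt_invert(rt_s)),
                 front = transform_cloud(base, rt_invert(rt_f)))
  reg2 <- register_views(views2,
                         coarse_params = list(seed = 11),
                         icp_params = list(trust_rot_deg = 45,
                                           trust_trans = 0.5,
                                           max_corr_dist = Inf))
  for (nm in c("side", "front")) {
    rt_true <- if (nm == "side") rt_s else rt_f
    err <- rt_compose(rt_invert(rt_true), reg2$transforms[[nm]])
    expect_lt(rotation_angle_deg(err), 0.5)
    expect_lt(sqrt(sum(err$T^2)), 1e-3)
  }
})
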