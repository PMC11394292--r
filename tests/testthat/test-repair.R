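test_that("a straight line is its own natural spline", {
  xs <- seq(0, 4, length.out = 7)
  sp <- fit_cubic_spline(xs, 2 * xs + 1)
  i <- seq_len(6)
  expect_lt(max(abs(sp$c[i])), 1e-10)
  expect_lt(max(abs(sp$d[i])), 1e-10)
  expect_equal(sp$b[i], rep(2, 6), tolerance = 1e-10)
})

test_that("the spline solves the natural tridiagonal system", {
  # independent oracle: assemble and solve the dense system for the knot
  # second derivatives, then evaluate piecewise
  natural_oracle <- function(xs, ys, x_eval) {
    n <- length(xs); h <- diff(xs)
    A <- diag(n); rhs <- numeric(n)
    for (i in 2:(n - 1)) {
      A[i, i - 1] <- h[i - 1]
      A[i, i] <- 2 * (h[i - 1] + h[i])
      A[i, i + 1] <- h[i]
      rhs[i] <- 6 * ((ys[i + 1] - ys[i]) / h[i] - (ys[i] - ys[i - 1]) / h[i - 1])
    }
    M <- solve(A, rhs)
    sapply(x_eval, function(x) {
      i <- max(1, min(n - 1, findInterval(x, xs)))
      t <- x - xs[i]
      b <- (ys[i + 1] - ys[i]) / h[i] - h[i] * (2 * M[i] + M[i + 1]) / 6
      ys[i] + b * t + M[i] / 2 * t^2 + (M[i + 1] - M[i]) / (6 * h[i]) * t^3
    })
  }
  sp <- fit_cubic_spline(c(0, 1, 2), c(0, 1, 0))
  expect_equal(eval_spline(sp, c(0, 1, 2)), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(eval_spline(sp, 0.5), natural_oracle(c(0, 1, 2), c(0, 1, 0), 0.5),
               tolerance = 1e-12)

  set.seed(6)
  for (trial in 1:5) {
    xs <- sort(runif(8)); ys <- rnorm(8)
    if (min(diff(xs)) < 1e-3) next
    sp <- fit_cubic_spline(xs, ys)
    xe <- runif(20, min(xs), max(xs))
    expect_equal(eval_spline(sp, xe), natural_oracle(xs, ys, xe),
                 tolerance = 1e-9)
    # cross-check against the independent reference implementation
    expect_equal(eval_spline(sp, xe),
                 stats::splinefun(xs, ys, method = "natural")(xe),
                 tolerance = 1e-9)
    expect_equal(eval_spline(sp, xs), ys, tolerance = 1e-12)
  }
})

test_that("adjacent spline segments join with C2 continuity", {
  set.seed(14)
  xs <- sort(runif(9, 0, 5)); ys <- rnorm(9)
  sp <- fit_cubic_spline(xs, ys)
  for (i in 2:8) {
    h <- xs[i] - xs[i - 1]
    val_l <- sp$a[i - 1] + sp$b[i - 1] * h + sp$c[i - 1] * h^2 + sp$d[i - 1] * h^3
    d1_l <- sp$b[i - 1] + 2 * sp$c[i - 1] * h + 3 * sp$d[i - 1] * h^2
    d2_l <- 2 * sp$c[i - 1] + 6 * sp$d[i - 1] * h
    expect_equal(val_l, sp$a[i], tolerance = 1e-9)
    expect_equal(d1_l, sp$b[i], tolerance = 1e-9)
    expect_equal(d2_l, 2 * sp$c[i], tolerance = 1e-9)
  }
  expect_error(fit_cubic_spline(c(0, 0, 1), 1:3), "increasing")
  expect_error(fit_cubic_spline(c(0, 1), c(0, 1)), "3 knots")
})

test_that("holes are found where the sampled surface is missing", {
  one <- holey_grid(disks = list(c(0.5, 0.5, 0.1)))
  p <- detect_holes(one)
  expect_length(p, 1)
  # rim points sit just outside the deleted disk
  rim <- one$points[p[[1]]$boundary_idx, , drop = FALSE]
  r <- sqrt((rim[, 1] - 0.5)^2 + (rim[, 2] - 0.5)^2)
  expect_true(all(r >= 0.1 - 1e-9))
  expect_true(all(r <= 0.1 + 3 * 0.04))

  expect_length(detect_holes(holey_grid()), 0)
  two <- holey_grid(disks = list(c(0.3, 0.3, 0.09), c(0.72, 0.72, 0.09)))
  expect_length(detect_holes(two), 2)
})

test_that("fill points restore a plane exactly and never disturb the input", {
  cl <- holey_grid(disks = list(c(0.5, 0.5, 0.1)))
  p <- detect_holes(cl)
  out <- fill_hole(cl, p[[1]])
  n0 <- n_points(cl)
  expect_gte(n_points(out), n0)
  expect_equal(out$points[seq_len(n0), ], cl$points)  # originals untouched
  new <- out$points[out$attrs$repaired == 1, , drop = FALSE]
  expect_gt(nrow(new), 0)
  expect_lt(max(abs(new[, 3] - 0.2)), 1e-9)  # coplanar with the sheet
  # fill points stay inside the rim ring
  r <- sqrt((new[, 1] - 0.5)^2 + (new[, 2] - 0.5)^2)
  expect_true(all(r <= 0.1 + 0.05))
})

test_that("fill follows a curved analytic surface to within a centimetre", {
  g <- expand.grid(x = seq(0, 1, 0.015), y = seq(0, 1, 0.015))
  keep <- (g$x - 0.5)^2 + (g$y - 0.5)^2 > 0.08^2
  cl <- point_cloud(cbind(g$x[keep], g$y[keep], 0.1 * sin(5 * g$x[keep])))
  p <- detect_holes(cl)
  expect_length(p, 1)
  out <- fill_hole(cl, p[[1]], spacing = 0.01)
  new <- out$points[out$attrs$repaired == 1, , drop = FALSE]
  expect_gt(nrow(new), 50)
  expect_lt(max(abs(new[, 3] - 0.1 * sin(5 * new[, 1]))), 1e-2)
  # fill height stays within the smooth range spanned by the rim
  rim_z <- cl$points[p[[1]]$boundary_idx, 3]
  pad <- 0.2 * diff(range(rim_z))
  expect_true(all(new[, 3] >= min(rim_z) - pad & new[, 3] <= max(rim_z) + pad))
  # filled density comparable to the rim density (within 2x)
  rim_density <- 1 / ovicloud:::median_nn_dist(
    cl$points[p[[1]]$boundary_idx, , drop = FALSE])^2
  fill_density <- 1 / ovicloud:::median_nn_dist(new)^2
  expect_gt(fill_density, rim_density / 4)
  expect_lt(fill_density, rim_density * 4)
})

test_that("tiny rims are skipped with a warning", {
  cl <- holey_grid(disks = list(c(0.5, 0.5, 0.1)))
  patch <- structure(list(boundary_idx = 1:3,
                          plane = list(origin = c(0, 0, 0.2), basis = diag(3)),
                          n_cells = 1),
                     class = "hole_patch")
  expect_warning(out <- fill_hole(cl, patch), "skipped")
  expect_equal(n_points(out), n_points(cl))
})

test_that("repair_cloud flags every appended point", {
  cl <- holey_grid(disks = list(c(0.5, 0.5, 0.1)))
  out <- repair_cloud(cl)
  expect_true("repaired" %in% names(out$attrs))
  n_new <- sum(out$attrs$repaired == 1)
  expect_equal(n_points(out), n_points(cl) + n_new)
  expect_gt(n_new, 0)
})
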