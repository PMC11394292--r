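# Shared fixtures, built in code at test time.

# uniform random cloud in a box
rand_cloud <- function(n, lo = 0, hi = 1, seed = 1) {
  set.seed(seed)
  point_cloud(matrix(runif(3 * n, lo, hi), ncol = 3))
}

# the 8 corners of the unit cube
cube_corners <- function() {
  point_cloud(as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1)))
}

# a rigid transform from axis-angle + translation
random_rt <- function(seed, max_angle_deg = 30, max_trans = 0.3) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, -max_angle_deg, max_angle_deg) * pi / 180
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  rigid_transform(R, runif(3, -max_trans, max_trans))
}

# regular planar grid with optional disk(s) removed, at height z
holey_grid <- function(spacing = 0.02, z = 0.2, disks = list()) {
  g <- expand.grid(x = seq(0, 1, spacing), y = seq(0, 1, spacing))
  keep <- rep(TRUE, nrow(g))
  for (d in disks) keep <- keep & ((g$x - d[1])^2 + (g$y - d[2])^2 > d[3]^2)
  point_cloud(cbind(g$x[keep], g$y[keep], z))
}

# multiset equality of two point sets to a tolerance
expect_same_points <- function(a, b, tol = 1e-9) {
  expect_equal(nrow(a), nrow(b))
  oa <- a[order(a[, 1], a[, 2], a[, 3]), , drop = FALSE]
  ob <- b[order(b[, 1], b[, 2], b[, 3]), , drop = FALSE]
  expect_lt(max(abs(oa - ob)), tol)
}

# the packaged reference body-length table (tape, point-cloud, printed error)
reference_table_printed_errors <- function() {
  c(1.7, 1.3, 0.1, 0.8, 1.0, 0.3, 0.1, 1.0, 1.3, 0.4,
    0.2, 1.1, 0.9, 0.3, 0.8, 1.4, 1.1, 0.5, 0.5, 1.1)
}
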