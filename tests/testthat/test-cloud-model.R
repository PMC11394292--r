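test_that("ASCII PLY parses in declared order and round-trips", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 3",
               "property float x", "property float y", "property float z",
               "end_header",
               "0 0 0", "1 0 0", "0 1 0"), f)
  pc <- read_cloud(f)
  expect_equal(n_points(pc), 3)
  expect_equal(pc$points[2, ], c(x = 1, y = 0, z = 0))

  cl <- rand_cloud(50, seed = 3)
  cl$attrs$view_id <- rep(2, 50)
  for (fmt in c("ply", "pcd", "xyz")) {
    g <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_cloud(cl, g)
    back <- read_cloud(g)
    expect_lt(max(abs(back$points - cl$points)), 1e-6)
    if (fmt == "ply") {
      expect_true("view_id" %in% names(back$attrs))
      expect_equal(back$attrs$view_id, cl$attrs$view_id)
      expect_true(any(grepl("property float view_id", readLines(g))))
    }
  }
})

test_that("PCD emits a version .7 ASCII header", {
  f <- withr::local_tempfile(fileext = ".pcd")
  write_cloud(rand_cloud(5), f)
  hdr <- readLines(f)
  expect_true("VERSION .7" %in% hdr)
  expect_true(any(grepl("^FIELDS x y z", hdr)))
  expect_true("DATA ascii" %in% hdr)
})

test_that("empty clouds and XYZ cube corners round-trip", {
  f <- withr::local_tempfile(fileext = ".ply")
  write_cloud(point_cloud(matrix(numeric(0), ncol = 3)), f)
  expect_equal(n_points(read_cloud(f)), 0)

  g <- withr::local_tempfile(fileext = ".xyz")
  write_cloud(cube_corners(), g)
  bb <- bounding_box(read_cloud(g))
  expect_equal(bb$min_corner, c(x = 0, y = 0, z = 0))
  expect_equal(bb$max_corner, c(x = 1, y = 1, z = 1))
})

test_that("malformed and binary dialect inputs fail loudly", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format binary_little_endian 1.0", "element vertex 1",
               "property float x", "property float y", "property float z",
               "end_header", "junk"), f)
  expect_error(read_cloud(f), "dialect")

  g <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 2",
               "property float x", "property float y", "property float z",
               "end_header", "0 0 0", "0 bad 0"), g)
  expect_error(read_cloud(g), "line 9")

  h <- withr::local_tempfile(fileext = ".pcd")
  writeLines(c("FIELDS x y z", "POINTS 1", "DATA binary", "xx"), h)
  expect_error(read_cloud(h), "dialect")
})

test_that("depth back-projection follows the pinhole model", {
  cam <- camera_model(width = 5, height = 5)
  d <- matrix(0, 5, 5)
  d[3, 3] <- 900  # principal ray
  pc <- depth_to_cloud(d, cam)
  expect_equal(n_points(pc), 1)
  expect_equal(as.numeric(pc$points), c(0, 0, 0.9), tolerance = 1e-12)

  expect_equal(n_points(depth_to_cloud(matrix(0, 5, 5), cam)), 0)

  # hand-computed tan-projection oracle for 4 off-centre pixels
  d2 <- matrix(0, 5, 5)
  px <- rbind(c(1, 1, 800), c(2, 5, 1200), c(5, 3, 2000), c(4, 4, 950))
  for (i in 1:4) d2[px[i, 1], px[i, 2]] <- px[i, 3]
  pc2 <- depth_to_cloud(d2, cam)
  expect_equal(n_points(pc2), 4)
  fx <- (5 / 2) / tan(70 * pi / 360)
  fy <- (5 / 2) / tan(60 * pi / 360)
  for (i in 1:4) {
    z <- px[i, 3] / 1000
    expected <- c((px[i, 2] - 3) / fx * z, (px[i, 1] - 3) / fy * z, z)
    j <- which.min(abs(pc2$points[, 3] - z))
    expect_lt(max(abs(pc2$points[j, ] - expected)), 1e-9)
  }

  # point count equals in-range nonzero pixels
  set.seed(4)
  d3 <- matrix(sample(c(0, 300, 900, 5000), 25, replace = TRUE), 5, 5)
  expect_equal(n_points(depth_to_cloud(d3, cam)), sum(d3 == 900))

  expect_error(depth_to_cloud(matrix(0, 4, 5), cam), "4x5")
})

test_that("rigid transforms behave as a group action", {
  cl <- rand_cloud(40, seed = 9)
  expect_equal(transform_cloud(cl, rt_identity())$points, cl$points)
  moved <- transform_cloud(point_cloud(c(0, 0, 0)),
                           rigid_transform(diag(3), c(1, 0, 0)))
  expect_equal(as.numeric(moved$points), c(1, 0, 0))

  rt <- random_rt(5)
  round_trip <- transform_cloud(transform_cloud(cl, rt),
                                rt_compose(rt_invert(rt), rt_identity()))
  expect_lt(max(abs(round_trip$points - cl$points)), 1e-9)

  # isometry: pairwise distances preserved
  d0 <- dist(cl$points)
  d1 <- dist(transform_cloud(cl, rt)$points)
  expect_lt(max(abs(d0 - d1) / pmax(d0, 1e-12)), 1e-9)

  expect_error(rigid_transform(matrix(1, 3, 3), c(0, 0, 0)), "orthonormal")
  expect_error(rigid_transform(diag(c(1, 1, -1)), c(0, 0, 0)), "det")
})

test_that("bounding boxes match a brute-force min/max loop", {
  bb <- bounding_box(cube_corners())
  expect_equal(unname(bb$min_corner), c(0, 0, 0))
  expect_equal(unname(bb$max_corner), c(1, 1, 1))

  p <- point_cloud(c(0.3, -0.2, 5))
  bb1 <- bounding_box(p)
  expect_equal(unname(bb1$min_corner), unname(bb1$max_corner))

  cl <- rand_cloud(100, -2, 3, seed = 11)
  bb2 <- bounding_box(cl)
  lo <- c(Inf, Inf, Inf); hi <- -lo
  for (i in 1:100) {
    lo <- pmin(lo, cl$points[i, ])
    hi <- pmax(hi, cl$points[i, ])
  }
  expect_equal(unname(bb2$min_corner), unname(lo))
  expect_equal(unname(bb2$max_corner), unname(hi))

  expect_error(bounding_box(point_cloud(matrix(numeric(0), ncol = 3))), "empty")
})

test_that("depth grids read from PGM and plain text", {
  f <- withr::local_tempfile(fileext = ".pgm")
  writeLines(c("P2", "3 2 65535", "0 100 200", "300 400 500"), f)
  m <- read_depth_grid(f)
  expect_equal(dim(m), c(2, 3))
  expect_equal(m[2, 1], 300)

  g <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 100 200", "300 400 500"), g)
  expect_equal(read_depth_grid(g), m)
})
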