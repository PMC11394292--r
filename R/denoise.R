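#' Passthrough filter
#'
#' Keeps exactly the points whose coordinate on one axis lies in the closed
#' interval `[lo, hi]`; the first stage of denoising, used to crop the region
#' of interest (the restraining-pen interior) out of the raw capture.
#'
#' @param cloud a [point_cloud()].
#' @param axis one of "x", "y", "z".
#' @param lo,hi interval bounds in metres, `lo <= hi`.
#' @return the filtered `point_cloud` (input order preserved).
#' @export
passthrough <- function(cloud, axis = c("x", "y", "z"), lo, hi) {
  axis <- match.arg(axis)
  if (lo > hi) stop("lo must be <= hi")
  v <- cloud$points[, axis]
  cloud_subset(cloud, v >= lo & v <= hi)
}

#' Crop a cloud to a box
#'
#' Convenience composition of three [passthrough()] filters.
#'
#' @param cloud a [point_cloud()].
#' @param box a [bbox()].
#' @return the cropped `point_cloud`.
#' @export
passthrough_box <- function(cloud, box) {
  stopifnot(inherits(box, "bounding_box"))
  for (i in 1:3) {
    cloud <- passthrough(cloud, c("x", "y", "z")[i],
                         box$min_corner[i], box$max_corner[i])
  }
  cloud
}

#' Statistical outlier removal
#'
#' For every point the characteristic distance is the mean Euclidean distance
#' to its `k` nearest neighbours (self excluded). Points whose characteristic
#' distance exceeds the global mean plus `r_sigma` standard deviations are
#' removed. The default multiplier `r_sigma = 0.6` removes isolated sensor
#' noise while keeping the body surface intact; larger values remove fewer
#' points.
#'
#' @param cloud a [point_cloud()] with more than `k` points.
#' @param k neighbour count (default 50).
#' @param r_sigma standard-deviation multiplier R (default 0.6).
#' @return a list with `cloud` (points kept), `removed` (logical mask over
#'   the input) and `char_dist` (the characteristic distances).
#' @export
statistical_outlier_removal <- function(cloud, k = 50, r_sigma = 0.6) {
  stopifnot(inherits(cloud, "point_cloud"), k >= 1, r_sigma > 0)
  n <- n_points(cloud)
  if (n <= k) stop("need more than k = ", k, " points, got ", n)
  nn <- cpp_knn(cloud$points, cloud$points, as.integer(k + 1))
  d <- rowMeans(nn$dist[, -1, drop = FALSE])  # first neighbour is the point itself
  mu <- mean(d)
  sigma <- sd(d)
  removed <- d > mu + r_sigma * sigma
  list(cloud = cloud_subset(cloud, !removed), removed = removed, char_dist = d)
}

#' Plane model
#'
#' Unit normal `n` and offset `c` describing the plane `n . x + c = 0`,
#' with the inlier bookkeeping of the RANSAC fit.
#' @name plane_model
NULL

plane_from_points <- function(p1, p2, p3) {
  n <- crossprod3(p2 - p1, p3 - p1)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) return(NULL)  # collinear sample
  n <- n / nn
  list(normal = n, offset = -sum(n * p1))
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

plane_distances <- function(points, plane) {
  as.numeric(points %*% plane$normal) + plane$offset
}

# Least-squares plane through a point set: centroid + smallest principal axis.
fit_plane_lsq <- function(points) {
  ctr <- colMeans(points)
  e <- eigen(cov(points), symmetric = TRUE)
  n <- e$vectors[, 3]
  if (n[3] < 0) n <- -n  # canonical orientation: normal points up
  list(normal = n, offset = -sum(n * ctr))
}

#' RANSAC plane segmentation
#'
#' Repeatedly samples three non-collinear points, forms their plane and
#' counts points within distance `alpha` of it as inliers; the plane with the
#' most inliers wins (first-found on ties) and is refit to its inliers by
#' least squares. Runs exactly `k_iters` trials (no early exit). Defaults
#' `alpha = 0.02` m and `k_iters = 550` are the settings that remove the
#' ground plane cleanly without eating into the animal's legs.
#'
#' @param cloud a [point_cloud()] with at least 3 non-collinear points.
#' @param alpha inlier distance threshold in metres.
#' @param k_iters number of RANSAC iterations.
#' @param seed optional integer seed for reproducible sampling.
#' @return an object of class `plane_model`: `normal` (unit 3-vector, z >= 0),
#'   `offset` (m), `inlier_mask` (logical over the input), `n_inliers`.
#' @export
ransac_plane <- function(cloud, alpha = 0.02, k_iters = 550, seed = NULL) {
  stopifnot(inherits(cloud, "point_cloud"), alpha > 0, k_iters >= 1)
  n <- n_points(cloud)
  if (n < 3) stop("need at least 3 points")
  pts <- cloud$points
  with_seed(seed, {
    best <- NULL
    best_count <- -1L
    degenerate <- 0L
    for (it in seq_len(k_iters)) {
      plane <- NULL
      for (try in 1:10) {  # resample on collinear triples
        s <- sample.int(n, 3)
        plane <- plane_from_points(pts[s[1], ], pts[s[2], ], pts[s[3], ])
        if (!is.null(plane)) break
      }
      if (is.null(plane)) { degenerate <- degenerate + 1L; next }
      count <- sum(abs(plane_distances(pts, plane)) < alpha)
      if (count > best_count) {
        best_count <- count
        best <- plane
      }
    }
    if (is.null(best)) stop("degenerate geometry: all sampled triples collinear")
    mask <- abs(plane_distances(pts, best)) < alpha
    if (sum(mask) >= 3) {
      refit <- fit_plane_lsq(pts[mask, , drop = FALSE])
      mask2 <- abs(plane_distances(pts, refit)) < alpha
      if (sum(mask2) >= 3) { best <- refit; mask <- mask2 }
    }
    if (best$normal[3] < 0) {
      best$normal <- -best$normal
      best$offset <- -best$offset
    }
    structure(list(normal = best$normal, offset = best$offset,
                   inlier_mask = mask, n_inliers = sum(mask),
                   alpha = alpha),
              class = "plane_model")
  })
}

#' @export
print.plane_model <- function(x, ...) {
  cat(sprintf("<plane_model> normal (%.4f, %.4f, %.4f), offset %.4f m, %d inliers\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset, x$n_inliers))
  invisible(x)
}

#' Remove the ground plane
#'
#' Segments the dominant plane with [ransac_plane()] and drops its inliers.
#' As a safety guard the cloud is returned unchanged (with a warning) when
#' the plane claims more than `max_inlier_frac` of the points, which signals
#' a degenerate scene rather than a ground plane under an animal.
#'
#' @inheritParams ransac_plane
#' @param max_inlier_frac refuse to remove a plane larger than this fraction.
#' @return the `point_cloud` without ground inliers, with the fitted
#'   `plane_model` attached as attribute `"plane"`.
#' @export
remove_ground <- function(cloud, alpha = 0.02, k_iters = 550, seed = NULL,
                          max_inlier_frac = 0.9) {
  plane <- ransac_plane(cloud, alpha = alpha, k_iters = k_iters, seed = seed)
  if (mean(plane$inlier_mask) > max_inlier_frac) {
    warning("dominant plane holds > ", round(100 * max_inlier_frac),
            "% of the cloud; refusing to remove it")
    out <- cloud
  } else {
    out <- cloud_subset(cloud, !plane$inlier_mask)
  }
  attr(out, "plane") <- plane
  out
}
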