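#' Fit a cubic interpolation spline
#'
#' Piecewise cubic `S_i(x) = a_i + b_i (x - x_i) + c_i (x - x_i)^2 +
#' d_i (x - x_i)^3` through the knots, C2-continuous, with natural boundary
#' conditions (zero second derivative at both ends) by default or clamped
#' first derivatives. Solved with the standard tridiagonal (Thomas)
#' elimination for the knot second derivatives.
#'
#' @param xs strictly increasing knot abscissas, length >= 3.
#' @param ys knot values, same length.
#' @param bc `"natural"` or `"clamped"`.
#' @param deriv_ends for `bc = "clamped"`, the end first derivatives.
#' @return an object of class `cubic_spline`: a data frame of segments with
#'   columns `x`, `a`, `b`, `c`, `d` (one row per interval plus the final
#'   knot row carrying only `x` and `a`).
#' @seealso [eval_spline()]
#' @export
fit_cubic_spline <- function(xs, ys, bc = c("natural", "clamped"),
                             deriv_ends = c(0, 0)) {
  bc <- match.arg(bc)
  n <- length(xs)
  if (n < 3) stop("need at least 3 knots")
  if (length(ys) != n) stop("xs and ys lengths differ")
  if (any(diff(xs) <= 0)) stop("xs must be strictly increasing")
  h <- diff(xs)
  slope <- diff(ys) / h
  # Tridiagonal system for second derivatives M_i at the knots.
  lower <- numeric(n); diagv <- numeric(n); upper <- numeric(n); rhs <- numeric(n)
  if (bc == "natural") {
    diagv[1] <- 1; upper[1] <- 0; rhs[1] <- 0
    diagv[n] <- 1; lower[n] <- 0; rhs[n] <- 0
  } else {
    diagv[1] <- 2 * h[1]; upper[1] <- h[1]
    rhs[1] <- 6 * (slope[1] - deriv_ends[1])
    diagv[n] <- 2 * h[n - 1]; lower[n] <- h[n - 1]
    rhs[n] <- 6 * (deriv_ends[2] - slope[n - 1])
  }
  for (i in 2:(n - 1)) {
    lower[i] <- h[i - 1]
    diagv[i] <- 2 * (h[i - 1] + h[i])
    upper[i] <- h[i]
    rhs[i] <- 6 * (slope[i] - slope[i - 1])
  }
  # Thomas elimination
  for (i in 2:n) {
    w <- lower[i] / diagv[i - 1]
    diagv[i] <- diagv[i] - w * upper[i - 1]
    rhs[i] <- rhs[i] - w * rhs[i - 1]
  }
  M <- numeric(n)
  M[n] <- rhs[n] / diagv[n]
  for (i in (n - 1):1) M[i] <- (rhs[i] - upper[i] * M[i + 1]) / diagv[i]
  i <- seq_len(n - 1)
  seg <- data.frame(
    x = xs,
    a = ys,
    b = c(slope - h * (2 * M[i] + M[i + 1]) / 6, NA),
    c = M / 2,
    d = c((M[i + 1] - M[i]) / (6 * h), NA))
  structure(seg, class = c("cubic_spline", "data.frame"))
}

#' Evaluate a cubic spline
#'
#' @param spline a [fit_cubic_spline()] result.
#' @param x numeric vector of evaluation points; values outside the knot
#'   range are extrapolated with the end segments.
#' @return numeric vector `S(x)`.
#' @export
eval_spline <- function(spline, x) {
  xs <- spline$x
  n <- length(xs)
  i <- findInterval(x, xs, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), n - 1L)
  t <- x - xs[i]
  spline$a[i] + spline$b[i] * t + spline$c[i] * t^2 + spline$d[i] * t^3
}

# --- hole detection ---------------------------------------------------------

# Project a cloud onto the plane of its two leading principal axes.
project_to_plane <- function(points, origin = colMeans(points),
                             basis = NULL) {
  centered <- sweep(points, 2, origin)
  if (is.null(basis)) {
    e <- eigen(cov(points), symmetric = TRUE)
    basis <- e$vectors  # columns: u, v, normal
  }
  uvw <- centered %*% basis
  list(uv = uvw[, 1:2, drop = FALSE], w = uvw[, 3], origin = origin,
       basis = basis)
}

median_nn_dist <- function(points) {
  if (nrow(points) < 2) return(NA_real_)
  nn <- cpp_knn(points, points, 2L)
  median(nn$dist[, 2])
}

#' Detect occlusion holes
#'
#' Finds interior regions where the sampled surface density collapses — the
#' footprint of railing occlusions. The cloud is projected onto its two
#' leading principal axes and rasterised at `cell` spacing; empty cells not
#' connected to the outside form hole candidates, and the occupied cells
#' bordering a candidate supply the rim points. Detection is a geometric
#' stand-in validated on synthetic holes; see the methods vignette.
#'
#' @param cloud a [point_cloud()].
#' @param cell raster cell size in metres; default 2x the median
#'   nearest-neighbour spacing.
#' @param min_cells minimum number of empty cells for a hole to be reported.
#' @param max_cells largest plausible hole, in cells; larger enclosed
#'   regions are treated as background (for example the region framed by
#'   the legs and belly in a frontal view) and left alone.
#' @param rim_min_points patches with fewer rim points are dropped.
#' @param rim_max_thickness maximum spread (m) of the rim points about
#'   their best-fit plane: a genuine occlusion hole is rimmed by a thin
#'   ring of surface, while spurious enclosures mix depths.
#' @param basis optional 3 x 3 projection basis (columns u, v, normal).
#'   Occlusion holes live in the camera's image plane, so passing the
#'   camera basis is the right choice when it is known; the default
#'   projects onto the cloud's two leading principal axes, which suits
#'   roughly planar patches.
#' @return a list of `hole_patch` objects with elements `boundary_idx`
#'   (indices of rim points in `cloud`), `plane` (local best-fit plane of the
#'   rim: `origin`, `basis`), and `n_cells`.
#' @export
detect_holes <- function(cloud, cell = NULL, min_cells = 3, max_cells = 60,
                         rim_min_points = 6, rim_max_thickness = 0.03,
                         basis = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  if (n < rim_min_points) return(list())
  proj <- project_to_plane(cloud$points, basis = basis)
  if (is.null(cell)) cell <- 2 * median_nn_dist(cloud$points)
  uv <- proj$uv
  lo <- apply(uv, 2, min); hi <- apply(uv, 2, max)
  nu <- max(1L, ceiling((hi[1] - lo[1]) / cell))
  nv <- max(1L, ceiling((hi[2] - lo[2]) / cell))
  iu <- pmin(pmax(floor((uv[, 1] - lo[1]) / cell), 0), nu - 1) + 1
  iv <- pmin(pmax(floor((uv[, 2] - lo[2]) / cell), 0), nv - 1) + 1
  occ <- matrix(FALSE, nu, nv)
  occ[cbind(iu, iv)] <- TRUE
  # flood fill the empty region reachable from the raster border
  outside <- matrix(FALSE, nu, nv)
  queue <- which(!occ & (row(occ) %in% c(1, nu) | col(occ) %in% c(1, nv)))
  outside[queue] <- TRUE
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    i <- (cur - 1) %% nu + 1; j <- (cur - 1) %/% nu + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii >= 1 && ii <= nu && jj >= 1 && jj <= nv) {
        k <- (jj - 1) * nu + ii
        if (!occ[k] && !outside[k]) { outside[k] <- TRUE; queue <- c(queue, k) }
      }
    }
  }
  hole_cells <- !occ & !outside
  if (!any(hole_cells)) return(list())
  # connected components of hole cells (4-connectivity)
  comp <- matrix(0L, nu, nv)
  ncomp <- 0L
  for (start in which(hole_cells)) {
    if (comp[start] != 0) next  # already labelled by an earlier flood
    ncomp <- ncomp + 1L
    queue <- start
    comp[start] <- ncomp
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      i <- (cur - 1) %% nu + 1; j <- (cur - 1) %/% nu + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nu && jj >= 1 && jj <= nv) {
          k <- (jj - 1) * nu + ii
          if (hole_cells[k] && comp[k] == 0) { comp[k] <- ncomp; queue <- c(queue, k) }
        }
      }
    }
  }
  patches <- list()
  cell_of_point <- (iv - 1) * nu + iu
  for (cid in seq_len(ncomp)) {
    cells <- which(comp == cid)
    if (length(cells) < min_cells || length(cells) > max_cells) next
    # occupied cells 8-adjacent to the component hold the rim points
    rim_cells <- integer(0)
    for (k in cells) {
      i <- (k - 1) %% nu + 1; j <- (k - 1) %/% nu + 1
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nu && jj >= 1 && jj <= nv) {
          kk <- (jj - 1) * nu + ii
          if (occ[kk]) rim_cells <- c(rim_cells, kk)
        }
      }
    }
    rim_idx <- which(cell_of_point %in% unique(rim_cells))
    # image cells can collect points from several surfaces along the ray;
    # the occluded surface is the front-most one, so keep only the rim
    # points in the front depth cluster
    w_cand <- proj$w[rim_idx]
    w_front <- quantile(w_cand, 0.1)
    rim_idx <- rim_idx[w_cand <= w_front + rim_max_thickness]
    if (length(rim_idx) < rim_min_points) next
    rim_pts <- cloud$points[rim_idx, , drop = FALSE]
    e <- eigen(cov(rim_pts), symmetric = TRUE)
    if (sqrt(max(e$values[3], 0)) > rim_max_thickness) next  # depth-mixed rim
    patches[[length(patches) + 1]] <- structure(
      list(boundary_idx = rim_idx,
           plane = list(origin = colMeans(rim_pts), basis = e$vectors),
           n_cells = length(cells)),
      class = "hole_patch")
  }
  patches
}

# point-in-polygon by ray crossing; poly is a closed (or open) ring
points_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]; xj <- poly_x[j]; yj <- poly_y[j]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Fill a detected hole with spline-interpolated points
#'
#' The rim (plus the surrounding surface within a small margin) is projected
#' onto the rim's best-fit plane, giving a height field over that plane. The
#' field is rasterised and interpolated across the gap by natural cubic
#' splines along each of the two plane axes (two tensor passes, averaged);
#' new points are generated on a grid of the given spacing inside the convex
#' hull of the projected rim, lifted by the interpolated height, and appended
#' to the cloud flagged with attribute `repaired = 1`.
#'
#' @param cloud a [point_cloud()].
#' @param patch a `hole_patch` from [detect_holes()].
#' @param spacing fill-point grid spacing in metres; default is the median
#'   nearest-neighbour distance of the rim points.
#' @return the input cloud with fill points appended (existing points are
#'   never moved or removed). If the rim is too small the patch is skipped
#'   with a warning and the cloud returned unchanged.
#' @export
fill_hole <- function(cloud, patch, spacing = NULL) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(patch, "hole_patch"))
  rim_idx <- patch$boundary_idx
  if (length(rim_idx) < 6) {
    warning("hole rim has fewer than 6 points; patch skipped")
    return(cloud)
  }
  rim_pts <- cloud$points[rim_idx, , drop = FALSE]
  if (is.null(spacing)) spacing <- median_nn_dist(rim_pts)
  origin <- patch$plane$origin
  basis <- patch$plane$basis
  # local neighbourhood: points within the inflated rim bbox that also lie
  # near the rim plane (image cells can hold unrelated surfaces far behind)
  rim_uvw <- sweep(cloud$points[rim_idx, , drop = FALSE], 2, origin) %*% basis
  margin <- 4 * spacing
  depth_win <- max(3 * diff(range(rim_uvw[, 3])), 0.03)
  all_uvw <- sweep(cloud$points, 2, origin) %*% basis
  near <- all_uvw[, 1] >= min(rim_uvw[, 1]) - margin &
          all_uvw[, 1] <= max(rim_uvw[, 1]) + margin &
          all_uvw[, 2] >= min(rim_uvw[, 2]) - margin &
          all_uvw[, 2] <= max(rim_uvw[, 2]) + margin &
          all_uvw[, 3] >= min(rim_uvw[, 3]) - depth_win &
          all_uvw[, 3] <= max(rim_uvw[, 3]) + depth_win
  uv <- all_uvw[near, 1:2, drop = FALSE]
  w <- all_uvw[near, 3]
  # rasterise the known height field at the fill spacing
  lo <- apply(uv, 2, min); hi <- apply(uv, 2, max)
  nu <- max(2L, ceiling((hi[1] - lo[1]) / spacing) + 1L)
  nv <- max(2L, ceiling((hi[2] - lo[2]) / spacing) + 1L)
  iu <- pmin(pmax(round((uv[, 1] - lo[1]) / spacing), 0), nu - 1) + 1
  iv <- pmin(pmax(round((uv[, 2] - lo[2]) / spacing), 0), nv - 1) + 1
  key <- (iv - 1) * nu + iu
  wsum <- rowsum(w, key)
  wcnt <- as.numeric(table(key)[rownames(wsum)])
  grid_w <- matrix(NA_real_, nu, nv)
  grid_w[as.integer(rownames(wsum))] <- wsum / wcnt
  ug <- lo[1] + (seq_len(nu) - 1) * spacing
  vg <- lo[2] + (seq_len(nv) - 1) * spacing
  # tensor passes: splines along rows (u) and columns (v), averaged
  fill_u <- matrix(NA_real_, nu, nv)
  for (j in seq_len(nv)) {
    known <- which(!is.na(grid_w[, j]))
    if (length(known) >= 3) {
      sp <- fit_cubic_spline(ug[known], grid_w[known, j])
      miss <- which(is.na(grid_w[, j]))
      miss <- miss[miss > min(known) & miss < max(known)]
      if (length(miss)) fill_u[miss, j] <- eval_spline(sp, ug[miss])
    }
  }
  fill_v <- matrix(NA_real_, nu, nv)
  for (i in seq_len(nu)) {
    known <- which(!is.na(grid_w[i, ]))
    if (length(known) >= 3) {
      sp <- fit_cubic_spline(vg[known], grid_w[i, known])
      miss <- which(is.na(grid_w[i, ]))
      miss <- miss[miss > min(known) & miss < max(known)]
      if (length(miss)) fill_v[i, miss] <- eval_spline(sp, vg[miss])
    }
  }
  filled <- ifelse(is.na(fill_u), fill_v,
                   ifelse(is.na(fill_v), fill_u, (fill_u + fill_v) / 2))
  cand <- which(is.na(grid_w) & !is.na(filled))
  if (length(cand) == 0) return(cloud)
  ci <- (cand - 1) %% nu + 1
  cj <- (cand - 1) %/% nu + 1
  cu <- ug[ci]; cv <- vg[cj]; cw <- filled[cand]
  # keep only nodes inside the convex hull of the projected rim
  hull <- grDevices::chull(rim_uvw[, 1], rim_uvw[, 2])
  keep <- points_in_polygon(cu, cv, rim_uvw[hull, 1], rim_uvw[hull, 2])
  if (!any(keep)) return(cloud)
  new_uvw <- cbind(cu[keep], cv[keep], cw[keep])
  new_pts <- sweep(new_uvw %*% t(basis), 2, origin, "+")
  n_new <- nrow(new_pts)
  old_flag <- if (!is.null(cloud$attrs$repaired)) cloud$attrs$repaired
              else rep(0, n_points(cloud))
  fill_attrs <- lapply(cloud$attrs, function(a) rep(NA, n_new))
  fill_cloud <- point_cloud(new_pts, fill_attrs, cloud$frame)
  out <- cloud_bind(cloud, fill_cloud)
  out$attrs$repaired <- c(old_flag, rep(1, n_new))
  out
}

#' Detect and fill all holes in a cloud
#'
#' Runs [detect_holes()] and fills each patch with [fill_hole()].
#'
#' @inheritParams detect_holes
#' @inheritParams fill_hole
#' @return the repaired `point_cloud` (attribute `repaired` flags new points).
#' @export
repair_cloud <- function(cloud, cell = NULL, min_cells = 3, max_cells = 60,
                         rim_min_points = 6, rim_max_thickness = 0.03,
                         spacing = NULL, basis = NULL) {
  patches <- detect_holes(cloud, cell = cell, min_cells = min_cells,
                          max_cells = max_cells,
                          rim_min_points = rim_min_points,
                          rim_max_thickness = rim_max_thickness,
                          basis = basis)
  # fill_hole only appends points, so patch indices stay valid throughout
  for (p in patches) cloud <- fill_hole(cloud, p, spacing = spacing)
  if (is.null(cloud$attrs$repaired))
    cloud$attrs$repaired <- rep(0, n_points(cloud))
  cloud
}
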