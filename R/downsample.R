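#' Voxel grid dimensions
#'
#' Lays a cubic grid of edge `lam` over a bounding box: `L = ceil(l_x/lam)`
#' cells along x and likewise `W`, `H` along y, z, for `N = L * W * H` cells
#' in total. An axis with zero extent contributes a single layer of cells.
#'
#' @param box a [bbox()].
#' @param lam voxel edge length (cloud units), positive.
#' @return a list with `L`, `W`, `H` and `N`.
#' @export
voxel_grid_counts <- function(box, lam) {
  stopifnot(inherits(box, "bounding_box"))
  if (lam <= 0) stop("lam must be positive")
  ext <- box$max_corner - box$min_corner
  if (all(ext == 0)) stop("bounding box degenerate on every axis")
  n <- pmax(1L, as.integer(ceiling(ext / lam - 1e-12)))
  list(L = n[1], W = n[2], H = n[3], N = prod(n))
}

# Voxel key of each point: half-open cells [min + i*lam, min + (i+1)*lam)
# with the top face closed, so every bbox point maps to exactly one cell.
# Keys are ordered x-fastest, then y, then z.
voxel_keys <- function(points, box, lam) {
  g <- voxel_grid_counts(box, lam)
  ijk <- sapply(1:3, function(d) {
    i <- floor((points[, d] - box$min_corner[d]) / lam)
    pmin(pmax(i, 0), c(g$L, g$W, g$H)[d] - 1)
  })
  if (is.null(dim(ijk))) ijk <- matrix(ijk, ncol = 3)
  key <- ijk[, 1] + g$L * (ijk[, 2] + g$W * ijk[, 3])
  list(key = key, grid = g)
}

#' Voxel-centroid downsampling
#'
#' Replaces the points inside each occupied voxel by their centroid
#' `c = (1/n) * sum(P_i)`, the uniform thinning step of the conditional
#' voxel filter. Output points are ordered by voxel index (x-fastest).
#' Attributes of a centroid are taken from the first member point of its
#' voxel (voxels are small, so members share labels in practice).
#'
#' @param cloud a non-empty [point_cloud()].
#' @param lam voxel edge length (cloud units).
#' @return the downsampled `point_cloud`, one point per occupied voxel.
#' @export
voxel_centroid_downsample <- function(cloud, lam) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) == 0) stop("empty cloud")
  box <- bounding_box(cloud)
  box <- bbox(box$min_corner, box$max_corner)
  vk <- voxel_keys(cloud$points, box, lam)
  ord <- order(vk$key)
  key_s <- vk$key[ord]
  grp <- cumsum(!duplicated(key_s))
  sums <- rowsum(cloud$points[ord, , drop = FALSE], grp, reorder = FALSE)
  counts <- as.numeric(table(grp)[as.character(seq_len(max(grp)))])
  centroids <- sums / counts
  first_idx <- ord[!duplicated(key_s)]
  attrs <- lapply(cloud$attrs, function(a) a[first_idx])
  point_cloud(centroids, attrs, cloud$frame)
}

#' Local-density condition mask
#'
#' Marks the "dense working area" of the conditional voxel filter: a point
#' satisfies the condition when at least `min_neighbors` other points lie
#' within `radius` of it. Dense regions are the targets of voxel thinning;
#' sparse regions (thin structures, region boundaries) are left untouched.
#'
#' @param cloud a non-empty [point_cloud()].
#' @param radius neighbourhood radius in metres (default 0.03).
#' @param min_neighbors neighbour count threshold (default 16).
#' @return logical mask of length N.
#' @export
conditional_mask <- function(cloud, radius = 0.03, min_neighbors = 16) {
  stopifnot(inherits(cloud, "point_cloud"), radius > 0, min_neighbors >= 1)
  if (n_points(cloud) == 0) stop("empty cloud")
  counts <- cpp_radius_count(cloud$points, cloud$points, radius) - 1L  # self
  counts >= min_neighbors
}

#' Conditional voxel filter
#'
#' Density-conditioned voxel-centroid downsampling: points in dense regions
#' (see [conditional_mask()]) are voxel-thinned with edge `lam`, points in
#' sparse regions pass through verbatim, and the output is their union.
#' Compared with plain voxel filtering this removes more points overall while
#' preserving thin or sparsely sampled features exactly.
#'
#' @param cloud a non-empty [point_cloud()].
#' @param lam voxel edge length (cloud units).
#' @param radius,min_neighbors density condition, see [conditional_mask()].
#' @return the filtered `point_cloud` (untouched sparse points first, then
#'   voxel centroids ordered by voxel index).
#' @export
conditional_voxel_filter <- function(cloud, lam, radius = 0.03,
                                     min_neighbors = 16) {
  mask <- conditional_mask(cloud, radius, min_neighbors)
  sparse <- cloud_subset(cloud, !mask)
  if (!any(mask)) return(cloud)
  dense <- voxel_centroid_downsample(cloud_subset(cloud, mask), lam)
  if (n_points(sparse) == 0) return(dense)
  cloud_bind(sparse, dense)
}
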