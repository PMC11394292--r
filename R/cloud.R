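#' Point cloud container
#'
#' A point cloud is an ordered set of 3D points in metres with optional named
#' per-point attributes (view label, part label, ...) and a coordinate-frame
#' tag. It is the currency passed between every pipeline stage.
#'
#' @param points numeric N x 3 matrix (or coercible) of coordinates in metres.
#' @param attrs named list of per-point vectors, each of length N.
#' @param frame character label of the coordinate frame the points live in.
#' @return an object of class `point_cloud`.
#' @examples
#' pc <- point_cloud(rbind(c(0, 0, 0), c(1, 1, 1)))
#' n_points(pc)
#' @export
point_cloud <- function(points, attrs = list(), frame = "unknown") {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  if (length(points) == 0) points <- matrix(numeric(0), ncol = 3)
  if (ncol(points) != 3) stop("points must have 3 columns")
  storage.mode(points) <- "double"
  if (nrow(points) > 0 && !all(is.finite(points)))
    stop("all coordinates must be finite")
  if (!is.list(attrs)) stop("attrs must be a named list")
  if (length(attrs) > 0 && is.null(names(attrs)))
    stop("attrs must be named")
  for (nm in names(attrs)) {
    if (length(attrs[[nm]]) != nrow(points))
      stop("attr '", nm, "' must have length N = ", nrow(points))
  }
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(list(points = points, attrs = attrs, frame = frame),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points, frame '%s'", n_points(x), x$frame))
  if (length(x$attrs)) cat(", attrs:", paste(names(x$attrs), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a [point_cloud()].
#' @return integer point count.
#' @export
n_points <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  nrow(cloud$points)
}

#' Subset a point cloud
#'
#' Keeps the points selected by `idx` (logical mask or integer indices),
#' carrying every attribute along.
#'
#' @param cloud a [point_cloud()].
#' @param idx logical mask of length N or integer index vector.
#' @return the subset `point_cloud`.
#' @export
cloud_subset <- function(cloud, idx) {
  stopifnot(inherits(cloud, "point_cloud"))
  pts <- cloud$points[idx, , drop = FALSE]
  attrs <- lapply(cloud$attrs, function(a) a[idx])
  point_cloud(pts, attrs, cloud$frame)
}

#' Concatenate point clouds
#'
#' Row-binds the points of several clouds. Attributes present in only some
#' clouds are padded with `NA` for the others; the frame tag of the first
#' cloud is kept.
#'
#' @param ... `point_cloud` objects.
#' @return the combined `point_cloud`.
#' @export
cloud_bind <- function(...) {
  clouds <- list(...)
  if (length(clouds) == 1 && is.list(clouds[[1]]) &&
      !inherits(clouds[[1]], "point_cloud")) clouds <- clouds[[1]]
  stopifnot(all(vapply(clouds, inherits, TRUE, "point_cloud")))
  pts <- do.call(rbind, lapply(clouds, function(c) c$points))
  nms <- unique(unlist(lapply(clouds, function(c) names(c$attrs))))
  attrs <- list()
  for (nm in nms) {
    attrs[[nm]] <- unlist(lapply(clouds, function(c) {
      if (!is.null(c$attrs[[nm]])) c$attrs[[nm]] else rep(NA, n_points(c))
    }), use.names = FALSE)
  }
  point_cloud(pts, attrs, clouds[[1]]$frame)
}

#' Rigid transform (rotation + translation)
#'
#' @param R 3 x 3 rotation matrix (orthonormal, determinant +1).
#' @param T length-3 translation vector in metres.
#' @return an object of class `rigid_transform` with elements `R` and `T`.
#' @examples
#' rt <- rigid_transform(diag(3), c(1, 0, 0))
#' @export
rigid_transform <- function(R = diag(3), T = c(0, 0, 0)) {
  R <- as.matrix(R)
  T <- as.numeric(T)
  if (!all(dim(R) == c(3, 3)) || length(T) != 3)
    stop("R must be 3x3 and T length 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    stop("R is not orthonormal")
  if (abs(det(R) - 1) > 1e-8)
    stop("R must be a proper rotation (det = +1)")
  structure(list(R = R, T = T), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("  rotation angle:", sprintf("%.4f deg", rotation_angle_deg(x)), "\n")
  cat("  translation:", sprintf("(%.4f, %.4f, %.4f) m", x$T[1], x$T[2], x$T[3]), "\n")
  invisible(x)
}

#' Identity rigid transform
#' @return a [rigid_transform()] with `R = I`, `T = 0`.
#' @export
rt_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` is the transform that applies `b` first, then `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return the composed [rigid_transform()].
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$T) + a$T)
}

#' Invert a rigid transform
#' @param rt a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
rt_invert <- function(rt) {
  rigid_transform(t(rt$R), as.numeric(-t(rt$R) %*% rt$T))
}

#' Rotation angle of a rigid transform
#' @param rt a [rigid_transform()].
#' @return the rotation angle in degrees (geodesic distance from identity).
#' @export
rotation_angle_deg <- function(rt) {
  c_ang <- (sum(diag(rt$R)) - 1) / 2
  acos(min(1, max(-1, c_ang))) * 180 / pi
}

#' Rotation about a coordinate axis
#' @param axis one of "x", "y", "z".
#' @param angle_deg rotation angle in degrees (right-handed).
#' @return a [rigid_transform()] with zero translation.
#' @export
rt_axis_rotation <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  R <- switch(axis,
    x = rbind(c(1, 0, 0), c(0, ca, -sa), c(0, sa, ca)),
    y = rbind(c(ca, 0, sa), c(0, 1, 0), c(-sa, 0, ca)),
    z = rbind(c(ca, -sa, 0), c(sa, ca, 0), c(0, 0, 1)))
  rigid_transform(R, c(0, 0, 0))
}

#' Apply a rigid transform to a cloud
#'
#' Maps every point p to `R p + T`; attributes are carried through unchanged.
#'
#' @param cloud a [point_cloud()].
#' @param rt a [rigid_transform()].
#' @param frame optional new frame label for the result.
#' @return the transformed `point_cloud`.
#' @export
transform_cloud <- function(cloud, rt, frame = cloud$frame) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(rt, "rigid_transform"))
  pts <- cloud$points %*% t(rt$R)
  pts <- sweep(pts, 2, rt$T, "+")
  point_cloud(pts, cloud$attrs, frame)
}

#' Axis-aligned bounding box
#'
#' Componentwise minimum and maximum of the coordinates: the axis-aligned
#' bounding box used to lay the voxel grid over a cloud.
#'
#' @param cloud a [point_cloud()] with at least one point.
#' @return an object of class `bounding_box` with `min_corner`, `max_corner`.
#' @export
bounding_box <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) == 0) stop("bounding_box of an empty cloud")
  structure(list(min_corner = apply(cloud$points, 2, min),
                 max_corner = apply(cloud$points, 2, max)),
            class = "bounding_box")
}

#' Construct a bounding box from two corners
#' @param min_corner,max_corner length-3 numeric vectors, componentwise
#'   `min_corner <= max_corner`.
#' @return a `bounding_box`.
#' @export
bbox <- function(min_corner, max_corner) {
  min_corner <- as.numeric(min_corner); max_corner <- as.numeric(max_corner)
  stopifnot(length(min_corner) == 3, length(max_corner) == 3)
  if (any(min_corner > max_corner))
    stop("min_corner must be <= max_corner componentwise")
  structure(list(min_corner = min_corner, max_corner = max_corner),
            class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box> (%.3f, %.3f, %.3f) - (%.3f, %.3f, %.3f)\n",
              x$min_corner[1], x$min_corner[2], x$min_corner[3],
              x$max_corner[1], x$max_corner[2], x$max_corner[3]))
  invisible(x)
}
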