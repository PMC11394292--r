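#' Read a point cloud from an ASCII file
#'
#' Supports ASCII PLY (`element vertex` with `x y z` properties, extra scalar
#' properties kept as attributes), PCD v0.7 `DATA ascii`, and plain
#' whitespace-separated XYZ (extra numeric columns kept as attributes
#' `a1, a2, ...`). Binary dialects are rejected so fixtures stay text-exact.
#'
#' @param path file to read.
#' @param fmt one of `"auto"` (by extension), `"ply"`, `"pcd"`, `"xyz"`.
#' @return a [point_cloud()].
#' @seealso [write_cloud()]
#' @export
read_cloud <- function(path, fmt = c("auto", "ply", "pcd", "xyz")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt == "auto") {
    ext <- tolower(tools::file_ext(path))
    fmt <- switch(ext, ply = "ply", pcd = "pcd", xyz = "xyz", txt = "xyz",
                  stop("cannot infer format from extension '", ext, "'"))
  }
  switch(fmt, ply = read_ply(path), pcd = read_pcd(path), xyz = read_xyz(path))
}

parse_numeric_rows <- function(lines, offset, ncol_expect, what) {
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "[ \t]+")[[1]]))
    if (length(v) < ncol_expect || any(is.na(v) & !is.nan(v)))
      stop(what, ": non-numeric or short row at line ", offset + i)
    v
  })
  do.call(rbind, rows)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[1]) != "ply")
    stop("PLY: missing 'ply' magic at line 1")
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stop("PLY: no end_header found")
  hdr <- trimws(lines[2:(hdr_end - 1)])
  fmt_line <- grep("^format ", hdr, value = TRUE)
  if (length(fmt_line) != 1) stop("PLY: missing format line")
  if (!grepl("^format ascii", fmt_line))
    stop("PLY: unsupported dialect '", fmt_line, "' (ASCII only)")
  # collect elements and their properties in declared order
  elems <- list(); cur <- NULL
  for (i in seq_along(hdr)) {
    tok <- strsplit(hdr[i], "[ \t]+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      elems[[cur]] <- list(count = as.integer(tok[3]), props = character(0),
                           list_props = character(0))
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("PLY: property before element at header line ", i + 1)
      if (tok[2] == "list")
        elems[[cur]]$list_props <- c(elems[[cur]]$list_props, tok[length(tok)])
      else
        elems[[cur]]$props <- c(elems[[cur]]$props, tok[length(tok)])
    }
  }
  if (is.null(elems$vertex)) stop("PLY: no vertex element")
  nv <- elems$vertex$count
  props <- elems$vertex$props
  if (!all(c("x", "y", "z") %in% props))
    stop("PLY: vertex element lacks x/y/z properties")
  # vertex data is the first element block after the header
  first <- names(elems)[1]
  if (first != "vertex")
    stop("PLY: only files with vertex as first element are supported")
  if (length(lines) < hdr_end + nv) stop("PLY: truncated vertex block")
  data <- if (nv > 0)
    parse_numeric_rows(lines[(hdr_end + 1):(hdr_end + nv)], hdr_end,
                       length(props), "PLY")
  else matrix(numeric(0), ncol = max(3, length(props)))
  colnames(data) <- if (nrow(data)) props else NULL
  pts <- if (nv > 0) data[, c("x", "y", "z"), drop = FALSE]
         else matrix(numeric(0), ncol = 3)
  extra <- setdiff(props, c("x", "y", "z"))
  attrs <- if (nv > 0) stats::setNames(lapply(extra, function(p) data[, p]), extra)
           else list()
  if (length(elems) > 1)
    warning("PLY: non-vertex elements (", paste(setdiff(names(elems), "vertex"),
            collapse = ", "), ") ignored")
  point_cloud(pts, attrs)
}

read_pcd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body_at <- NA; hdr <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    tok <- strsplit(ln, "[ \t]+")[[1]]
    key <- toupper(tok[1])
    hdr[[key]] <- tok[-1]
    if (key == "DATA") { body_at <- i; break }
  }
  if (is.na(body_at)) stop("PCD: no DATA line found")
  if (tolower(hdr$DATA[1]) != "ascii")
    stop("PCD: unsupported dialect '", hdr$DATA[1], "' (ASCII only)")
  fields <- hdr$FIELDS
  if (is.null(fields) || !all(c("x", "y", "z") %in% fields))
    stop("PCD: FIELDS must include x y z")
  np <- as.integer(hdr$POINTS[1])
  if (is.na(np)) stop("PCD: missing POINTS count")
  if (length(lines) < body_at + np) stop("PCD: truncated data block")
  data <- if (np > 0)
    parse_numeric_rows(lines[(body_at + 1):(body_at + np)], body_at,
                       length(fields), "PCD")
  else matrix(numeric(0), ncol = length(fields))
  colnames(data) <- if (nrow(data)) fields else NULL
  pts <- if (np > 0) data[, c("x", "y", "z"), drop = FALSE]
         else matrix(numeric(0), ncol = 3)
  extra <- setdiff(fields, c("x", "y", "z"))
  attrs <- if (np > 0) stats::setNames(lapply(extra, function(p) data[, p]), extra)
           else list()
  point_cloud(pts, attrs)
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0) return(point_cloud(matrix(numeric(0), ncol = 3)))
  data <- parse_numeric_rows(lines, 0, 3, "XYZ")
  pts <- data[, 1:3, drop = FALSE]
  attrs <- list()
  if (ncol(data) > 3)
    for (j in 4:ncol(data)) attrs[[paste0("a", j - 3)]] <- data[, j]
  point_cloud(pts, attrs)
}

fmt_num <- function(x) {
  out <- sprintf("%.9g", x)
  out[!is.finite(x)] <- "nan"  # missing attribute values (e.g. on outliers)
  out
}

#' Write a point cloud to an ASCII file
#'
#' The emitted file re-reads to an equal cloud (coordinates to 1e-6 m).
#' Numeric attributes become extra PLY/PCD fields; non-numeric attributes are
#' dropped with a warning. XYZ output keeps coordinates plus numeric
#' attributes as extra columns.
#'
#' @param cloud a [point_cloud()].
#' @param path output file path.
#' @param fmt one of `"auto"` (by extension), `"ply"`, `"pcd"`, `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, fmt = c("auto", "ply", "pcd", "xyz")) {
  stopifnot(inherits(cloud, "point_cloud"))
  fmt <- match.arg(fmt)
  if (fmt == "auto") {
    ext <- tolower(tools::file_ext(path))
    fmt <- switch(ext, ply = "ply", pcd = "pcd", xyz = "xyz", txt = "xyz",
                  stop("cannot infer format from extension '", ext, "'"))
  }
  num_attrs <- Filter(is.numeric, cloud$attrs)
  dropped <- setdiff(names(cloud$attrs), names(num_attrs))
  if (length(dropped))
    warning("dropping non-numeric attrs on write: ", paste(dropped, collapse = ", "))
  n <- n_points(cloud)
  cols <- cloud$points
  if (length(num_attrs) > 0 && n > 0)
    cols <- cbind(cols, do.call(cbind, num_attrs))
  colnames(cols) <- c("x", "y", "z",
                      if (n > 0) names(num_attrs))
  body <- if (n > 0) apply(cols, 1, function(r) paste(fmt_num(r), collapse = " "))
          else character(0)
  txt <- switch(fmt,
    ply = c("ply", "format ascii 1.0",
            paste("element vertex", n),
            paste("property float", colnames(cols)),
            "end_header", body),
    pcd = c("# .PCD v.7 - Point Cloud Data file format",
            "VERSION .7",
            paste("FIELDS", paste(colnames(cols), collapse = " ")),
            paste("SIZE", paste(rep(4, ncol(cols)), collapse = " ")),
            paste("TYPE", paste(rep("F", ncol(cols)), collapse = " ")),
            paste("COUNT", paste(rep(1, ncol(cols)), collapse = " ")),
            paste("WIDTH", n), "HEIGHT 1",
            "VIEWPOINT 0 0 0 1 0 0 0",
            paste("POINTS", n), "DATA ascii", body),
    xyz = body)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(txt, con)
  invisible(path)
}

#' Depth camera model
#'
#' Pinhole depth camera described by its field of view, pixel counts, valid
#' depth range and pose. Defaults follow a Kinect-v2-like sensor: 70 x 60
#' degree field of view, 512 x 424 pixels, 0.5-4.5 m range.
#'
#' @param fov_h,fov_v horizontal/vertical field of view in degrees.
#' @param width,height image size in pixels.
#' @param range_min,range_max valid depth range in metres.
#' @param pose camera-to-world [rigid_transform()].
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(fov_h = 70, fov_v = 60, width = 512, height = 424,
                         range_min = 0.5, range_max = 4.5,
                         pose = rt_identity()) {
  stopifnot(fov_h > 0, fov_h < 180, fov_v > 0, fov_v < 180,
            width >= 1, height >= 1, range_min < range_max,
            inherits(pose, "rigid_transform"))
  structure(list(fov_h = fov_h, fov_v = fov_v, width = as.integer(width),
                 height = as.integer(height), range_min = range_min,
                 range_max = range_max, pose = pose),
            class = "camera_model")
}

camera_intrinsics <- function(camera) {
  list(fx = (camera$width / 2) / tan(camera$fov_h * pi / 360),
       fy = (camera$height / 2) / tan(camera$fov_v * pi / 360),
       cx = (camera$width + 1) / 2,
       cy = (camera$height + 1) / 2)
}

#' Back-project a depth image to a point cloud
#'
#' Pinhole back-projection with focal lengths derived from the field of view
#' (`f_x = (W/2)/tan(fov_h/2)`, `f_y = (H/2)/tan(fov_v/2)`) and principal
#' point at the image centre. Depth is in millimetres (depth-sensor
#' convention); the cloud is in metres, camera frame, +z forward, +x right,
#' +y down in the image. Zero pixels and depths outside the camera range are
#' dropped.
#'
#' @param depth_mm H x W numeric matrix of depths in millimetres (row = image
#'   row, column = image column).
#' @param camera a [camera_model()]; `width`/`height` must match `depth_mm`.
#' @return a [point_cloud()] in the camera frame.
#' @export
depth_to_cloud <- function(depth_mm, camera) {
  stopifnot(inherits(camera, "camera_model"), is.matrix(depth_mm))
  if (any(depth_mm < 0, na.rm = TRUE)) stop("depth values must be >= 0")
  if (nrow(depth_mm) != camera$height || ncol(depth_mm) != camera$width)
    stop(sprintf("depth image is %dx%d but camera expects %dx%d",
                 nrow(depth_mm), ncol(depth_mm), camera$height, camera$width))
  K <- camera_intrinsics(camera)
  z <- as.vector(depth_mm) / 1000  # column-major: row index fastest
  v <- rep(seq_len(camera$height), times = camera$width)
  u <- rep(seq_len(camera$width), each = camera$height)
  keep <- !is.na(z) & z > 0 & z >= camera$range_min & z <= camera$range_max
  z <- z[keep]; u <- u[keep]; v <- v[keep]
  pts <- cbind(x = (u - K$cx) / K$fx * z,
               y = (v - K$cy) / K$fy * z,
               z = z)
  point_cloud(pts, frame = "camera")
}

#' Read a depth image stored as text
#'
#' Accepts ASCII PGM (`P2`) or a plain whitespace grid of numbers; values are
#' depths in millimetres, zero marking invalid pixels.
#'
#' @param path file to read.
#' @return numeric H x W matrix of depths in millimetres.
#' @export
read_depth_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (length(lines) > 0 && trimws(lines[1]) == "P2") {
    toks <- as.numeric(unlist(strsplit(trimws(lines[-1]), "[ \t]+")))
    toks <- toks[!is.na(toks)]
    w <- toks[1]; h <- toks[2]  # toks[3] is maxval
    vals <- toks[-(1:3)]
    if (length(vals) != w * h) stop("PGM: expected ", w * h, " values")
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    rows <- lapply(lines[trimws(lines) != ""], function(l)
      as.numeric(strsplit(trimws(l), "[ \t]+")[[1]]))
    if (length(unique(lengths(rows))) != 1) stop("ragged depth grid")
    do.call(rbind, rows)
  }
}
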