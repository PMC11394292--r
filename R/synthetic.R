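#' Synthetic sheep body parameters
#'
#' Dimensions of the procedural sheep used by the scene generator, sized to
#' 8-12 month meat sheep of 35-45 kg (trunk length around 0.60-0.75 m). The
#' trunk is a blunt-ended superellipsoid (chest and rump are blunt, not
#' pointed), with four cylindrical legs and a raised ellipsoidal head set
#' over the chest so the trunk dominates the longest body axis.
#'
#' @param body_length trunk length in metres (x extent of the torso).
#' @param body_height trunk dorsoventral depth in metres.
#' @param body_width trunk width in metres.
#' @param leg_radius,leg_length leg cylinder dimensions in metres.
#' @param head_offset x offset of the head centre from the torso front tip
#'   in metres (negative = set back so the head does not pass the chest).
#' @param blunt_exponent superellipsoid exponent of the trunk profile along
#'   x; larger is blunter (default 12, a barrel-like trunk).
#' @param seed integer seed for surface sampling.
#' @return a list of class `sheep_params`.
#' @export
sheep_params <- function(body_length = 0.68, body_height = 0.32,
                         body_width = 0.26, leg_radius = 0.035,
                         leg_length = 0.33, head_offset = -0.09,
                         blunt_exponent = 12, seed = 1) {
  p <- list(body_length = body_length, body_height = body_height,
            body_width = body_width, leg_radius = leg_radius,
            leg_length = leg_length, head_offset = head_offset,
            blunt_exponent = blunt_exponent, seed = seed)
  dims <- unlist(p[c("body_length", "body_height", "body_width",
                     "leg_radius", "leg_length")])
  if (any(dims <= 0)) stop("all dimensions must be positive")
  structure(p, class = "sheep_params")
}

# Sample a parametric surface patch ~uniformly by area: cell areas on a
# parameter grid weight a multinomial draw, points jittered within cells.
sample_param_surface <- function(fmap, u_range, v_range, nu, nv, density) {
  ug <- seq(u_range[1], u_range[2], length.out = nu + 1)
  vg <- seq(v_range[1], v_range[2], length.out = nv + 1)
  corners <- function(ui, vi) fmap(ug[ui], vg[vi])
  # corner positions: (nu+1) x (nv+1) x 3
  P <- array(0, c(nu + 1, nv + 1, 3))
  for (i in seq_len(nu + 1)) for (j in seq_len(nv + 1))
    P[i, j, ] <- fmap(ug[i], vg[j])
  du <- P[-1, -(nv + 1), , drop = FALSE] - P[-(nu + 1), -(nv + 1), , drop = FALSE]
  dv <- P[-(nu + 1), -1, , drop = FALSE] - P[-(nu + 1), -(nv + 1), , drop = FALSE]
  cx <- du[, , 2] * dv[, , 3] - du[, , 3] * dv[, , 2]
  cy <- du[, , 3] * dv[, , 1] - du[, , 1] * dv[, , 3]
  cz <- du[, , 1] * dv[, , 2] - du[, , 2] * dv[, , 1]
  area <- sqrt(cx^2 + cy^2 + cz^2)
  total <- sum(area)
  n <- round(total * density)
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  cell <- sample.int(length(area), n, replace = TRUE, prob = as.vector(area))
  ci <- (cell - 1) %% nu + 1
  cj <- (cell - 1) %/% nu + 1
  uu <- ug[ci] + runif(n) * diff(ug)[1]
  vv <- vg[cj] + runif(n) * diff(vg)[1]
  t(mapply(fmap, uu, vv))
}

#' Sample the synthetic sheep surface
#'
#' Deterministic (seeded) near-uniform area sampling of the sheep body:
#' blunt superellipsoid trunk, four leg cylinders standing on z = 0 and a
#' raised head ellipsoid, with points inside another primitive culled so
#' only the union surface remains. The body frame has +x along the trunk,
#' +z up, feet at z = 0.
#'
#' @param params a [sheep_params()].
#' @param density target surface sampling density in points per square metre.
#' @return a list with `cloud` (a [point_cloud()] with attr `part` in
#'   `torso/leg/head`) and `dims` (exact ground-truth dimensions; the
#'   ground-truth `body_length` is the x extent of the trunk, i.e.
#'   `params$body_length` by construction).
#' @export
make_sheep_surface <- function(params = sheep_params(), density = 4500) {
  stopifnot(inherits(params, "sheep_params"), density > 0)
  a <- params$body_length / 2
  b <- params$body_width / 2
  c_ <- params$body_height / 2
  p <- params$blunt_exponent
  z0 <- params$leg_length + c_ - 0.02  # trunk overlaps leg tops slightly
  leg_x <- c(-1, -1, 1, 1) * (a - 0.14)
  leg_y <- c(-1, 1, -1, 1) * (b - params$leg_radius)
  head_r <- c(0.09, 0.055, 0.065)
  head_ctr <- c(a + params$head_offset, 0, z0 + c_)

  inside_torso <- function(pts)
    abs(pts[, 1] / a)^p + (pts[, 2] / b)^2 + ((pts[, 3] - z0) / c_)^2 < 0.98
  inside_head <- function(pts)
    ((pts[, 1] - head_ctr[1]) / head_r[1])^2 +
    ((pts[, 2] - head_ctr[2]) / head_r[2])^2 +
    ((pts[, 3] - head_ctr[3]) / head_r[3])^2 < 0.98
  inside_leg <- function(pts) {
    res <- rep(FALSE, nrow(pts))
    for (l in 1:4) {
      res <- res | ((pts[, 1] - leg_x[l])^2 + (pts[, 2] - leg_y[l])^2 <
                      (0.99 * params$leg_radius)^2 &
                    pts[, 3] >= 0 & pts[, 3] <= params$leg_length + 0.01)
    }
    res
  }

  with_seed(params$seed, {
    torso_map <- function(u, v) {
      w <- cos(u)
      rho <- sqrt(max(0, 1 - abs(w)^p))
      c(a * w, b * rho * cos(v), z0 + c_ * rho * sin(v))
    }
    torso <- sample_param_surface(torso_map, c(0, pi), c(0, 2 * pi),
                                  150, 100, density)
    head_map <- function(u, v)
      head_ctr + head_r * c(cos(u), sin(u) * cos(v), sin(u) * sin(v))
    head <- sample_param_surface(head_map, c(0, pi), c(0, 2 * pi),
                                 60, 40, density)
    legs <- list()
    for (l in 1:4) {
      xl <- leg_x[l]; yl <- leg_y[l]; r <- params$leg_radius
      leg_map <- function(u, v) c(xl + r * cos(u), yl + r * sin(u), v)
      legs[[l]] <- sample_param_surface(leg_map, c(0, 2 * pi),
                                        c(0, params$leg_length), 40, 40,
                                        density)
    }
    legs <- do.call(rbind, legs)
    # union surface: cull points inside another primitive
    torso <- torso[!inside_head(torso) & !inside_leg(torso), , drop = FALSE]
    head <- head[!inside_torso(head), , drop = FALSE]
    legs <- legs[!inside_torso(legs) & !inside_head(legs), , drop = FALSE]
    # analytic outward normals (gradients of the implicit surfaces), used by
    # the renderer to emulate incidence-dependent sensor dropout
    norm_rows <- function(m) m / sqrt(rowSums(m^2))
    n_torso <- norm_rows(cbind(
      p * sign(torso[, 1]) * abs(torso[, 1] / a)^(p - 1) / a,
      2 * torso[, 2] / b^2, 2 * (torso[, 3] - z0) / c_^2))
    n_head <- norm_rows(sweep(head, 2, head_ctr) %*% diag(1 / head_r^2))
    leg_id <- rep(1:4, each = 0)
    dxy <- legs[, 1:2]
    for (l in 1:4) {
      cand <- sqrt((legs[, 1] - leg_x[l])^2 + (legs[, 2] - leg_y[l])^2)
      if (l == 1) { best <- cand; dxy <- cbind(legs[, 1] - leg_x[l], legs[, 2] - leg_y[l]) }
      else {
        better <- cand < best
        best[better] <- cand[better]
        dxy[better, ] <- cbind(legs[better, 1] - leg_x[l], legs[better, 2] - leg_y[l])
      }
    }
    n_legs <- if (nrow(legs)) norm_rows(cbind(dxy, 0)) else matrix(numeric(0), ncol = 3)
    pts <- rbind(torso, head, legs)
    normals <- rbind(n_torso, n_head, n_legs)
    part <- c(rep("torso", nrow(torso)), rep("head", nrow(head)),
              rep("leg", nrow(legs)))
    dims <- list(body_length = params$body_length,
                 body_height = params$body_height,
                 body_width = params$body_width,
                 wither_height = params$leg_length + params$body_height - 0.02)
    list(cloud = point_cloud(pts, list(part = part,
                                       nx = normals[, 1], ny = normals[, 2],
                                       nz = normals[, 3]),
                             frame = "body"),
         dims = dims)
  })
}

#' Synthetic scene parameters
#'
#' Conditions of the three-camera capture rig emulated by the generator:
#' a sheep standing on the floor of a trapezoidal restraining pen, viewed by
#' a top camera, an oblique side camera (the pen's 53 degree side) and a
#' front camera at roughly 0.9 m, each a Kinect-v2-like sensor (70 x 60
#' degree field of view, 0.5-4.5 m range). Defaults: 2 mm sensor noise along
#' the ray, 50 uniform stray outliers per view plus 200 flying-pixel clutter
#' points hanging 15-60 cm off the captured surfaces (the dominant Kinect-v2
#' artifact at depth discontinuities), two vertical railing bars in
#' front of the chest producing the occlusion holes the repair stage fills,
#' a random body yaw up to +/-20 degrees (pitch a quarter of that), and a
#' small camera-calibration error (0.2 degrees, 2 mm, the quality a fixed
#' rig achieves with checkerboard calibration) on the extrinsics handed to
#' the pipeline.
#'
#' @param noise_sigma sensor noise standard deviation along the viewing ray,
#'   metres.
#' @param outlier_count stray outlier points added per view.
#' @param outlier_box [bbox()] the outliers are drawn from (world frame).
#' @param clutter_count flying-pixel clutter points added per view.
#' @param clutter_range distance range (m) of clutter from the surface.
#' @param railing list of [bbox()] occluder slabs (world frame).
#' @param ground_z ground plane height in metres.
#' @param tilt_deg body yaw perturbation bound in degrees (pitch bound is a
#'   quarter of it).
#' @param body_density,ground_density sampling densities, points per m^2.
#' @param ground_half_extent half extents (x, y) of the sampled floor, m.
#' @param cameras optional named list of three [camera_model()]s
#'   (`top`, `side`, `front`); default rig per the pen geometry.
#' @param max_incidence_deg incidence cutoff in degrees: surface points whose
#'   normal is tilted further than this from the viewing ray return no depth.
#'   This single signed test culls back-facing (hidden) surfaces and models
#'   the grazing-incidence dropout of a time-of-flight sensor.
#' @param calib_rot_sd_deg,calib_trans_sd_m calibration error scales.
#' @return a list of class `scene_params`.
#' @export
scene_params <- function(noise_sigma = 0.002, outlier_count = 50,
                         outlier_box = bbox(c(-1.2, -1.2, 0), c(1.2, 1.2, 1.4)),
                         clutter_count = 200, clutter_range = c(0.15, 0.6),
                         railing = default_railing(), ground_z = 0,
                         tilt_deg = 20, body_density = 9000,
                         ground_density = 9000,
                         ground_half_extent = c(0.7, 0.32),
                         cameras = NULL, max_incidence_deg = 70,
                         calib_rot_sd_deg = 0.2, calib_trans_sd_m = 0.002) {
  stopifnot(noise_sigma >= 0, outlier_count >= 0, tilt_deg >= 0)
  structure(list(noise_sigma = noise_sigma, outlier_count = outlier_count,
                 outlier_box = outlier_box, clutter_count = clutter_count,
                 clutter_range = clutter_range, railing = railing,
                 ground_z = ground_z, tilt_deg = tilt_deg,
                 body_density = body_density, ground_density = ground_density,
                 ground_half_extent = ground_half_extent,
                 cameras = cameras, max_incidence_deg = max_incidence_deg,
                 calib_rot_sd_deg = calib_rot_sd_deg,
                 calib_trans_sd_m = calib_trans_sd_m),
            class = "scene_params")
}

#' Default railing occluders
#'
#' Two bar segments of the restraining pen between the front camera and the
#' chest, the source of the front-view occlusion holes. The segments sit
#' either side of the chest midline at chest height, so their shadows fall
#' inside the chest silhouette (enclosed holes the repair stage can detect
#' and fill) for moderate body yaw while leaving the chest apex clear.
#' @return list of [bbox()] slabs in the world frame.
#' @export
default_railing <- function() {
  list(bbox(c(0.52, -0.065, 0.414), c(0.55, -0.035, 0.534)),
       bbox(c(0.52, 0.035, 0.414), c(0.55, 0.065, 0.534)))
}

# Camera-to-world pose looking from `eye` toward `target`; camera frame is
# +z forward, +x right, +y down.
look_at <- function(eye, target, up = c(0, 0, 1)) {
  zc <- target - eye
  zc <- zc / sqrt(sum(zc^2))
  xc <- crossprod3(zc, up)
  if (sqrt(sum(xc^2)) < 1e-6) xc <- crossprod3(zc, c(0, -1, 0))
  xc <- xc / sqrt(sum(xc^2))
  yc <- crossprod3(zc, xc)
  rigid_transform(cbind(xc, yc, zc), eye)
}

#' Default three-camera rig
#'
#' Top camera above the pen, front camera at about 0.9 m from the chest, and
#' an oblique side camera along the pen's 53 degree side, all Kinect-v2-like.
#' @return named list of [camera_model()]s `top`, `side`, `front`.
#' @export
default_cameras <- function() {
  list(top = camera_model(pose = look_at(c(0, 0, 1.5), c(0, 0, 0.4))),
       side = camera_model(pose = look_at(c(-1.05, -0.8, 0.75), c(0, 0, 0.35))),
       front = camera_model(pose = look_at(c(1.35, 0, 0.55), c(0, 0, 0.45))))
}

# does the segment origin -> point intersect an axis-aligned slab?
segment_hits_box <- function(origin, pts, box) {
  n <- nrow(pts)
  tmin <- rep(0, n); tmax <- rep(1, n)
  for (d in 1:3) {
    dir <- pts[, d] - origin[d]
    lo <- (box$min_corner[d] - origin[d])
    hi <- (box$max_corner[d] - origin[d])
    par <- abs(dir) < 1e-12
    t1 <- ifelse(par, ifelse(origin[d] >= box$min_corner[d] &
                               origin[d] <= box$max_corner[d], -Inf, Inf),
                 lo / dir)
    t2 <- ifelse(par, ifelse(origin[d] >= box$min_corner[d] &
                               origin[d] <= box$max_corner[d], Inf, -Inf),
                 hi / dir)
    a <- pmin(t1, t2); b <- pmax(t1, t2)
    tmin <- pmax(tmin, a); tmax <- pmin(tmax, b)
  }
  tmin <= tmax
}

#' Render one depth-camera view of a scene cloud
#'
#' Simulates what one depth camera sees of a world-frame cloud: points are
#' projected with the camera's pinhole model, points outside the image or
#' the depth range are dropped, railing slabs occlude along the viewing ray,
#' hidden points are removed with a bucketed depth buffer (as a real depth
#' sensor self-occludes), Gaussian sensor noise is added along the ray, and
#' uniform stray outliers are appended. The result is in the camera frame.
#'
#' @param world a [point_cloud()] in the world frame (body plus ground).
#' @param camera a [camera_model()] with a world pose.
#' @param scene a [scene_params()].
#' @param seed optional integer seed for noise and outliers.
#' @return a [point_cloud()] in the camera frame; attr `label` marks
#'   `body`/`ground` (carried from the input) and `outlier`.
#' @export
render_view <- function(world, camera, scene = scene_params(), seed = NULL) {
  stopifnot(inherits(world, "point_cloud"), inherits(camera, "camera_model"))
  cam_inv <- rt_invert(camera$pose)
  pc <- transform_cloud(world, cam_inv, frame = "camera")
  z <- pc$points[, 3]
  keep <- z >= camera$range_min & z <= camera$range_max
  K <- camera_intrinsics(camera)
  u <- K$fx * pc$points[, 1] / z + K$cx
  v <- K$fy * pc$points[, 2] / z + K$cy
  keep <- keep & u >= 0.5 & u <= camera$width + 0.5 &
    v >= 0.5 & v <= camera$height + 0.5
  if (!any(keep)) {
    warning("camera sees no points")
    return(point_cloud(matrix(numeric(0), ncol = 3), frame = "camera"))
  }
  # visibility: back-facing surfaces are hidden, and a ToF sensor returns
  # nothing from front-facing surfaces seen at grazing incidence (the signal
  # amplitude collapses), so both are culled with one signed-incidence test
  eye <- camera$pose$T
  if (!is.null(world$attrs$nx)) {
    ray <- sweep(world$points, 2, eye)
    ray <- ray / sqrt(rowSums(ray^2))
    nrm <- cbind(world$attrs$nx, world$attrs$ny, world$attrs$nz)
    cosi <- -rowSums(ray * nrm)  # +1 = surface squarely facing the camera
    has_n <- !is.na(cosi)
    keep[has_n] <- keep[has_n] &
      cosi[has_n] >= cos(scene$max_incidence_deg * pi / 180)
  }
  # railing occlusion along camera->point segments (world frame)
  occl <- rep(FALSE, n_points(world))
  for (slab in scene$railing) {
    idx <- which(keep & !occl)
    if (length(idx) == 0) break
    occl[idx] <- segment_hits_box(eye, world$points[idx, , drop = FALSE], slab)
  }
  keep <- keep & !occl
  out <- cloud_subset(pc, keep)
  if (!is.null(out$attrs$nx)) {
    nrm <- cbind(out$attrs$nx, out$attrs$ny, out$attrs$nz) %*% t(cam_inv$R)
    out$attrs$nx <- nrm[, 1]; out$attrs$ny <- nrm[, 2]; out$attrs$nz <- nrm[, 3]
  }
  if (is.null(out$attrs$label)) out$attrs$label <- rep("body", n_points(out))
  with_seed(seed, {
    if (scene$noise_sigma > 0 && n_points(out) > 0) {
      r <- sqrt(rowSums(out$points^2))
      out$points <- out$points * (1 + scene$noise_sigma * rnorm(n_points(out)) / r)
    }
    if (scene$outlier_count > 0) {
      ob <- scene$outlier_box
      op <- sapply(1:3, function(d)
        runif(scene$outlier_count, ob$min_corner[d], ob$max_corner[d]))
      if (is.null(dim(op))) op <- matrix(op, ncol = 3)
      oc <- transform_cloud(point_cloud(op), cam_inv, frame = "camera")
      oc$attrs$label <- rep("outlier", scene$outlier_count)
      out <- cloud_bind(out, oc)
    }
    if (scene$clutter_count > 0 && n_points(out) > 0) {
      # flying-pixel clutter: stray returns hanging off the captured surface
      # in random directions, as time-of-flight sensors produce at depth
      # discontinuities; candidates closer than the lower clutter range to
      # any captured point are rejected so the clutter is genuinely stray
      cp <- matrix(numeric(0), ncol = 3)
      for (round in 1:6) {
        need <- scene$clutter_count - nrow(cp)
        if (need <= 0) break
        src <- sample.int(n_points(out), 2 * need, replace = TRUE)
        dir <- matrix(rnorm(6 * need), ncol = 3)
        dir <- dir / sqrt(rowSums(dir^2))
        dist <- runif(2 * need, scene$clutter_range[1], scene$clutter_range[2])
        cand <- out$points[src, , drop = FALSE] + dir * dist
        clear <- cpp_knn(out$points, cand, 1L)$dist[, 1] >= scene$clutter_range[1]
        cand <- cand[clear, , drop = FALSE]
        cp <- rbind(cp, cand[seq_len(min(need, nrow(cand))), , drop = FALSE])
      }
      if (nrow(cp) > 0) {
        cc <- point_cloud(cp, frame = "camera")
        cc$attrs$label <- rep("outlier", nrow(cp))
        out <- cloud_bind(out, cc)
      }
    }
    out
  })
}

perturb_pose <- function(pose, rot_sd_deg, trans_sd_m) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- rnorm(1, 0, rot_sd_deg) * pi / 180
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  Rerr <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  rigid_transform(Rerr %*% pose$R, pose$T + rnorm(3, 0, trans_sd_m))
}

#' Generate a full synthetic three-view scene
#'
#' Places the sampled sheep on the pen floor with a random yaw (and smaller
#' pitch) tilt, adds floor points, renders the three camera views with
#' noise, occlusion and outliers, and records the full ground truth: exact
#' body dimensions, the tilt, true camera poses, and the slightly perturbed
#' "calibrated" poses a real multi-camera calibration would hand the
#' pipeline.
#'
#' @param sheep a [sheep_params()].
#' @param scene a [scene_params()].
#' @param seed integer master seed; every random stage derives from it.
#' @return an object of class `sheep_scene`: `views` (named list of
#'   camera-frame [point_cloud()]s with `label`/`part` attrs), `cameras`
#'   (true poses), `calib` (calibrated camera-to-world transforms),
#'   `truth` (dims, tilt angles, body transform) and the parameter sets.
#' @export
make_scene <- function(sheep = sheep_params(), scene = scene_params(),
                       seed = 1) {
  surf <- make_sheep_surface(sheep, density = scene$body_density)
  body <- surf$cloud
  # tilt: yaw within +/- tilt_deg, pitch within a quarter of it
  yaw <- with_seed(derive_seed(seed, "tilt"),
                  runif(2, -scene$tilt_deg, scene$tilt_deg))
  pitch <- yaw[2] / 4
  rt_tilt <- rt_compose(rt_axis_rotation("z", yaw[1]),
                        rt_axis_rotation("y", pitch))
  ctr <- colMeans(body$points)
  body_w <- transform_cloud(body, rigid_transform(
    rt_tilt$R, as.numeric(ctr - rt_tilt$R %*% ctr)), frame = "world")
  lift <- scene$ground_z - min(body_w$points[, 3])
  body_rt <- rigid_transform(rt_tilt$R,
                             as.numeric(ctr - rt_tilt$R %*% ctr) + c(0, 0, lift))
  body_w <- transform_cloud(body, body_rt, frame = "world")
  nrm <- cbind(body$attrs$nx, body$attrs$ny, body$attrs$nz) %*% t(body_rt$R)
  body_w$attrs$nx <- nrm[, 1]; body_w$attrs$ny <- nrm[, 2]
  body_w$attrs$nz <- nrm[, 3]
  body_w$attrs$label <- rep("body", n_points(body_w))
  ground <- with_seed(derive_seed(seed, "ground"), {
    he <- scene$ground_half_extent
    ng <- round(4 * he[1] * he[2] * scene$ground_density)
    point_cloud(cbind(runif(ng, -he[1], he[1]), runif(ng, -he[2], he[2]),
                      rep(scene$ground_z, ng)),
                list(label = rep("ground", ng), part = rep("ground", ng),
                     nx = rep(0, ng), ny = rep(0, ng), nz = rep(1, ng)),
                frame = "world")
  })
  world <- cloud_bind(body_w, ground)
  cams <- if (is.null(scene$cameras)) default_cameras() else scene$cameras
  views <- list()
  calib <- list()
  for (nm in names(cams)) {
    views[[nm]] <- render_view(world, cams[[nm]], scene,
                               seed = derive_seed(seed, paste0("view_", nm)))
    views[[nm]]$frame <- paste0("camera_", nm)
    calib[[nm]] <- with_seed(derive_seed(seed, paste0("calib_", nm)),
                             perturb_pose(cams[[nm]]$pose,
                                          scene$calib_rot_sd_deg,
                                          scene$calib_trans_sd_m))
  }
  structure(list(views = views, cameras = cams, calib = calib,
                 truth = list(dims = surf$dims,
                              body_length = surf$dims$body_length,
                              yaw_deg = yaw[1], pitch_deg = pitch,
                              body_transform = body_rt),
                 sheep = sheep, scene = scene, seed = seed),
            class = "sheep_scene")
}

#' @export
print.sheep_scene <- function(x, ...) {
  cat("<sheep_scene> seed", x$seed, "\n")
  for (nm in names(x$views))
    cat(sprintf("  %-6s %5d points\n", nm, n_points(x$views[[nm]])))
  cat(sprintf("  truth: body length %.1f cm, yaw %.1f deg, pitch %.1f deg\n",
              100 * x$truth$body_length, x$truth$yaw_deg, x$truth$pitch_deg))
  invisible(x)
}
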