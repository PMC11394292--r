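#' Closed-form rigid alignment of paired points (Kabsch/SVD)
#'
#' Returns the rotation and translation minimising
#' `sum ||q_i - (R p_i + T)||^2` via SVD of the centred cross-covariance,
#' with determinant correction so a proper rotation (no reflection) is
#' always returned.
#'
#' @param P,Q k x 3 matrices of paired points (k >= 3, P not collinear).
#' @return a [rigid_transform()] mapping `P` onto `Q`.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) < 3 || nrow(Q) != nrow(P)) stop("need >= 3 paired points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)  # sum p_i q_i^T
  s <- svd(H)
  if (s$d[2] < 1e-12 * max(s$d[1], 1e-300))
    stop("degenerate geometry: paired points are collinear")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, as.numeric(cq - R %*% cp))
}

# Rotation-invariant local-geometry descriptor per point: neighbourhood
# shape (eigenvalue ratios), spread, centroid offset, and a short histogram
# of neighbour distances over a fixed radius.
local_descriptors <- function(points, radius = 0.05, k_max = 30L) {
  n <- nrow(points)
  k <- min(k_max, n)
  nn <- cpp_knn(points, points, as.integer(k))
  nbins <- 4L
  desc <- matrix(0, n, 6 + nbins)
  for (i in seq_len(n)) {
    d <- nn$dist[i, -1]
    sel <- which(d <= radius)
    if (length(sel) < 3) next
    idx <- nn$idx[i, -1][sel]
    nb <- points[idx, , drop = FALSE]
    rel <- sweep(nb, 2, points[i, ])
    C <- crossprod(rel) / nrow(rel)
    ev <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
    ctr <- colMeans(rel)
    hist_d <- tabulate(pmin(ceiling(d[sel] / radius * nbins), nbins), nbins)
    desc[i, ] <- c(length(sel) / k,
                   sqrt(ev[2] / max(ev[1], 1e-20)),
                   sqrt(ev[3] / max(ev[1], 1e-20)),
                   sqrt(ev[1]) / radius,
                   sqrt(sum(ctr^2)) / radius,
                   mean(d[sel]) / radius,
                   hist_d / length(sel))
  }
  desc
}

#' Match points between two clouds by local-geometry descriptors
#'
#' Computes a rotation-invariant descriptor per point (neighbourhood shape
#' and distance statistics over a fixed radius) and returns mutual
#' nearest-descriptor pairs. Deterministic; each source index appears at
#' most once.
#'
#' @param src,dst non-empty [point_cloud()]s.
#' @param radius descriptor neighbourhood radius in metres.
#' @param max_ratio keep a pair only if its descriptor distance is below
#'   `max_ratio` times the median mutual-pair distance (loose mismatch gate).
#' @return a data frame with columns `src`, `dst`, `score` (descriptor
#'   distance); zero rows when the clouds are too sparse for the radius.
#' @export
match_features <- function(src, dst, radius = 0.05, max_ratio = 3) {
  stopifnot(inherits(src, "point_cloud"), inherits(dst, "point_cloud"))
  if (n_points(src) == 0 || n_points(dst) == 0) stop("empty cloud")
  ds <- local_descriptors(src$points, radius)
  dd <- local_descriptors(dst$points, radius)
  ok_s <- rowSums(ds != 0) > 0
  ok_d <- rowSums(dd != 0) > 0
  if (sum(ok_s) < 3 || sum(ok_d) < 3)
    return(data.frame(src = integer(0), dst = integer(0), score = numeric(0)))
  is_ <- which(ok_s); id_ <- which(ok_d)
  fwd <- cpp_knn(dd[id_, , drop = FALSE], ds[is_, , drop = FALSE], 1L)
  bwd <- cpp_knn(ds[is_, , drop = FALSE], dd[id_, , drop = FALSE], 1L)
  mutual <- bwd$idx[fwd$idx[, 1], 1] == seq_along(is_)
  pairs <- data.frame(src = is_[mutual],
                      dst = id_[fwd$idx[mutual, 1]],
                      score = fwd$dist[mutual, 1])
  if (nrow(pairs) > 0) {
    gate <- max_ratio * max(median(pairs$score), 1e-12)
    pairs <- pairs[pairs$score <= gate, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  pairs
}

#' Coarse registration by correspondence RANSAC
#'
#' Per iteration, three non-collinear correspondence pairs are sampled, the
#' rigid transform solved in closed form ([kabsch()]), and the mean squared
#' distance K from the transformed matched source points to their targets is
#' compared with the threshold `v_thresh`; iteration stops when `K <=
#' v_thresh` or after `t_iters` trials. The best transform is then refit on
#' the consensus pairs (those within `sqrt(3 * v_thresh)` of their targets).
#'
#' @param src,dst [point_cloud()]s.
#' @param corr correspondence data frame with columns `src`, `dst` (e.g. from
#'   [match_features()]); at least 3 pairs.
#' @param v_thresh mean-squared-error threshold V in square metres.
#' @param t_iters iteration cap t.
#' @param seed optional integer seed.
#' @return a list with `transform` ([rigid_transform()]), `k_mse` (final K
#'   over consensus pairs), `n_consensus`, and `converged`.
#' @export
ransac_coarse <- function(src, dst, corr, v_thresh = 1e-4, t_iters = 1000,
                          seed = NULL) {
  stopifnot(v_thresh > 0, t_iters >= 1)
  if (nrow(corr) < 3) stop("need at least 3 correspondence pairs")
  P <- src$points[corr$src, , drop = FALSE]
  Q <- dst$points[corr$dst, , drop = FALSE]
  m <- nrow(P)
  with_seed(seed, {
    best_rt <- NULL; best_k <- Inf
    for (it in seq_len(t_iters)) {
      rt <- NULL
      for (try in 1:10) {
        s <- sample.int(m, 3)
        a <- crossprod3(P[s[2], ] - P[s[1], ], P[s[3], ] - P[s[1], ])
        if (sqrt(sum(a^2)) < 1e-12) next  # collinear sample: resample
        rt <- tryCatch(kabsch(P[s, ], Q[s, ]), error = function(e) NULL)
        if (!is.null(rt)) break
      }
      if (is.null(rt)) next
      res <- Q - (P %*% t(rt$R) + rep(1, m) %o% rt$T)
      K <- mean(rowSums(res^2))
      if (K < best_k) { best_k <- K; best_rt <- rt }
      if (best_k <= v_thresh) break
    }
    if (is.null(best_rt)) stop("degenerate geometry: no valid sample found")
    # consensus refit on pairs within sqrt(3 V) of their targets
    res <- Q - (P %*% t(best_rt$R) + rep(1, m) %o% best_rt$T)
    d2 <- rowSums(res^2)
    consensus <- d2 <= 3 * v_thresh
    if (sum(consensus) >= 3) {
      refit <- tryCatch(kabsch(P[consensus, , drop = FALSE],
                               Q[consensus, , drop = FALSE]),
                        error = function(e) NULL)
      if (!is.null(refit)) {
        res2 <- Q[consensus, , drop = FALSE] -
          (P[consensus, , drop = FALSE] %*% t(refit$R) +
             rep(1, sum(consensus)) %o% refit$T)
        best_rt <- refit
        best_k <- mean(rowSums(res2^2))
      }
    }
    list(transform = best_rt, k_mse = best_k, n_consensus = sum(consensus),
         converged = sum(consensus) >= 3 && best_k <= v_thresh)
  })
}

#' Iterative closest point (ICP) fine registration
#'
#' Classic point-to-point ICP: transform the source by the current estimate,
#' pair each transformed point with its exact nearest neighbour in the
#' target, solve the rigid alignment in closed form, and repeat. The
#' objective `f(R,T) = (1/n) sum ||q_i - (R p_i + T)||^2` is recorded each
#' iteration and is non-increasing; iteration stops when the change between
#' consecutive objective values falls below `eps` or `max_iters` is reached.
#'
#' @param src,dst [point_cloud()]s with at least 3 points.
#' @param init initial [rigid_transform()] estimate (e.g. from
#'   [ransac_coarse()]).
#' @param max_iters iteration cap (default 50).
#' @param eps convergence threshold on `|f_(n+1) - f_n|` in square metres
#'   (default 1e-6).
#' @param max_corr_dist correspondence distance gate in metres: pairs whose
#'   nearest-neighbour distance exceeds it are excluded from the alignment
#'   step, the standard guard for partially overlapping clouds. `Inf`
#'   (default) is the classic ungated algorithm.
#' @param symmetric when `TRUE`, correspondences are collected in both
#'   directions (source to target and target to source) and pooled before
#'   the alignment solve, which cancels the first-order boundary pull that
#'   one-sided matching exerts on partially overlapping clouds.
#' @return a list with `transform`, `mse_history`, `n_iters`, `converged`,
#'   and `overlap` (diagnostic: fraction of source points whose nearest
#'   target neighbour is within twice the median pairing distance).
#' @export
icp <- function(src, dst, init = rt_identity(), max_iters = 50, eps = 1e-6,
                max_corr_dist = Inf, symmetric = FALSE) {
  stopifnot(inherits(src, "point_cloud"), inherits(dst, "point_cloud"))
  if (n_points(src) < 3 || n_points(dst) < 3) stop("need >= 3 points per cloud")
  P <- src$points
  D <- dst$points
  rt <- init
  history <- numeric(0)
  converged <- FALSE
  nn <- NULL
  for (it in seq_len(max_iters)) {
    Pt <- P %*% t(rt$R) + rep(1, nrow(P)) %o% rt$T
    nn <- cpp_knn(D, Pt, 1L)
    sel <- which(nn$dist[, 1] <= max_corr_dist)
    if (length(sel) < 3) break  # overlap lost: report non-converged
    Pp <- P[sel, , drop = FALSE]
    Qm <- D[nn$idx[sel, 1], , drop = FALSE]
    if (symmetric) {
      bw <- cpp_knn(Pt, D, 1L)
      sel2 <- which(bw$dist[, 1] <= max_corr_dist)
      Pp <- rbind(Pp, P[bw$idx[sel2, 1], , drop = FALSE])
      Qm <- rbind(Qm, D[sel2, , drop = FALSE])
    }
    step <- tryCatch(kabsch(Pp, Qm), error = function(e) NULL)
    if (is.null(step)) break  # degenerate pairing: report non-converged
    rt <- step
    Pt2 <- Pp %*% t(rt$R) + rep(1, nrow(Pp)) %o% rt$T
    f <- mean(rowSums((Qm - Pt2)^2))
    history <- c(history, f)
    if (it > 1 && abs(history[it] - history[it - 1]) < eps) {
      converged <- TRUE
      break
    }
  }
  overlap <- if (!is.null(nn)) {
    med <- median(nn$dist[, 1])
    mean(nn$dist[, 1] <= 2 * max(med, 1e-12))
  } else NA_real_
  list(transform = rt, mse_history = history, n_iters = length(history),
       converged = converged, overlap = overlap)
}

#' Register three views into a common frame
#'
#' Registers the side and front views onto the top view (the reference
#' frame). The initial transform per view comes from the supplied `init`
#' list when available (camera calibration, the usual case) and otherwise
#' from feature matching ([match_features()]) plus coarse RANSAC
#' ([ransac_coarse()]); either way it is refined by distance-gated [icp()].
#'
#' @param views named list of three [point_cloud()]s: `top`, `side`, `front`.
#' @param init optional named list of initial [rigid_transform()]s for
#'   `side`/`front` (identity when the views are already roughly aligned by
#'   calibration). Views without an entry fall back to the coarse stage.
#' @param coarse_params list of [ransac_coarse()] settings
#'   (`v_thresh`, `t_iters`, `seed`) and `radius` for [match_features()].
#' @param icp_params list of [icp()] settings (`max_iters`, `eps`,
#'   `max_corr_dist`, `symmetric`) plus the trust region
#'   (`trust_rot_deg`, `trust_trans`): a refinement that strays further
#'   than this from its initial estimate, or worsens the gated alignment
#'   error, is rejected in favour of the initial estimate. Defaults are
#'   tuned for partially overlapping calibrated views (20 mm gate,
#'   symmetric matching, 1.5 degrees / 15 mm trust).
#' @return a list with `merged` (the union cloud in the reference frame,
#'   carrying a `view_id` attribute: 1 = top, 2 = side, 3 = front) and
#'   `transforms` (named list of per-view [rigid_transform()]s).
#' @export
register_views <- function(views, init = NULL, coarse_params = list(),
                           icp_params = list()) {
  stopifnot(is.list(views), all(c("top", "side", "front") %in% names(views)))
  cp <- utils::modifyList(list(v_thresh = 1e-4, t_iters = 1000, seed = NULL,
                               radius = 0.05), coarse_params)
  ip <- utils::modifyList(list(max_iters = 100, eps = 1e-7,
                               max_corr_dist = 0.02, symmetric = TRUE,
                               trust_rot_deg = 1.5, trust_trans = 0.015),
                          icp_params)
  ref <- views$top
  if (n_points(ref) == 0) stop("empty reference (top) view")
  gated_rmse <- function(cloud, anchor, rt) {
    p <- transform_cloud(cloud, rt)
    d <- cpp_knn(anchor$points, p$points, 1L)$dist[, 1]
    sqrt(mean(pmin(d, ip$max_corr_dist)^2))
  }
  transforms <- list(top = rt_identity())
  anchor <- ref
  registered <- list(top = ref)
  for (nm in c("side", "front")) {
    v <- views[[nm]]
    if (n_points(v) == 0) stop("empty ", nm, " view")
    if (!is.null(init[[nm]])) {
      start <- init[[nm]]
    } else {
      # feature matching runs against the reference view (duplicated points
      # in the growing anchor would distort the local descriptors)
      corr <- match_features(v, ref, radius = cp$radius)
      if (nrow(corr) < 3)
        stop("registration failed for view '", nm,
             "' at stage coarse: too few feature correspondences")
      coarse <- ransac_coarse(v, ref, corr, v_thresh = cp$v_thresh,
                              t_iters = cp$t_iters, seed = cp$seed)
      if (!coarse$converged)
        stop("registration failed for view '", nm,
             "' at stage coarse: no converged estimate")
      start <- coarse$transform
    }
    fine <- icp(v, anchor, init = start, max_iters = ip$max_iters,
                eps = ip$eps, max_corr_dist = ip$max_corr_dist,
                symmetric = ip$symmetric)
    # trust region around the initial estimate: when an initial transform
    # was supplied (calibration), a refinement that strays far from it or
    # worsens the gated alignment error is rejected in favour of the start
    delta <- rt_compose(fine$transform, rt_invert(start))
    trusted <- fine$converged &&
      rotation_angle_deg(delta) <= ip$trust_rot_deg &&
      sqrt(sum(delta$T^2)) <= ip$trust_trans &&
      gated_rmse(v, anchor, fine$transform) <= gated_rmse(v, anchor, start)
    if (!trusted && is.null(init[[nm]]))
      stop("registration failed for view '", nm, "' at stage icp: ",
           "no trusted convergence in ", ip$max_iters, " iterations")
    rt <- if (trusted) fine$transform else start
    transforms[[nm]] <- rt
    registered[[nm]] <- transform_cloud(v, rt, frame = ref$frame)
    # incremental anchoring: the next view registers against everything
    # aligned so far, which constrains views with little mutual overlap
    anchor <- cloud_bind(anchor, registered[[nm]])
  }
  for (i in seq_along(registered))
    registered[[i]]$attrs$view_id <- rep(i, n_points(registered[[i]]))
  list(merged = cloud_bind(registered), transforms = transforms)
}
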