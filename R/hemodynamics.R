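# Haemodynamic markers: wall shear stress by near-wall velocity fitting,
# time-averaged WSS, oscillatory shear index, axial/circumferential
# decomposition, normalized flow displacement, and the per-subject summary.

#' Trilinear velocity interpolation
#'
#' Interpolates each velocity component trilinearly; exact on affine fields.
#'
#' @param field a [velocity_field()].
#' @param points n x 3 world coordinates, mm (must lie inside the grid
#'   bounding box).
#' @param frame 1-based frame index.
#' @return n x 3 matrix of velocities, m/s.
#' @export
interpolate_velocity <- function(field, points, frame = 1L) {
  stopifnot(inherits(field, "velocity_field"))
  points <- matrix(points, ncol = 3)
  frac <- world_to_frac(points, field$spacing, field$origin)
  out <- matrix(0, nrow(points), 3)
  for (comp in 1:3)
    out[, comp] <- interp3(field$v[, , , frame, comp], frac, check = TRUE)
  out
}

#' Estimate wall shear stress by near-wall velocity fitting
#'
#' For each wall sample, velocity is sampled at distances `h, 2h, ..., n*h`
#' along the inward normal (`h = step_mm`, default half the smallest voxel
#' spacing; `n = n_points`, default 3), the no-slip zero at the wall is
#' enforced by fitting each tangential velocity component as
#' `a*d + b*d^2` by least squares through the origin, and the wall shear
#' stress vector is `mu` times the fitted wall gradient `a`, expressed in
#' world coordinates (tangent to the wall by construction). Sampling depths
#' that leave the lumen (thin or opposing walls) are dropped for that sample;
#' samples left with a single depth get a linear fit, samples with none are
#' flagged and returned as `NA`.
#'
#' @param field a [velocity_field()].
#' @param wall a [extract_wall_samples()] result (optionally subset).
#' @param frame 1-based frame index.
#' @param mu dynamic viscosity, Pa s.
#' @param fit list with `n_points` and `step_mm` (NULL = half min spacing).
#' @param seg optional [segmentation()] used to validate sampling depths.
#' @return object of class `wss_field`: `tau` (n x 3, Pa), `magnitude`,
#'   `n_depths_used`, and the wall geometry.
#' @export
estimate_wss <- function(field, wall, frame = 1L, mu = 3.2e-3,
                         fit = list(n_points = 3L, step_mm = NULL),
                         seg = NULL) {
  stopifnot(inherits(field, "velocity_field"))
  n_pts <- fit$n_points %||% 3L
  h <- fit$step_mm %||% (min(field$spacing) / 2)
  n <- nrow(wall$position)
  nrm <- wall$normal
  ok_nrm <- is.finite(rowSums(nrm)) & abs(vec_norm(nrm) - 1) < 1e-6
  if (!any(ok_nrm)) stop("all wall samples have degenerate normals")
  if (any(!ok_nrm)) warning(sum(!ok_nrm), " wall sample(s) skipped: degenerate normal")
  depths_mm <- h * seq_len(n_pts)
  tb <- tangent_basis(nrm)
  u1 <- u2 <- valid <- matrix(NA_real_, n, n_pts)
  for (j in seq_len(n_pts)) {
    pts <- wall$position + depths_mm[j] * nrm
    v <- interpolate_velocity(field, pts, frame)
    vn <- rowSums(v * nrm)
    vt <- v - vn * nrm
    u1[, j] <- rowSums(vt * tb$t1)
    u2[, j] <- rowSums(vt * tb$t2)
    inlum <- if (is.null(seg)) rep(TRUE, n) else
      mask_lookup(seg$mask[, , , frame], pts, seg$spacing, seg$origin)
    valid[, j] <- as.numeric(inlum & ok_nrm)
  }
  depths_m <- depths_mm / 1e3    # fit in SI so the gradient is 1/s
  a1 <- a2 <- rep(NA_real_, n)
  ndep <- rowSums(valid)
  pat <- apply(valid, 1, paste0, collapse = "")
  for (p in unique(pat)) {
    rows <- which(pat == p)
    use <- which(valid[rows[1], ] == 1)
    if (length(use) == 0) next
    if (length(use) == 1) {
      a1[rows] <- u1[rows, use] / depths_m[use]
      a2[rows] <- u2[rows, use] / depths_m[use]
    } else {
      X <- cbind(depths_m[use], depths_m[use]^2)
      P <- solve(crossprod(X), t(X))   # 2 x k through-origin LS operator
      a1[rows] <- u1[rows, use, drop = FALSE] %*% P[1, ]
      a2[rows] <- u2[rows, use, drop = FALSE] %*% P[1, ]
    }
  }
  tau <- mu * (a1 * tb$t1 + a2 * tb$t2)
  if (any(ndep == 0 & ok_nrm))
    warning(sum(ndep == 0 & ok_nrm),
            " wall sample(s) had no in-lumen sampling depth; WSS set to NA")
  structure(list(tau = tau, magnitude = vec_norm(tau),
                 n_depths_used = ndep, frame = frame, mu = mu,
                 position = wall$position, normal = nrm),
            class = "wss_field")
}

#' Peak-systolic frame
#'
#' The frame maximizing net forward flow through the most proximal analysis
#' plane (through-plane velocity times in-plane pixel area, summed over the
#' cross-section); ties broken by the earliest frame. The alternative rule
#' `"mean_speed"` picks the frame of maximum spatial-mean in-lumen speed.
#'
#' @param field a [velocity_field()].
#' @param region an [delimit_and_planes()] result.
#' @param rule `"plane_flow"` (default) or `"mean_speed"`.
#' @param seg required for `"mean_speed"`.
#' @return 1-based frame index, with attribute `flow` (per-frame flow, ml/s
#'   for `"plane_flow"`).
#' @export
find_peak_systole <- function(field, region = NULL,
                              rule = c("plane_flow", "mean_speed"),
                              seg = NULL) {
  rule <- match.arg(rule)
  nt <- dim(field$v)[4]
  if (rule == "plane_flow") {
    stopifnot(!is.null(region), length(region$planes) >= 1)
    pl <- region$planes[[1]]
    px_area <- pl$area / nrow(pl$points)          # mm^2
    q <- vapply(seq_len(nt), function(k) {
      v <- interpolate_velocity(field, pl$points, k)
      sum(v %*% pl$normal) * px_area * 1e3        # m/s * mm^2 -> mm^3/s... scaled
    }, numeric(1))
  } else {
    stopifnot(!is.null(seg))
    q <- vapply(seq_len(nt), function(k) {
      m <- seg$mask[, , , k] > 0
      sp <- sqrt(field$v[, , , k, 1]^2 + field$v[, , , k, 2]^2 +
                 field$v[, , , k, 3]^2)
      mean(sp[m])
    }, numeric(1))
  }
  peak <- which.max(q)   # which.max returns the earliest maximum
  attr(peak, "flow") <- q
  peak
}

#' Time-averaged WSS per wall sample
#'
#' Rectangle-rule average of the WSS magnitude over the cardiac cycle,
#' `(1/T) sum |tau(t)| dt` with uniform frame duration; frames where a sample
#' has no WSS (unmatched wall correspondence) are zero-weight gaps and the
#' quadrature renormalizes over the remaining frames.
#'
#' @param tau_series n x 3 x n_frames array of WSS vectors, Pa.
#' @return numeric vector, Pa.
#' @export
compute_tawss <- function(tau_series) {
  mag <- sqrt(apply(tau_series^2, c(1, 3), sum))
  rowMeans(mag, na.rm = TRUE)
}

#' Oscillatory shear index per wall sample
#'
#' `OSI = 0.5 * (1 - ||sum tau dt|| / sum ||tau|| dt)` with rectangle-rule
#' quadrature; 0 when the denominator vanishes. Always in `[0, 0.5]`.
#'
#' @inheritParams compute_tawss
#' @return numeric vector in `[0, 0.5]`.
#' @export
compute_osi <- function(tau_series) {
  mag <- sqrt(apply(tau_series^2, c(1, 3), sum))
  num <- sqrt(apply(tau_series, c(1, 2), sum, na.rm = TRUE)^2 %*% rep(1, 3))
  den <- rowSums(mag, na.rm = TRUE)
  osi <- ifelse(den > 0, 0.5 * (1 - as.vector(num) / den), 0)
  pmin(pmax(osi, 0), 0.5)
}

#' Axial and circumferential WSS components
#'
#' At each wall sample the axial direction is the nearest centerline tangent
#' projected into the wall tangent plane and renormalized; the
#' circumferential direction is its cross product with the inward normal.
#' Returns the component magnitudes `|tau . axial|` and `|tau . circ|`.
#'
#' @param wss a [estimate_wss()] result (typically at the peak frame).
#' @param cl a [compute_centerline()] result.
#' @return data.frame with columns `axial` and `circumferential` (Pa); rows
#'   where the tangent is parallel to the normal are `NA` (skipped with a
#'   warning).
#' @export
decompose_axial_circumferential <- function(wss, cl) {
  pr <- project_polyline(wss$position, cl)
  t_hat <- sapply(1:3, function(a) approx(cl$arc, cl$tangents[, a],
                                          xout = pmin(pmax(pr$s, 0),
                                                      max(cl$arc)))$y)
  t_hat <- matrix(t_hat, ncol = 3)
  nrm <- wss$normal
  ax <- t_hat - rowSums(t_hat * nrm) * nrm
  nn <- vec_norm(ax)
  bad <- nn < 1e-3
  if (any(bad))
    warning(sum(bad), " wall sample(s) skipped in the axial/circumferential ",
            "decomposition: centerline tangent parallel to the wall normal")
  ax <- ax / ifelse(bad, NA_real_, nn)
  circ <- cross_rows(nrm, ax)
  data.frame(axial = abs(rowSums(wss$tau * ax)),
             circumferential = abs(rowSums(wss$tau * circ)))
}

#' Normalized flow displacement in an analysis plane
#'
#' `FD = ||C_flow - C_lumen|| / D_eff`, where `C_lumen` is the unweighted
#' centroid of the cross-section points, `C_flow` the centroid weighted by
#' forward through-plane velocity (negative through-plane velocities clamped
#' to zero), and `D_eff = 2 sqrt(A/pi)` the effective diameter. `NA` when no
#' forward flow crosses the plane.
#'
#' @param field a [velocity_field()].
#' @param plane an `analysis_plane` from [delimit_and_planes()].
#' @param frame 1-based frame index (peak systole in the pipeline).
#' @return dimensionless fraction (scale by 100 for percent display).
#' @export
flow_displacement <- function(field, plane, frame) {
  v <- interpolate_velocity(field, plane$points, frame)
  fwd <- pmax(as.vector(v %*% plane$normal), 0)
  if (sum(fwd) <= 0) return(NA_real_)
  c_flow <- colSums(plane$points * fwd) / sum(fwd)
  c_lumen <- colMeans(plane$points)
  d_eff <- 2 * sqrt(plane$area / pi)
  sqrt(sum((c_flow - c_lumen)^2)) / d_eff
}

#' Regional summary: mean and maximum
#'
#' Wall-sample statistics use the unweighted arithmetic mean and, as the
#' "maximum", the `percentile`-th percentile (default 99) by linear
#' interpolation between order statistics. Plane statistics (flow
#' displacement over at most seven planes) use the mean and the plain
#' maximum.
#'
#' @param x numeric values (per wall sample or per plane); `NA`s dropped.
#' @param type `"wall"` or `"planes"`.
#' @param percentile percentile used as the wall maximum.
#' @return named vector `c(mean, max)`.
#' @export
summarize_region <- function(x, type = c("wall", "planes"), percentile = 99) {
  type <- match.arg(type)
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite values to summarize")
  mx <- if (type == "wall") percentile_linear(x, percentile) else max(x)
  c(mean = mean(x), max = mx)
}

#' Per-subject haemodynamic summary
#'
#' Runs the full per-subject pipeline: geometry (wall samples, centerline,
#' ascending-aorta region, seven analysis planes), peak-systole selection,
#' WSS at every frame, TAWSS and OSI over the cycle, the
#' axial/circumferential decomposition at peak systole, and flow displacement
#' in all planes, then reduces to the ten reported scalars.
#'
#' Per-frame wall samples come from that frame's mask; the centerline and the
#' planes are fixed at the peak-systolic frame. Per-sample time series are
#' built by nearest-neighbour correspondence from the peak-frame wall to each
#' frame's wall, capped at one voxel (identity when the segmentation is
#' static).
#'
#' @param field a [velocity_field()].
#' @param seg a [segmentation()] on the same grid.
#' @param lm a [landmarks()] object.
#' @param config an [default_config()] list.
#' @return object of class `hemo_summary` with the ten scalars
#'   (`mean_peak_wss`, `max_peak_wss`, `mean_tawss`, `max_tawss`, `mean_osi`,
#'   `max_osi`, `mean_fd`, `max_fd`, `axial_mean_wss_peak`,
#'   `circ_mean_wss_peak`), `peak_frame`, and provenance.
#' @export
subject_summary <- function(field, seg, lm, config = default_config()) {
  if (!grids_agree(field, seg))
    stop("velocity and segmentation grids disagree (shape, spacing or origin)")
  nt <- dim(field$v)[4]
  static_mask <- all(vapply(seq_len(nt), function(k)
    identical(seg$mask[, , , k], seg$mask[, , , 1]), logical(1)))
  # provisional peak (cheap), geometry there, then the configured rule
  f0 <- find_peak_systole(field, rule = "mean_speed", seg = seg)
  geo <- build_geometry(seg, f0, lm, config)
  peak <- if (config$peak_rule == "plane_flow")
    find_peak_systole(field, geo$region, rule = "plane_flow")
  else f0
  if (peak != f0 && !static_mask) geo <- build_geometry(seg, peak, lm, config)
  wall <- geo$wall; region <- geo$region
  member <- region_membership(wall, region)
  rwall <- subset_wall(wall, member)
  fitp <- list(n_points = config$fit$n_points,
               step_mm = config$fit$step_mm %||% (min(field$spacing) / 2))
  n_reg <- nrow(rwall$position)
  tau_series <- array(NA_real_, c(n_reg, 3, nt))
  for (k in seq_len(nt)) {
    wk <- if (static_mask) rwall else {
      wf <- extract_wall_samples(seg, k, smooth = config$smooth_normals)
      mf <- region_membership(wf, region)
      subset_wall(wf, mf)
    }
    wssk <- estimate_wss(field, wk, frame = k, mu = config$mu, fit = fitp,
                         seg = seg)
    if (static_mask) {
      tau_series[, , k] <- wssk$tau
    } else {
      idx <- nearest_correspondence(rwall$position, wk$position,
                                    cap = max(field$spacing))
      hit <- !is.na(idx)
      tau_series[hit, , k] <- wssk$tau[idx[hit], ]
    }
    if (k == peak) wss_peak <- list(tau = wssk$tau, position = wk$position,
                                    normal = wk$normal)
  }
  peak_mag <- vec_norm(tau_series[, , peak])
  tawss <- compute_tawss(tau_series)
  osi <- compute_osi(tau_series)
  dec <- decompose_axial_circumferential(
    structure(wss_peak, class = "wss_field"), region$centerline)
  fd <- vapply(region$planes, function(pl)
    flow_displacement(field, pl, peak), numeric(1))
  fd_scale <- if (config$fd_scale == "percent") 100 else 1
  pw <- summarize_region(peak_mag, "wall", config$percentile)
  tw <- summarize_region(tawss, "wall", config$percentile)
  os <- summarize_region(osi, "wall", config$percentile)
  fds <- summarize_region(fd * fd_scale, "planes")
  structure(list(
    mean_peak_wss = pw[["mean"]], max_peak_wss = pw[["max"]],
    mean_tawss = tw[["mean"]], max_tawss = tw[["max"]],
    mean_osi = os[["mean"]], max_osi = os[["max"]],
    mean_fd = fds[["mean"]], max_fd = fds[["max"]],
    axial_mean_wss_peak = mean(dec$axial, na.rm = TRUE),
    circ_mean_wss_peak = mean(dec$circumferential, na.rm = TRUE),
    peak_frame = as.integer(peak),
    n_wall_samples = n_reg, n_planes_defined = sum(is.finite(fd)),
    config_hash = config_hash(config)),
    class = "hemo_summary")
}

build_geometry <- function(seg, frame, lm, config) {
  wall <- extract_wall_samples(seg, frame, smooth = config$smooth_normals)
  cl <- compute_centerline(seg, frame, lm,
                           step_mm = config$centerline_step_mm)
  region <- delimit_and_planes(cl, lm, seg, frame, k = config$n_planes)
  list(wall = wall, region = region, frame = frame)
}

subset_wall <- function(wall, keep) {
  structure(list(position = wall$position[keep, , drop = FALSE],
                 normal = wall$normal[keep, , drop = FALSE],
                 owner = wall$owner[keep],
                 spacing = wall$spacing, origin = wall$origin,
                 frame = wall$frame),
            class = "wall_samples")
}

nearest_correspondence <- function(from, to, cap) {
  n <- nrow(from)
  idx <- rep(NA_integer_, n)
  chunk <- max(1L, floor(2e6 / max(1, nrow(to))))
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1)
    d2 <- outer(rowSums(from[s:e, , drop = FALSE]^2), rowSums(to^2), `+`) -
      2 * from[s:e, , drop = FALSE] %*% t(to)
    j <- max.col(-d2, ties.method = "first")
    dd <- sqrt(pmax(d2[cbind(seq_len(e - s + 1), j)], 0))
    idx[s:e] <- ifelse(dd <= cap, j, NA_integer_)
  }
  idx
}

#' @export
print.hemo_summary <- function(x, ...) {
  cat("<hemo_summary>  peak frame", x$peak_frame, "|",
      x$n_wall_samples, "regional wall samples\n")
  cat(sprintf("  peak WSS  mean %.3f  max %.3f Pa\n",
              x$mean_peak_wss, x$max_peak_wss))
  cat(sprintf("  TAWSS     mean %.3f  max %.3f Pa\n",
              x$mean_tawss, x$max_tawss))
  cat(sprintf("  OSI       mean %.4f max %.4f\n", x$mean_osi, x$max_osi))
  cat(sprintf("  flow disp mean %.4f max %.4f\n", x$mean_fd, x$max_fd))
  cat(sprintf("  axial/circ mean WSS at peak: %.3f / %.3f Pa\n",
              x$axial_mean_wss_peak, x$circ_mean_wss_peak))
  invisible(x)
}
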