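# Geometry: wall samples with inward normals from a binary lumen mask,
# centerline between the two landmarks, ascending-aorta delimitation and the
# seven equidistant analysis planes.

shift_array <- function(arr, axis, by, fill = 0) {
  dm <- dim(arr)
  out <- array(fill, dm)
  idx_src <- idx_dst <- lapply(dm, seq_len)
  n <- dm[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) { idx_dst[[axis]] <- (1 + by):n; idx_src[[axis]] <- 1:(n - by) }
  if (by < 0) { idx_dst[[axis]] <- 1:(n + by); idx_src[[axis]] <- (1 - by):n }
  out <- do.call(`[<-`, c(list(out), idx_dst, list(do.call(`[`, c(list(arr), idx_src)))))
  out
}

# 6- or 26-connected component labelling; returns logical array of the
# component containing `seed_lin`, or the largest component when seed is NULL.
mask_component <- function(mask, seed_lin = NULL, conn = 6L) {
  dm <- dim(mask)
  offs <- conn_offsets(conn)
  inside <- mask > 0
  visited <- array(FALSE, dm)
  best <- NULL; best_size <- -1L; n_comp <- 0L
  todo <- if (is.null(seed_lin)) which(inside) else seed_lin
  for (start in todo) {
    if (visited[start] || !inside[start]) next
    n_comp <- n_comp + 1L
    comp <- array(FALSE, dm)
    frontier <- start
    comp[frontier] <- TRUE; visited[frontier] <- TRUE
    while (length(frontier)) {
      ijk <- lin_to_ijk(frontier, dm)
      nxt <- integer(0)
      for (o in seq_len(nrow(offs))) {
        nb <- sweep(ijk, 2, offs[o, ], `+`)
        ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 &
              nb[, 2] <= dm[2] & nb[, 3] >= 1 & nb[, 3] <= dm[3]
        if (!any(ok)) next
        lin <- ijk_to_lin(nb[ok, , drop = FALSE], dm)
        new <- lin[inside[lin] & !visited[lin]]
        if (length(new)) {
          visited[new] <- TRUE; comp[new] <- TRUE
          nxt <- c(nxt, new)
        }
      }
      frontier <- unique(nxt)
    }
    if (!is.null(seed_lin)) return(comp)
    size <- sum(comp)
    if (size > best_size) { best <- comp; best_size <- size }
  }
  attr(best, "n_components") <- n_comp
  best
}

conn_offsets <- function(conn) {
  if (conn == 6L) {
    rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
}

#' Extract wall sample points with inward normals
#'
#' One sample per boundary face of the mask: a face separating an inside
#' voxel from an outside voxel within the grid. The sample sits at the face
#' midpoint; its inward normal is the negated outward face normal, optionally
#' smoothed by averaging over all samples within a one-voxel radius and
#' renormalizing (recommended: raw face normals are quantized to the grid
#' axes, smoothed ones approximate the true surface normal).
#'
#' @param seg a [segmentation()].
#' @param frame 1-based frame index.
#' @param smooth smooth the face normals (default TRUE).
#' @param smooth_iters number of smoothing passes; each pass averages over
#'   the one-voxel neighbourhood, so two passes (the default) give an
#'   effective two-voxel support, which roughly halves the angular error of
#'   the quantized face normals on curved walls.
#' @return object of class `wall_samples`: `position` (n x 3, mm), `normal`
#'   (n x 3, unit, pointing into the lumen), `owner` (linear voxel index of
#'   the inside voxel), plus the grid metadata.
#' @export
extract_wall_samples <- function(seg, frame = 1L, smooth = TRUE,
                                 smooth_iters = 2L) {
  stopifnot(inherits(seg, "segmentation"))
  mask <- seg$mask[, , , frame]
  if (sum(mask) == 0) stop("mask frame ", frame, " is empty")
  comp <- mask_component(mask, conn = 6L)
  if (attr(comp, "n_components") > 1L) {
    warning("mask frame ", frame, " has ", attr(comp, "n_components"),
            " 6-connected components; using the largest")
    mask <- array(as.integer(comp), dim(mask))
  }
  dm <- dim(mask)
  pos <- list(); nrm <- list(); own <- list()
  axes <- diag(3)
  for (a in 1:3) for (d in c(1L, -1L)) {
    # neighbor in direction d along axis a; off-grid treated as inside (no face)
    nb <- shift_array(mask, a, -d, fill = 1)
    face <- which(mask == 1 & nb == 0)
    if (!length(face)) next
    ijk <- lin_to_ijk(face, dm)
    ctr <- voxel_centers(ijk, seg$spacing, seg$origin)
    mid <- ctr; mid[, a] <- mid[, a] + d * seg$spacing[a] / 2
    pos[[length(pos) + 1]] <- mid
    nrm[[length(nrm) + 1]] <-
      matrix(rep(-d * axes[a, ], each = length(face)), ncol = 3)
    own[[length(own) + 1]] <- face
  }
  if (!length(pos))
    stop("mask frame ", frame, " has no boundary faces within the grid")
  position <- do.call(rbind, pos)
  normal <- do.call(rbind, nrm)
  owner <- unlist(own)
  if (smooth) for (it in seq_len(smooth_iters))
    normal <- smooth_normals(position, normal, owner, dm, seg$spacing)
  structure(list(position = position, normal = normal, owner = owner,
                 spacing = seg$spacing, origin = seg$origin, frame = frame),
            class = "wall_samples")
}

# Average each sample's normal over all samples within a one-voxel radius
# (Euclidean, 1.001 * max spacing), then renormalize. Neighbour search by
# owner-voxel binning over the 27-neighbourhood.
smooth_normals <- function(position, normal, owner, dm, spacing) {
  n <- nrow(position)
  radius <- 1.001 * max(spacing)
  ijk <- lin_to_ijk(owner, dm)
  keys <- ijk_to_lin(ijk, dm)
  uk <- sort(unique(keys))
  grp <- match(keys, uk)
  by_vox <- split(seq_len(n), grp)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  acc <- matrix(0, n, 3)
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(ijk, 2, offs[o, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 &
          nb[, 2] <= dm[2] & nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (!any(ok)) next
    g <- match(ijk_to_lin(nb[ok, , drop = FALSE], dm), uk)
    hit <- which(ok)[!is.na(g)]
    g <- g[!is.na(g)]
    if (!length(hit)) next
    lens <- lengths(by_vox)[g]
    i_rep <- rep(hit, lens)
    j <- unlist(by_vox[g], use.names = FALSE)
    d2 <- rowSums((position[i_rep, , drop = FALSE] -
                   position[j, , drop = FALSE])^2)
    keep <- d2 <= radius^2
    if (!any(keep)) next
    i_rep <- i_rep[keep]; j <- j[keep]
    acc <- acc + rowsum_fill(normal[j, , drop = FALSE], i_rep, n)
  }
  sm <- normalize_rows(acc)
  bad <- !is.finite(sm[, 1])   # cancelled normals: keep the raw face normal
  sm[bad, ] <- normal[bad, ]
  sm
}

rowsum_fill <- function(x, group, n) {
  out <- matrix(0, n, ncol(x))
  rs <- rowsum(x, group)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

#' Centerline between the valve and brachiocephalic-trunk landmarks
#'
#' Shortest 26-connected inside-mask voxel path (Euclidean edge weights)
#' between the landmark voxels, refined by replacing each node with the
#' centroid of its perpendicular lumen cross-section (two passes), smoothed
#' with a 3-point moving average and resampled to uniform arc-length steps.
#' Tangents by central differences, renormalized.
#'
#' @param seg a [segmentation()].
#' @param frame 1-based frame index.
#' @param lm a [landmarks()] object.
#' @param step_mm resampling step along the arc, mm.
#' @return object of class `centerline`: `points` (m x 3, mm), `tangents`
#'   (m x 3, unit), `arc` (cumulative arc length, mm).
#' @export
compute_centerline <- function(seg, frame = 1L, lm, step_mm = 1) {
  stopifnot(inherits(seg, "segmentation"), inherits(lm, "landmarks"))
  mask <- seg$mask[, , , frame]
  dm <- dim(mask)
  sp <- seg$spacing
  inside_lin <- which(mask > 0)
  if (!length(inside_lin)) stop("mask frame ", frame, " is empty")
  v_lin <- resolve_landmark(lm$valve, mask, sp, seg$origin, "valve")
  b_lin <- resolve_landmark(lm$bct, mask, sp, seg$origin, "brachiocephalic trunk")
  if (v_lin == b_lin)
    stop("valve and brachiocephalic-trunk landmarks resolve to the same voxel")
  vid <- integer(prod(dm))
  vid[inside_lin] <- seq_along(inside_lin)
  offs <- conn_offsets(26L)
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
               (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), , drop = FALSE]
  ijk <- lin_to_ijk(inside_lin, dm)
  from <- to <- w <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(ijk, 2, offs[o, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 &
          nb[, 2] <= dm[2] & nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (!any(ok)) next
    nb_lin <- ijk_to_lin(nb[ok, , drop = FALSE], dm)
    hit <- vid[nb_lin] > 0
    from[[o]] <- vid[inside_lin[ok]][hit]
    to[[o]] <- vid[nb_lin[hit]]
    w[[o]] <- rep(sqrt(sum((offs[o, ] * sp)^2)), sum(hit))
  }
  g <- igraph::make_graph(rbind(unlist(from), unlist(to)),
                          n = length(inside_lin), directed = FALSE)
  sp_out <- suppressWarnings(igraph::shortest_paths(
    g, from = vid[v_lin], to = vid[b_lin], weights = unlist(w),
    output = "vpath"))
  path <- as.integer(sp_out$vpath[[1]])
  if (length(path) < 2)
    stop("landmarks are not connected through the mask ",
         "(no inside-mask path from valve to brachiocephalic trunk)")
  pts <- voxel_centers(lin_to_ijk(inside_lin[path], dm), sp, seg$origin)
  pts <- moving_average(pts, 3L)
  # resample the voxel path to the target arc step first, so the centroid
  # refinement cost is independent of the voxel resolution
  pts <- resample_polyline(pts, step_mm)$points
  # two refinement passes: tangents -> perpendicular cross-section centroids
  centers_inside <- voxel_centers(lin_to_ijk(inside_lin, dm), sp, seg$origin)
  for (pass in 1:2) {
    tg <- polyline_tangents(pts)
    new_pts <- pts
    for (i in seq_len(nrow(pts))) {
      cs <- slab_voxels(centers_inside, pts[i, ], tg[i, ], sp)
      if (length(cs$idx) == 0) next
      keep <- slab_component(inside_lin[cs$idx], cs$seed_row, dm)
      new_pts[i, ] <- colMeans(cs$proj[keep, , drop = FALSE])
    }
    pts <- moving_average(new_pts, 3L)
  }
  res <- resample_polyline(pts, step_mm)
  structure(list(points = res$points, tangents = polyline_tangents(res$points),
                 arc = res$arc), class = "centerline")
}

resolve_landmark <- function(p, mask, spacing, origin, what) {
  dm <- dim(mask)
  idx <- round((p - origin) / spacing) + 1
  if (all(idx >= 1) && all(idx <= dm)) {
    lin <- ijk_to_lin(matrix(as.integer(idx), 1), dm)
    if (mask[lin] > 0) return(lin)
  }
  # snap to the nearest inside voxel, but only within ~1 voxel
  inside_lin <- which(mask > 0)
  ctr <- voxel_centers(lin_to_ijk(inside_lin, dm), spacing, origin)
  d2 <- rowSums(sweep(ctr, 2, p, `-`)^2)
  j <- which.min(d2)
  if (sqrt(d2[j]) > 1.5 * max(spacing))
    stop("the ", what, " landmark is not inside (or within one voxel of) the lumen")
  inside_lin[j]
}

polyline_tangents <- function(pts) {
  n <- nrow(pts)
  tg <- matrix(0, n, 3)
  if (n == 1) return(tg)
  tg[1, ] <- pts[2, ] - pts[1, ]
  tg[n, ] <- pts[n, ] - pts[n - 1, ]
  if (n > 2) tg[2:(n - 1), ] <- pts[3:n, ] - pts[1:(n - 2), ]
  normalize_rows(tg)
}

# voxel centers within half a voxel of the plane through `center` with
# normal `nrm`; returns their row indices, plane projections and the row
# nearest the center (slab seed)
slab_voxels <- function(centers, center, nrm, spacing) {
  half <- 0.5 * sum(abs(nrm) * spacing)
  rel <- sweep(centers, 2, center, `-`)
  dist_n <- rel %*% nrm
  idx <- which(abs(dist_n) <= half)
  if (!length(idx))
    return(list(idx = integer(0), proj = NULL, seed_row = NA))
  proj <- centers[idx, , drop = FALSE] -
    dist_n[idx] %*% matrix(nrm, nrow = 1)
  d2 <- rowSums(sweep(proj, 2, center, `-`)^2)
  list(idx = idx, proj = proj, seed_row = which.min(d2), half = half)
}

# 26-connected component of a voxel subset (linear indices into the grid)
# containing the seed row; BFS with match on the sorted index set
slab_component <- function(lin, seed_row, dm) {
  keys <- sort(lin)
  pos <- match(lin, keys)            # row -> sorted position
  keep <- logical(length(keys))
  offs <- conn_offsets(26L)
  frontier <- pos[seed_row]
  keep[frontier] <- TRUE
  while (length(frontier)) {
    ijk <- lin_to_ijk(keys[frontier], dm)
    nxt <- integer(0)
    for (o in seq_len(nrow(offs))) {
      nb <- sweep(ijk, 2, offs[o, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 &
            nb[, 2] <= dm[2] & nb[, 3] >= 1 & nb[, 3] <= dm[3]
      if (!any(ok)) next
      hit <- match(ijk_to_lin(nb[ok, , drop = FALSE], dm), keys)
      hit <- hit[!is.na(hit) & !keep[hit]]
      if (length(hit)) { keep[hit] <- TRUE; nxt <- c(nxt, hit) }
    }
    frontier <- unique(nxt)
  }
  which(pos %in% which(keep))
}

resample_polyline <- function(pts, step_mm) {
  seg_len <- sqrt(rowSums(diff(pts)^2))
  arc <- c(0, cumsum(seg_len))
  total <- arc[length(arc)]
  s_new <- seq(0, total, by = step_mm)
  if (s_new[length(s_new)] < total) s_new <- c(s_new, total)
  out <- sapply(1:3, function(a) approx(arc, pts[, a], xout = s_new)$y)
  list(points = out, arc = s_new)
}

# continuous projection of points onto the centerline polyline:
# returns arc length s of the nearest point and whether it was clamped at
# either polyline end
project_polyline <- function(points, cl) {
  pts <- cl$points; arc <- cl$arc
  n <- nrow(points)
  best_d2 <- rep(Inf, n); best_s <- numeric(n)
  clamp_lo <- logical(n); clamp_hi <- logical(n)
  nseg <- nrow(pts) - 1
  for (j in seq_len(nseg)) {
    a <- pts[j, ]; b <- pts[j + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    rel <- sweep(points, 2, a, `-`)
    t <- as.vector(rel %*% ab) / len2
    tc <- pmin(pmax(t, 0), 1)
    close <- sweep(rel, 2, c(0, 0, 0), `-`) - outer(tc, ab)
    d2 <- rowSums(close^2)
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      best_s[upd] <- arc[j] + tc[upd] * (arc[j + 1] - arc[j])
      clamp_lo[upd] <- j == 1 & t[upd] <= 0
      clamp_hi[upd] <- j == nseg & t[upd] >= 1
    }
  }
  list(s = best_s, dist = sqrt(best_d2),
       clamped = clamp_lo | clamp_hi)
}

#' Delimit the ascending aorta and place equidistant analysis planes
#'
#' The region is the centerline arc interval between the projections of the
#' valve and brachiocephalic-trunk landmarks. `k` planes are placed strictly
#' inside the region at arc fractions `i/(k+1)`, i = 1..k, each with the
#' local centerline tangent as its normal; a plane's lumen cross-section is
#' the set of mask voxels within half a voxel of the plane, restricted to the
#' connected component containing the centerline point, projected onto the
#' plane.
#'
#' @param cl a [compute_centerline()] result.
#' @param lm the [landmarks()].
#' @param seg the [segmentation()].
#' @param frame frame whose mask defines the cross-sections.
#' @param k number of planes (default 7).
#' @return object of class `aorta_region` with `s_valve`, `s_bct`, `planes`
#'   (list of `analysis_plane`: `center`, `normal`, `points` (projected voxel
#'   centers, mm), `area` (mm^2), `s`), and the centerline.
#' @export
delimit_and_planes <- function(cl, lm, seg, frame = 1L, k = 7L) {
  stopifnot(inherits(cl, "centerline"))
  if (k < 1) stop("k must be >= 1")
  pr <- project_polyline(rbind(lm$valve, lm$bct), cl)
  s_valve <- pr$s[1]; s_bct <- pr$s[2]
  if (s_valve >= s_bct)
    stop("degenerate region: the valve projection does not precede the ",
         "brachiocephalic-trunk projection on the centerline")
  mask <- seg$mask[, , , frame]
  dm <- dim(mask)
  inside_lin <- which(mask > 0)
  centers_inside <- voxel_centers(lin_to_ijk(inside_lin, dm),
                                  seg$spacing, seg$origin)
  fracs <- seq_len(k) / (k + 1)
  s_planes <- s_valve + fracs * (s_bct - s_valve)
  planes <- vector("list", k)
  voxvol <- prod(seg$spacing)
  for (i in seq_len(k)) {
    ctr <- sapply(1:3, function(a) approx(cl$arc, cl$points[, a],
                                          xout = s_planes[i])$y)
    tg <- sapply(1:3, function(a) approx(cl$arc, cl$tangents[, a],
                                         xout = s_planes[i])$y)
    tg <- tg / sqrt(sum(tg^2))
    cs <- slab_voxels(centers_inside, ctr, tg, seg$spacing)
    if (!length(cs$idx)) stop("analysis plane ", i, " has an empty cross-section")
    keep <- slab_component(inside_lin[cs$idx], cs$seed_row, dm)
    pts <- cs$proj[keep, , drop = FALSE]
    area <- length(keep) * voxvol / (2 * cs$half)
    planes[[i]] <- structure(list(center = ctr, normal = tg, points = pts,
                                  area = area, s = s_planes[i]),
                             class = "analysis_plane")
  }
  structure(list(s_valve = s_valve, s_bct = s_bct, planes = planes,
                 centerline = cl, k = k),
            class = "aorta_region")
}

#' Assign wall samples to the ascending-aorta region
#'
#' A sample belongs to the region when its continuous projection onto the
#' centerline polyline falls strictly between the valve and
#' brachiocephalic-trunk arc positions (samples whose projection clamps to a
#' polyline end, e.g. on the inflow/outflow caps of a tube phantom, are
#' excluded).
#'
#' @param wall a [extract_wall_samples()] result.
#' @param region an [delimit_and_planes()] result.
#' @return logical vector of membership plus attribute `s` (arc lengths).
#' @export
region_membership <- function(wall, region) {
  pr <- project_polyline(wall$position, region$centerline)
  m <- pr$s > region$s_valve & pr$s < region$s_bct & !pr$clamped
  attr(m, "s") <- pr$s
  m
}
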