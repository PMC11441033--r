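# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

vec_norm <- function(m) {
  if (is.null(dim(m))) return(sqrt(sum(m^2)))
  sqrt(rowSums(m^2))
}

normalize_rows <- function(m, eps = 1e-12) {
  n <- vec_norm(m)
  n[n < eps] <- NA_real_
  m / n
}

#' World coordinates of voxel centers
#'
#' Voxel indices are 1-based; a voxel at index `(i,j,k)` has its center at
#' `origin + (index - 1) * spacing` (mm) and occupies the half-open cube of
#' one spacing centered there.
#' @noRd
voxel_centers <- function(idx, spacing, origin) {
  sweep(sweep(idx - 1, 2, spacing, `*`), 2, origin, `+`)
}

# points (n x 3, mm) -> fractional 0-based lattice coordinates
world_to_frac <- function(points, spacing, origin) {
  sweep(sweep(points, 2, origin, `-`), 2, spacing, `/`)
}

#' Vectorized trilinear interpolation of a 3D array
#'
#' @param arr numeric 3D array.
#' @param frac n x 3 matrix of fractional 0-based lattice coordinates.
#' @param check error on points outside the bounding box (default) or clamp.
#' @noRd
interp3 <- function(arr, frac, check = TRUE) {
  dm <- dim(arr)
  if (check) {
    bad <- frac[, 1] < 0 | frac[, 1] > dm[1] - 1 |
           frac[, 2] < 0 | frac[, 2] > dm[2] - 1 |
           frac[, 3] < 0 | frac[, 3] > dm[3] - 1
    if (any(bad)) {
      stop("interpolation point outside the grid bounding box (",
           sum(bad), " point(s))")
    }
  }
  i0 <- pmin(pmax(floor(frac), 0), rep(dm - 2L, each = nrow(frac)))
  # degenerate axes of size 1: keep i0 = 0, weight 0
  for (a in 1:3) if (dm[a] == 1L) i0[, a] <- 0
  w <- frac - i0
  w <- pmin(pmax(w, 0), 1)
  for (a in 1:3) if (dm[a] == 1L) w[, a] <- 0
  nx <- dm[1]; nxy <- dm[1] * dm[2]
  base <- 1 + i0[, 1] + i0[, 2] * nx + i0[, 3] * nxy
  sx <- ifelse(dim(arr)[1] == 1L, 0L, 1L)
  sy <- ifelse(dim(arr)[2] == 1L, 0L, nx)
  sz <- ifelse(dim(arr)[3] == 1L, 0L, nxy)
  wx <- w[, 1]; wy <- w[, 2]; wz <- w[, 3]
  c000 <- arr[base];                 c100 <- arr[base + sx]
  c010 <- arr[base + sy];            c110 <- arr[base + sx + sy]
  c001 <- arr[base + sz];            c101 <- arr[base + sx + sz]
  c011 <- arr[base + sy + sz];       c111 <- arr[base + sx + sy + sz]
  c00 <- c000 * (1 - wx) + c100 * wx
  c10 <- c010 * (1 - wx) + c110 * wx
  c01 <- c001 * (1 - wx) + c101 * wx
  c11 <- c011 * (1 - wx) + c111 * wx
  c0 <- c00 * (1 - wy) + c10 * wy
  c1 <- c01 * (1 - wy) + c11 * wy
  c0 * (1 - wz) + c1 * wz
}

# Nearest-voxel membership lookup: TRUE where the voxel nearest to the point
# is inside the mask; points off the grid are outside.
mask_lookup <- function(mask, points, spacing, origin) {
  dm <- dim(mask)
  idx <- round(world_to_frac(points, spacing, origin)) + 1
  ok <- idx[, 1] >= 1 & idx[, 1] <= dm[1] &
        idx[, 2] >= 1 & idx[, 2] <= dm[2] &
        idx[, 3] >= 1 & idx[, 3] <= dm[3]
  out <- logical(nrow(points))
  if (any(ok)) {
    lin <- idx[ok, 1] + (idx[ok, 2] - 1) * dm[1] + (idx[ok, 3] - 1) * dm[1] * dm[2]
    out[ok] <- mask[lin] > 0
  }
  out
}

# Two unit tangent vectors orthogonal to each row of unit normals n (n x 3).
tangent_basis <- function(n) {
  ref <- matrix(rep(c(1, 0, 0), each = nrow(n)), ncol = 3)
  swap <- abs(n[, 1]) > 0.9
  ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
  t1 <- cross_rows(n, ref)
  t1 <- normalize_rows(t1)
  t2 <- cross_rows(n, t1)
  list(t1 = t1, t2 = normalize_rows(t2))
}

cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Percentile by linear interpolation between order statistics
# (rank = 1 + p/100 * (n - 1); base R quantile type 7).
percentile_linear <- function(x, p) {
  unname(quantile(x, p / 100, type = 7, names = FALSE))
}

# moving average with window w (odd), ends shrink to available window
moving_average <- function(x, w = 3L) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  half <- w %/% 2L
  n <- nrow(x)
  out <- x
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i, ] <- colMeans(x[lo:hi, , drop = FALSE])
  }
  out
}

# linear-index <-> (i,j,k) helpers for a 3D grid
lin_to_ijk <- function(lin, dm) {
  lin0 <- lin - 1L
  i <- lin0 %% dm[1]
  j <- (lin0 %/% dm[1]) %% dm[2]
  k <- lin0 %/% (dm[1] * dm[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

ijk_to_lin <- function(ijk, dm) {
  ijk[, 1] + (ijk[, 2] - 1L) * dm[1] + (ijk[, 3] - 1L) * dm[1] * dm[2]
}
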