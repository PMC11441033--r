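# Wall sampling, centerline extraction, region delimitation and the
# analysis planes, checked against digitized primitives with known geometry.

test_that("a single isolated voxel yields 6 face samples pointing inward", {
  mask <- array(0L, c(5, 5, 5, 1)); mask[3, 3, 3, 1] <- 1L
  seg <- segmentation(mask, spacing = c(1, 1, 1))
  w <- extract_wall_samples(seg, 1, smooth = FALSE)
  expect_equal(nrow(w$position), 6)
  ctr <- c(2, 2, 2)  # world center of voxel (3,3,3) with origin 0
  to_center <- ctr - w$position
  to_center <- to_center / sqrt(rowSums(to_center^2))
  expect_equal(w$normal, to_center, tolerance = 1e-12)
})

test_that("an all-ones mask has no boundary faces and errors", {
  mask <- array(1L, c(4, 4, 4, 1))
  seg <- segmentation(mask, spacing = c(1, 1, 1))
  expect_error(extract_wall_samples(seg, 1), "no boundary faces")
})

test_that("cylinder wall samples sit within one voxel of the true surface", {
  cyl <- cylinder_seg(radius = 10, length = 30, spacing = 1)
  w <- extract_wall_samples(cyl$seg, 1)
  side <- abs(w$normal[, 3]) < 0.5   # exclude cap-dominated samples
  r <- sqrt((w$position[side, 1] - cyl$axis_xy[1])^2 +
            (w$position[side, 2] - cyl$axis_xy[2])^2)
  expect_true(all(r >= 9 & r <= 11))
  # smoothed side normals align with the true inward radial direction
  radial <- cbind(cyl$axis_xy[1] - w$position[side, 1],
                  cyl$axis_xy[2] - w$position[side, 2], 0)
  radial <- radial / sqrt(rowSums(radial^2))
  cosang <- rowSums(w$normal[side, ] * radial)
  expect_gt(mean(cosang), cos(15 * pi / 180))
})

test_that("straight-tube centerline tracks the axis and the landmark span", {
  cyl <- cylinder_seg(radius = 10, length = 100, spacing = 1, lm_inset = 10)
  cl <- compute_centerline(cyl$seg, 1, cyl$lm)
  off_axis <- sqrt((cl$points[, 1] - cyl$axis_xy[1])^2 +
                   (cl$points[, 2] - cyl$axis_xy[2])^2)
  expect_lt(max(off_axis), 0.5)
  expect_equal(max(cl$arc), 80, tolerance = 0.05 * 80)  # 100 - 2*10 inset
  expect_equal(sqrt(rowSums(cl$tangents^2)), rep(1, nrow(cl$tangents)),
               tolerance = 1e-9)
  # ends land within one voxel of the landmarks
  expect_lt(sqrt(sum((cl$points[1, ] - cyl$lm$valve)^2)), 1.5)
  expect_lt(sqrt(sum((cl$points[nrow(cl$points), ] - cyl$lm$bct)^2)), 1.5)
})

test_that("quarter-torus centerline arc length matches pi*R_bend/2 within 5%", {
  tq <- torus_quarter_seg(r_bend = 30, r_tube = 8, spacing = 1)
  cl <- compute_centerline(tq$seg, 1, tq$lm)
  expect_equal(max(cl$arc), tq$arc_true, tolerance = 0.05 * tq$arc_true)
})

test_that("degenerate or disconnected landmark configurations are rejected", {
  cyl <- cylinder_seg(radius = 6, length = 20, spacing = 1)
  lm_same <- landmarks(cyl$lm$valve, cyl$lm$valve)
  expect_error(compute_centerline(cyl$seg, 1, lm_same), "same voxel")
  # two disjoint blobs: no inside-mask path
  mask <- array(0L, c(12, 6, 6, 1))
  mask[2:4, 2:4, 2:4, 1] <- 1L
  mask[9:11, 2:4, 2:4, 1] <- 1L
  seg2 <- segmentation(mask, spacing = c(1, 1, 1))
  lm2 <- landmarks(c(2, 2, 2), c(9, 2, 2))
  expect_error(compute_centerline(seg2, 1, lm2), "not connected")
})

test_that("seven planes sit at interior equidistant fractions", {
  cyl <- cylinder_seg(radius = 10, length = 100, spacing = 1, lm_inset = 10)
  cl <- compute_centerline(cyl$seg, 1, cyl$lm)
  region <- delimit_and_planes(cl, cyl$lm, cyl$seg, 1, k = 7)
  s_rel <- vapply(region$planes, function(p) p$s, numeric(1)) - region$s_valve
  L <- region$s_bct - region$s_valve   # ~80 mm
  expect_equal(s_rel, (1:7) / 8 * L, tolerance = 1e-6)
  expect_equal(s_rel / L * 80, seq(10, 70, by = 10), tolerance = 0.05 * 80)
  # k = 1 gives the single mid-region plane
  r1 <- delimit_and_planes(cl, cyl$lm, cyl$seg, 1, k = 1)
  expect_equal(r1$planes[[1]]$s - r1$s_valve, L / 2, tolerance = 1e-6)
  expect_error(delimit_and_planes(cl, cyl$lm, cyl$seg, 1, k = 0), "k must")
})

test_that("plane cross-section areas match pi*R^2 within 5%", {
  cyl <- cylinder_seg(radius = 10, length = 60, spacing = 1, lm_inset = 8)
  cl <- compute_centerline(cyl$seg, 1, cyl$lm)
  region <- delimit_and_planes(cl, cyl$lm, cyl$seg, 1, k = 7)
  areas <- vapply(region$planes, function(p) p$area, numeric(1))
  expect_true(all(abs(areas - pi * 100) < 0.05 * pi * 100))
  # plane normals are unit and orthogonal to the in-plane point cloud
  for (p in region$planes) {
    expect_equal(sum(p$normal^2), 1, tolerance = 1e-9)
    rel <- sweep(p$points, 2, p$center, `-`)
    expect_lt(max(abs(rel %*% p$normal)), 1e-6)
  }
})

test_that("regional wall samples project inside the landmark arc interval", {
  cyl <- cylinder_seg(radius = 8, length = 50, spacing = 1, lm_inset = 8)
  cl <- compute_centerline(cyl$seg, 1, cyl$lm)
  region <- delimit_and_planes(cl, cyl$lm, cyl$seg, 1)
  w <- extract_wall_samples(cyl$seg, 1)
  m <- region_membership(w, region)
  s <- attr(m, "s")
  expect_true(all(s[m] >= region$s_valve & s[m] <= region$s_bct))
  # end-cap samples (axial normals near tube ends) are excluded
  caps <- abs(w$normal[, 3]) > 0.9 &
    (w$position[, 3] < cyl$zlo + 1 | w$position[, 3] > cyl$zhi - 1)
  expect_true(!any(m[caps]))
})

test_that("whole-voxel translation translates the geometry exactly", {
  mk <- function(shift) {
    n <- c(16, 16, 24)
    idx <- as.matrix(expand.grid(1:n[1], 1:n[2], 1:n[3]))
    pts <- idx - 1
    ctr <- c(7, 7, 0) + c(shift, 0)
    r2 <- (pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2
    inside <- r2 <= 25 & pts[, 3] >= 4 & pts[, 3] <= 19
    seg <- segmentation(array(as.integer(inside), c(n, 1)), rep(1, 3))
    lm <- landmarks(c(ctr[1], ctr[2], 6), c(ctr[1], ctr[2], 17))
    list(seg = seg, lm = lm, shift = c(shift, 0))
  }
  a <- mk(c(0, 0)); b <- mk(c(2, 1))
  wa <- extract_wall_samples(a$seg, 1); wb <- extract_wall_samples(b$seg, 1)
  ord_a <- order(wa$position[, 3], wa$position[, 2], wa$position[, 1])
  ord_b <- order(wb$position[, 3], wb$position[, 2], wb$position[, 1])
  expect_equal(sweep(wb$position[ord_b, ], 2, b$shift, `-`),
               wa$position[ord_a, ], tolerance = 1e-12)
  expect_equal(wb$normal[ord_b, ], wa$normal[ord_a, ], tolerance = 1e-12)
})
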