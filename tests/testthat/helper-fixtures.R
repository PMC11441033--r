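# Fixtures built in code: small phantoms, a bent-tube mask, synthetic
# velocity fields and independent statistical oracles.

`%||%` <- function(a, b) if (is.null(a)) b else a

quick_spec <- function(profile = "steady_parabolic", spacing = 1,
                       radius = 10, length = 40, n_frames = 1, ...) {
  flow_phantom_spec(tube_radius = radius, tube_length = length,
                    voxel_spacing = spacing, n_frames = n_frames,
                    profile_kind = profile, ...)
}

# Digitized quarter-torus lumen: tube of radius r_tube bent along a quarter
# circle of radius r_bend in the xy-plane, plus landmarks at the two end
# cross-section centers.
torus_quarter_seg <- function(r_bend = 30, r_tube = 8, spacing = 1) {
  pad <- 3 * spacing
  ext <- r_bend + r_tube + pad
  gx <- seq(-pad, ext, by = spacing)
  gy <- seq(-pad, ext, by = spacing)
  gz <- seq(-r_tube - pad, r_tube + pad, by = spacing)
  g <- expand.grid(x = gx, y = gy, z = gz)
  rho <- sqrt(g$x^2 + g$y^2)
  th <- atan2(g$y, g$x)
  d2 <- (rho - r_bend)^2 + g$z^2
  inside <- d2 <= r_tube^2 & th >= 0 & th <= pi / 2
  mask <- array(as.integer(inside), c(length(gx), length(gy), length(gz), 1))
  seg <- segmentation(mask, spacing = rep(spacing, 3),
                      origin = c(gx[1], gy[1], gz[1]))
  lm <- landmarks(valve = c(r_bend, 0, 0), bct = c(0, r_bend, 0))
  list(seg = seg, lm = lm, arc_true = pi * r_bend / 2)
}

# Straight digitized cylinder along z with landmarks a given arc apart.
cylinder_seg <- function(radius = 10, length = 100, spacing = 1,
                         lm_inset = 10) {
  n_xy <- ceiling(2 * radius / spacing) + 7
  n_z <- ceiling(length / spacing) + 7
  ctr <- (c(n_xy, n_xy, n_z) - 1) / 2 * spacing
  idx <- as.matrix(expand.grid(i = 1:n_xy, j = 1:n_xy, k = 1:n_z))
  pts <- sweep(idx - 1, 2, rep(spacing, 3), `*`)
  r2 <- (pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2
  zlo <- ctr[3] - length / 2; zhi <- ctr[3] + length / 2
  inside <- r2 <= radius^2 & pts[, 3] >= zlo & pts[, 3] <= zhi
  mask <- array(as.integer(inside), c(n_xy, n_xy, n_z, 1))
  seg <- segmentation(mask, spacing = rep(spacing, 3), origin = c(0, 0, 0))
  lm <- landmarks(valve = c(ctr[1], ctr[2], zlo + lm_inset),
                  bct = c(ctr[1], ctr[2], zhi - lm_inset))
  list(seg = seg, lm = lm, axis_xy = ctr[1:2], zlo = zlo, zhi = zhi)
}

# Uniform linear-shear velocity field v_x = g * (z_top - z) everywhere
# (analytic continuation outside any mask), exact under trilinear sampling.
linear_shear_field <- function(g = 50, n = c(12, 12, 12), spacing = 1,
                               z_top = NULL) {
  z_top <- z_top %||% ((n[3] - 1) * spacing)
  v <- array(0, c(n, 1, 3))
  for (k in seq_len(n[3]))
    v[, , k, 1, 1] <- g * (z_top - (k - 1) * spacing)
  velocity_field(v, spacing = rep(spacing, 3), frame_duration = 40)
}

# Independent brute-force two-sided Fisher p (point-probability method).
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  lo <- max(0, r1 + c1 - N); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, c1, N - c1, r1)
  p_obs <- dhyper(a, c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Independent quadratic-time BH step-up: largest k with p_(k) <= q k/m.
bh_oracle <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ks <- which(ps <= q * seq_len(m) / m)
  rej <- logical(m)
  if (length(ks)) rej[o[seq_len(max(ks))]] <- TRUE
  rej
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol * abs(expected))
}
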