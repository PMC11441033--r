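# WSS estimation, OSI/TAWSS reductions, flow displacement, peak-systole
# selection and the per-subject summary, against closed forms and the
# phantom oracles.

synthetic_wall <- function(position, normal) {
  structure(list(position = position, normal = normal,
                 owner = rep(NA_integer_, nrow(position)),
                 spacing = c(1, 1, 1), origin = c(0, 0, 0), frame = 1L),
            class = "wall_samples")
}

test_that("trilinear interpolation reproduces constant, linear and nodal values", {
  v <- array(0, c(6, 6, 6, 1, 3))
  v[, , , 1, 1] <- 1
  f <- velocity_field(v, spacing = c(1, 1, 1), frame_duration = 40)
  expect_equal(interpolate_velocity(f, c(2.3, 1.7, 4.2), 1),
               matrix(c(1, 0, 0), 1), tolerance = 1e-12)
  # linear field v_x = 0.2 * x is exact anywhere
  for (i in 1:6) v[i, , , 1, 1] <- 0.2 * (i - 1)
  f2 <- velocity_field(v, spacing = c(1, 1, 1), frame_duration = 40)
  expect_equal(interpolate_velocity(f2, c(3.25, 2.5, 1.1), 1)[1, 1],
               0.2 * 3.25, tolerance = 1e-12)
  expect_equal(interpolate_velocity(f2, c(4, 2, 3), 1)[1, 1], 0.8,
               tolerance = 1e-12)   # lattice node
  expect_error(interpolate_velocity(f2, c(-1, 2, 3), 1), "outside")
})

test_that("WSS fitting is exact on a linear shear and a quadratic profile", {
  g <- 0.1  # (m/s)/mm wall gradient
  f <- linear_shear_field(g = g, n = c(10, 10, 12), spacing = 1)
  z_top <- 11
  pos <- as.matrix(expand.grid(x = 3:6, y = 3:6))
  wall <- synthetic_wall(cbind(pos, z_top),
                         matrix(rep(c(0, 0, -1), each = nrow(pos)), ncol = 3))
  wss <- estimate_wss(f, wall, mu = 3.2e-3)
  expect_equal(wss$magnitude, rep(3.2e-3 * g * 1e3, nrow(pos)),
               tolerance = 1e-9)
  expect_equal(wss$tau[, 1], rep(0.32, nrow(pos)), tolerance = 1e-9)
  expect_lt(max(abs(rowSums(wss$tau * wall$normal))),
            1e-6 * max(wss$magnitude))   # tangency
  # doubling the velocity doubles every WSS vector exactly
  f2 <- f; f2$v <- f$v * 2
  wss2 <- estimate_wss(f2, wall, mu = 3.2e-3)
  expect_equal(wss2$tau, 2 * wss$tau, tolerance = 1e-12)
  # quadratic profile a*d + b*d^2 sampled at voxel centers is recovered
  a <- 0.05; b <- -0.002
  v <- array(0, c(10, 10, 12, 1, 3))
  for (k in 1:12) {
    d <- z_top - (k - 1)
    v[, , k, 1, 1] <- a * d + b * d^2
  }
  fq <- velocity_field(v, spacing = c(1, 1, 1), frame_duration = 40)
  wq <- estimate_wss(fq, wall, mu = 3.2e-3,
                     fit = list(n_points = 3, step_mm = 1))
  expect_equal(wq$magnitude, rep(3.2e-3 * a * 1e3, nrow(pos)),
               tolerance = 1e-9)
})

test_that("steady parabolic regional mean WSS lands near 2*mu*vmax/R", {
  ph <- build_phantom(quick_spec(spacing = 1, length = 40))
  hs <- subject_summary(ph$velocity, ph$seg, ph$landmarks, default_config())
  # coarse 1 mm lattice: generous discretization budget
  expect_rel(hs$mean_peak_wss, 0.64, 0.25)
  expect_equal(hs$mean_peak_wss, hs$mean_tawss, tolerance = 0.01)
  expect_lt(hs$mean_osi, 1e-6)
  expect_lt(hs$mean_fd, 0.5 / 20)  # half-pixel bound on FD
  expect_gte(hs$max_peak_wss, hs$mean_peak_wss)
  expect_gte(hs$max_osi, hs$mean_osi)
})

test_that("OSI closed forms and bounds", {
  mk <- function(series) {
    arr <- array(0, c(1, 3, length(series)))
    arr[1, 1, ] <- series
    arr
  }
  expect_equal(compute_osi(mk(rep(1, 8))), 0)
  expect_equal(compute_osi(mk(c(2, 1, 3, 2, 1, 2))), 0)  # fixed direction
  expect_equal(compute_osi(mk(c(1, 1, -1, -1))), 0.5)
  expect_equal(compute_osi(mk(c(1, 1, -0.5, -0.5))), 1 / 3,
               tolerance = 1e-12)
  expect_equal(compute_osi(mk(rep(0, 5))), 0)   # zero field convention
  set.seed(8)
  for (i in 1:25) {
    arr <- array(rnorm(7 * 3 * 11), c(7, 3, 11))
    osi <- compute_osi(arr)
    expect_true(all(osi >= 0 & osi <= 0.5))
  }
})

test_that("TAWSS is the rectangle-rule magnitude average", {
  arr <- array(0, c(1, 3, 4))
  arr[1, 2, ] <- c(1, 0, 1, 0)
  expect_equal(compute_tawss(arr), 0.5)
  arr2 <- array(0, c(1, 3, 3)); arr2[1, 1, ] <- c(3, 4, 5)
  expect_equal(compute_tawss(arr2), 4)
})

test_that("regional summary: interpolated percentile and plane maximum", {
  s <- summarize_region(1:100, "wall")
  expect_equal(s[["mean"]], 50.5)
  expect_equal(s[["max"]], 99.01)  # rank 1 + 0.99*(n-1)
  expect_equal(summarize_region(rep(3, 10), "wall"), c(mean = 3, max = 3))
  expect_equal(summarize_region(c(0.1, 0.2, 0.3), "planes"),
               c(mean = 0.2, max = 0.3))
  expect_error(summarize_region(numeric(0), "wall"), "no finite")
})

test_that("peak systole: waveform peak, steady tie-break, reversing cosine", {
  ph <- build_phantom(quick_spec("pulsatile_parabolic", n_frames = 10,
                                 waveform_params = list(peak_frame = 6)))
  geo <- aortaflow:::build_geometry(ph$seg, 1, ph$landmarks, default_config())
  expect_equal(as.integer(find_peak_systole(ph$velocity, geo$region)), 6L)
  st <- build_phantom(quick_spec(n_frames = 10))
  geo_st <- aortaflow:::build_geometry(st$seg, 1, st$landmarks, default_config())
  expect_equal(as.integer(find_peak_systole(st$velocity, geo_st$region)), 1L)
  rv <- build_phantom(quick_spec("reversing_parabolic", n_frames = 20))
  geo_rv <- aortaflow:::build_geometry(rv$seg, 1, rv$landmarks, default_config())
  expect_equal(as.integer(find_peak_systole(rv$velocity, geo_rv$region)), 1L)
})

test_that("axial/circumferential decomposition separates flow components", {
  cfg <- default_config()
  ax <- build_phantom(quick_spec(spacing = 1))
  h_ax <- subject_summary(ax$velocity, ax$seg, ax$landmarks, cfg)
  expect_lt(h_ax$circ_mean_wss_peak, 0.05 * h_ax$axial_mean_wss_peak)
  sw <- build_phantom(quick_spec("swirl_plus_axial", spacing = 0.5))
  h_sw <- subject_summary(sw$velocity, sw$seg, sw$landmarks, cfg)
  # equal wall derivatives: axial and circumferential agree within 15%
  expect_rel(h_sw$circ_mean_wss_peak, h_sw$axial_mean_wss_peak, 0.15)
  # regional mean magnitude within 15% of the analytic 0.64*sqrt(2)
  expect_rel(h_sw$mean_peak_wss, 0.64 * sqrt(2), 0.15)
})

test_that("reversing phantom reaches the OSI ceiling regionally", {
  rv <- build_phantom(quick_spec("reversing_parabolic", n_frames = 20,
                                 spacing = 1))
  hs <- subject_summary(rv$velocity, rv$seg, rv$landmarks, default_config())
  expect_gte(hs$max_osi, 0.45)
  expect_lte(hs$max_osi, 0.5)
})

test_that("flow displacement: symmetry, point jet and Gaussian-jet oracle", {
  cfg <- default_config()
  jet <- quick_spec("eccentric_jet", spacing = 1,
                    waveform_params = list(jet_offset_mm = 5,
                                           jet_width_mm = 1.5))
  ph <- build_phantom(jet)
  hs <- subject_summary(ph$velocity, ph$seg, ph$landmarks, cfg)
  expect_lt(abs(hs$mean_fd - 0.25), 0.5 / 20)  # half-pixel bound
  gauss <- quick_spec("eccentric_jet", spacing = 0.5, length = 30,
                      waveform_params = list(jet_offset_mm = 4,
                                             jet_width_mm = 3))
  ph2 <- build_phantom(gauss)
  hs2 <- subject_summary(ph2$velocity, ph2$seg, ph2$landmarks, cfg)
  expect_rel(hs2$mean_fd, phantom_fd_oracle(gauss), 0.02)
})

test_that("velocity scaling and grid-axis permutation leave summaries invariant", {
  cfg <- default_config()
  ph <- build_phantom(quick_spec(spacing = 1, n_frames = 2))
  h1 <- subject_summary(ph$velocity, ph$seg, ph$landmarks, cfg)
  v3 <- ph$velocity; v3$v <- v3$v * 3
  h3 <- subject_summary(v3, ph$seg, ph$landmarks, cfg)
  for (f in c("mean_peak_wss", "max_peak_wss", "mean_tawss", "max_tawss",
              "axial_mean_wss_peak", "circ_mean_wss_peak"))
    expect_equal(h3[[f]], 3 * h1[[f]], tolerance = 1e-12)
  for (f in c("mean_osi", "max_osi", "mean_fd", "max_fd"))
    expect_equal(h3[[f]], h1[[f]], tolerance = 1e-12)
  ph_x <- build_phantom(quick_spec(spacing = 1, n_frames = 2, axis = 1))
  hx <- subject_summary(ph_x$velocity, ph_x$seg, ph_x$landmarks, cfg)
  for (f in c("mean_peak_wss", "max_peak_wss", "mean_osi", "max_osi",
              "mean_fd", "max_fd", "axial_mean_wss_peak",
              "circ_mean_wss_peak"))
    expect_equal(hx[[f]], h1[[f]], tolerance = 1e-6)
})
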