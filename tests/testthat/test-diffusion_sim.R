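test_that("analytic profile reproduces the erf solution and its limits", {
  de <- 1.29e-9; t <- 12 * 3600
  expect_equal(analytic_profile(0, t, de, cs = 0.08), 0.08)
  expect_equal(analytic_profile(c(0, 0.002), 0, de, cs = 0.08, c0 = 0.001),
               c(0.08, 0.001))
  x <- seq(0, 0.01, by = 5e-4)
  expect_equal(analytic_profile(x, t, de, 0.08, 0),
               0.08 - 0.08 * erf_ind(x / (2 * sqrt(de * t))), tolerance = 1e-12)
  expect_equal(round(analytic_profile(0.002, t, de, 0.08, 0), 4), 0.0680)
  expect_error(analytic_profile(0.002, -1, de, 0.08), class = "invalid_config")
})

test_that("1D Crank-Nicolson matches the erf oracle at second order", {
  de <- 1.29e-9
  deep <- slab_geometry(c(0.03, 0.03, 0.04), 5e-4)  # extended depth: no far-face influence
  errs <- sapply(c(1, 2), function(ref) {
    cfg <- sim_config(de, "one_face", boundary_value = 0.08, initial_value = 0,
                      duration = 6 * 3600, time_step = 60 / ref)
    f <- solve_slab_1d(cfg, deep, dx = 2.5e-4 / ref)[[1]]
    x <- f$coords[[1]]
    ref_v <- 0.08 - 0.08 * erf_ind(x / (2 * sqrt(de * f$time)))
    sel <- x > 0 & x <= 0.006
    max(abs(f$values[sel] - ref_v[sel]) / ref_v[sel])
  })
  expect_lt(errs[1], 0.01)            # default grid within 1% for x <= 6 mm
  expect_gt(errs[1] / errs[2], 3)     # ~4x error reduction on halving
  expect_lt(errs[1] / errs[2], 6)
})

test_that("1D solver limits: frozen field, steady state, maximum principle", {
  geom <- slab_geometry()
  tiny <- sim_config(1e-14, "one_face", 0.08, 0.001, duration = 600, time_step = 60)
  f <- solve_slab_1d(tiny, geom)[[1]]
  expect_equal(f$values[1], 0.08)
  expect_lt(max(abs(f$values[-1] - 0.001)), 1e-5)

  long <- sim_config(1e-7, "one_face", 0.08, 0, duration = 24 * 3600, time_step = 60)
  fl <- solve_slab_1d(long, geom)[[1]]
  expect_equal(fl$values, rep(0.08, length(fl$values)), tolerance = 1e-6)

  mid <- sim_config(1.29e-9, "one_face", 0.08, 0, duration = 12 * 3600,
                    time_step = 60, output_times = c(3, 6, 12) * 3600)
  for (fld in solve_slab_1d(mid, geom)) {
    expect_true(all(fld$values >= 0 - 1e-12))
    expect_true(all(fld$values <= 0.08 + 1e-12))
    expect_true(all(diff(fld$values) <= 1e-12))  # monotone decay with depth
  }
})

test_that("3D all-faces field respects the slab's reflection symmetries", {
  geom <- slab_geometry(spacing = 1e-3)
  cfg <- sim_config(1.21e-9, "all_faces", boundary_value = 1350,
                    initial_value = 0, duration = 3600, time_step = 60)
  v <- solve_slab_3d(cfg, geom)[[1]]$values
  d <- dim(v)
  expect_lt(max(abs(v - v[d[1]:1, , ])), 1e-10)
  expect_lt(max(abs(v - v[, d[2]:1, ])), 1e-10)
  expect_lt(max(abs(v - v[, , d[3]:1])), 1e-10)
  expect_true(all(v >= -1e-9) && all(v <= 1350 + 1e-9))
})

test_that("3D one-face centreline matches the 1D solver", {
  geom <- slab_geometry(spacing = 5e-4)
  cfg <- sim_config(1.21e-9, "one_face", 0.08, 0, duration = 2 * 3600,
                    time_step = 60)
  f3 <- solve_slab_3d(cfg, geom)[[1]]
  f1 <- solve_slab_1d(cfg, geom, dx = 5e-4)[[1]]
  mid <- ceiling(dim(f3$values)[1:2] / 2)
  line <- f3$values[mid[1], mid[2], ]
  sel <- f1$values > 1e-4 * 0.08   # before lateral influence / above noise floor
  expect_lt(max(abs(line[sel] - f1$values[sel]) / f1$values[sel]), 0.005)
})

test_that("t = 0 output returns the initial state off-boundary", {
  geom <- slab_geometry(spacing = 1e-3)
  cfg <- sim_config(1.21e-9, "one_face", 0.08, 0.003, duration = 3600,
                    time_step = 60, output_times = c(0, 3600))
  f0 <- solve_slab_3d(cfg, geom)[[1]]
  expect_equal(f0$time, 0)
  expect_true(all(f0$values[, , 1] == 0.08))
  expect_true(all(f0$values[, , -1] == 0.003))
})

test_that("sealed slab conserves total solute", {
  geom <- slab_geometry(spacing = 1e-3)
  xs <- lapply(1:3, function(d) seq(0, geom$lengths[d], length.out = geom$n_nodes[d]))
  g <- expand.grid(x = xs[[1]], y = xs[[2]], z = xs[[3]])
  init <- array(1000 * exp(-((g$x - 0.015)^2 + (g$y - 0.015)^2 +
                             (g$z - 0.005)^2) / (2 * 0.004^2)), geom$n_nodes)
  cfg <- sim_config(5e-8, "sealed", boundary_value = 0, initial_value = 0,
                    duration = 2 * 3600, time_step = 60)
  out <- solve_slab_3d(cfg, geom, init = init)[[1]]
  tot0 <- total_solute(concentration_field(xs, init, 0, 0, 0), geom)
  tot1 <- total_solute(out, geom)
  expect_lt(abs(tot1 - tot0) / tot0, 1e-6)
})

test_that("penetration depth thresholds and caps correctly", {
  geom <- slab_geometry()
  cfg0 <- sim_config(1.21e-9, "one_face", 0.08, 0, duration = 3600,
                     time_step = 60, output_times = c(0, 3600))
  f0 <- solve_slab_1d(cfg0, geom)[[1]]
  # t = 0: only the boundary node is wetted, front depth is 0
  expect_equal(penetration_depth(f0, 0.01), 0)

  cfg <- sim_config(1.21e-9, "one_face", 0.08, 0, duration = 12 * 3600,
                    time_step = 60)
  f <- solve_slab_1d(cfg, geom)[[1]]
  expect_equal(penetration_depth(f, 0.01), 0.01)  # full 10 mm slab penetrated

  # semi-infinite front position agrees with the erfinv oracle
  deep <- slab_geometry(c(0.03, 0.03, 0.04), 5e-4)
  fd <- solve_slab_1d(cfg, deep)[[1]]
  oracle <- 2 * sqrt(1.21e-9 * 12 * 3600) * erfinv_ind(0.99)
  expect_lt(abs(penetration_depth(fd, 0.01) - oracle), 5e-4)

  uni <- concentration_field(list(seq(0, 0.01, 5e-4)), rep(0.08, 21),
                             3600, c0 = 0, cs = 0.08)
  expect_equal(penetration_depth(uni, 0.5), 0.01)
})

test_that("slice averaging is exact for uniform and linear fields", {
  x <- seq(0, 0.01, by = 2.5e-4)
  uni <- concentration_field(list(x), rep(0.05, length(x)), 3600, 0, 0.08)
  sp <- field_to_slices(uni, 0.002)
  expect_equal(sp$salt_frac, rep(0.05, 5))
  expect_equal(sp$slice_centers, c(1, 3, 5, 7, 9) / 1000)

  lin <- concentration_field(list(x), 0.08 - 6 * x, 3600, 0, 0.08)
  spl <- field_to_slices(lin, 0.002)
  expect_equal(spl$salt_frac, 0.08 - 6 * spl$slice_centers, tolerance = 1e-12)

  # erf-shaped field: slice means strictly decreasing with depth
  cfg <- sim_config(1.29e-9, "one_face", 0.08, 0, duration = 12 * 3600,
                    time_step = 60)
  fe <- solve_slab_1d(cfg, slab_geometry())[[1]]
  spe <- field_to_slices(fe, 0.002)
  expect_true(all(diff(spe$salt_frac) < 0))
  # slice means of an exact erf field equal the numerically integrated means
  t12 <- 12 * 3600
  xf <- seq(0, 0.01, by = 5e-5)
  fa <- concentration_field(list(xf),
                            analytic_profile(xf, t12, 1.29e-9, 0.08, 0),
                            t12, c0 = 0, cs = 0.08)
  spa <- field_to_slices(fa, 0.002)
  for (k in 1:5) {
    lo <- (k - 1) * 0.002; hi <- k * 0.002
    num <- integrate(function(u) analytic_profile(u, t12, 1.29e-9, 0.08, 0),
                     lo, hi)$value / 0.002
    expect_equal(spa$salt_frac[k], num, tolerance = 1e-5)
  }
})

test_that("profile error metric matches hand arithmetic", {
  ctr <- c(1, 3, 5, 7, 9) / 1000
  a <- slice_profile(24, ctr, c(0.06, 0.05, 0.04, 0.03, 0.02))
  expect_equal(profile_relative_error(a, a), 0)
  b <- a; b$salt_frac <- a$salt_frac * 1.10
  expect_equal(profile_relative_error(a, b), 100 * 0.1 / 1.1, tolerance = 1e-10)
  d <- a; d$salt_frac[3] <- a$salt_frac[3] * 1.5
  expect_equal(profile_relative_error(d, a), 10, tolerance = 1e-10)
  z <- a; z$salt_frac[1] <- 0
  expect_error(profile_relative_error(a, z), class = "invalid_profile")
  short <- slice_profile(24, ctr[1:4], a$salt_frac[1:4])
  expect_error(profile_relative_error(a, short), class = "grid_mismatch")
})

test_that("total solute integrates uniform fields and erf uptake correctly", {
  geom <- slab_geometry(spacing = 1e-3)
  xs <- lapply(1:3, function(d) seq(0, geom$lengths[d], length.out = geom$n_nodes[d]))
  uni <- concentration_field(xs, array(100, geom$n_nodes), 0, 0, 100)
  expect_equal(total_solute(uni, geom), 100 * prod(geom$lengths), tolerance = 1e-10)
  zero <- concentration_field(xs, array(0, geom$n_nodes), 0, 0, 0)
  expect_equal(total_solute(zero, geom), 0)

  # semi-infinite uptake closed form: M(t) = 2 cs sqrt(De t / pi) * area
  de <- 1.29e-9; t <- 6 * 3600
  deep <- slab_geometry(c(0.03, 0.03, 0.04), 5e-4)
  x <- seq(0, 0.04, by = 1e-4)
  f <- concentration_field(list(x), analytic_profile(x, t, de, 1350, 0), t, 0, 1350)
  closed <- 2 * 1350 * sqrt(de * t / pi) * 0.03 * 0.03
  expect_equal(total_solute(f, deep), closed, tolerance = 0.01)
})

test_that("geometry and config validation rejects bad inputs", {
  expect_error(slab_geometry(c(0.03, 0.03, 0.01), 3e-4), class = "invalid_geometry")
  expect_error(sim_config(-1, "one_face", duration = 10), class = "invalid_config")
  expect_error(sim_config(1e-9, "one_face", duration = 10, time_step = 60,
                          output_times = 100), class = "invalid_config")
  expect_error(solve_slab_3d(sim_config(1e-9, "one_face", duration = 60),
                             slab_geometry(c(0.3, 0.3, 0.3), 1e-4)),
               class = "grid_too_large")
  x <- seq(0, 0.01, by = 2.5e-4)
  f <- concentration_field(list(x), rep(0, length(x)), 0, 0, 0.08)
  expect_error(field_to_slices(f, 0.0033), class = "invalid_geometry")
})

test_that("field export round-trips through CSV and writes valid VTK", {
  tmp <- tempfile(fileext = ".csv")
  x <- seq(0, 0.01, by = 2.5e-4)
  f <- concentration_field(list(x), analytic_profile(x, 3600, 1.2e-9, 0.08, 0),
                           3600, 0, 0.08)
  write_field_csv(f, tmp)
  df <- read.csv(tmp)
  expect_equal(df$z, x)
  expect_equal(df$c, f$values)

  geom <- slab_geometry(spacing = 2e-3)
  cfg <- sim_config(1.2e-9, "all_faces", 1350, 0, duration = 600, time_step = 60)
  f3 <- solve_slab_3d(cfg, geom)[[1]]
  vtk <- tempfile(fileext = ".vtk")
  write_field_vtk(f3, vtk)
  lines <- readLines(vtk)
  expect_equal(lines[4], "DATASET STRUCTURED_POINTS")
  expect_match(lines[5], "DIMENSIONS 16 16 6")
  expect_length(lines, 10 + prod(dim(f3$values)))
})
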