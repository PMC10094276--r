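test_that("slope method inverts its generating line exactly", {
  th <- seq(2, 24, by = 2)
  # hand-derived slope: s = 5.731e-3 s^-0.5, L = 0.01 m -> De = pi (sL/2)^2
  s <- 5.731e-3
  omy <- s * sqrt(th * 3600) - 0.1
  est <- slope_method(th, omy, thickness_L = 0.01)
  expect_equal(est$de, pi * (s * 0.01 / 2)^2, tolerance = 1e-10)
  expect_equal(est$de, 2.5796e-9, tolerance = 1e-4)

  # regeneration from every printed slope-method parameter set
  for (i in seq_len(nrow(tbl_slope))) {
    omy <- slope_line(tbl_slope$de[i], tbl_slope$K[i], 0.01, th)
    est <- slope_method(th, omy, 0.01)
    expect_equal(est$de, tbl_slope$de[i], tolerance = 1e-9)
    expect_equal(est$intercept_K, tbl_slope$K[i], tolerance = 1e-9)
    expect_equal(est$r2, 1)
  }
})

test_that("slope method flags flat or decreasing driving-force series", {
  th <- seq(2, 24, by = 2)
  expect_error(slope_method(th, rep(0.5, length(th)), 0.01),
               class = "invalid_direction")
  expect_error(slope_method(th, 1 - 0.01 * sqrt(th), 0.01),
               class = "invalid_direction")
  expect_error(slope_method(c(2, 4), c(0.1, 0.2), 0.01),
               class = "insufficient_data")
})

test_that("erf-profile inversion is the identity on analytic forward profiles", {
  centers <- c(1, 3, 5, 7, 9) / 1000
  for (de in c(1.29e-9, 1.15e-9, 3e-10, 5e-9)) {
    for (t_h in c(6, 12, 24)) {
      C <- 0.08 - 0.08 * erf_ind(centers / (2 * sqrt(de * t_h * 3600)))
      prof <- slice_profile(t_h, centers, C)
      est <- erf_profile_method(prof, cs = 0.08, c0 = 0)
      expect_lt(rel_err(est$de, de), 1e-6)
      est2 <- erf_profile_method(prof, cs = 0.08, c0 = 0, aggregate = "lsq")
      expect_lt(rel_err(est2$de, de), 1e-6)
    }
  }
})

test_that("a slice at the erf(1) point gives De = x^2 / (4 t)", {
  x <- 0.004; t_h <- 12
  C <- 0.08 - 0.08 * erf_ind(1)
  prof <- slice_profile(t_h, x, C)
  est <- erf_profile_method(prof, cs = 0.08, c0 = 0)
  expect_equal(est$de, x^2 / (4 * t_h * 3600), tolerance = 1e-9)
})

test_that("saturated and untouched slices are excluded and counted", {
  centers <- c(1, 3, 5, 7, 9) / 1000
  C <- c(0.08, 0.05, 0.03, 0.01, 0)  # first saturated, last untouched
  prof <- slice_profile(12, centers, C)
  est <- erf_profile_method(prof, cs = 0.08, c0 = 0)
  expect_equal(est$n_points, 3L)
  expect_equal(est$excluded, 2L)
  expect_equal(est$n_points + est$excluded, length(centers))
  expect_error(erf_profile_method(slice_profile(12, centers, rep(0.08, 5)),
                                  cs = 0.08, c0 = 0),
               class = "estimation_failure")
})

test_that("model-implied De matches an independent recomputation", {
  # reconstruction for the 0% power row: ze = 0.0675, z0 = 0.005467,
  # L = 0.01 m, grid 2..24 h
  tgrid <- seq(2, 24, by = 2)
  z <- 0.026587 * tgrid^0.212376 + 0.005467
  fit <- fit_time_model("power", tgrid, z)
  est <- de_from_time_model(fit, equilibrium_state(0.005467, 0.0675),
                            thickness_L = 0.01, grid = tgrid)
  # independent oracle: direct regression of the composed quantity
  omy <- 1 - (z - 0.0675) / (0.005467 - 0.0675)
  cf <- coef(lm(omy ~ I(sqrt(tgrid * 3600))))
  de_oracle <- pi * (unname(cf[2]) * 0.01 / 2)^2
  expect_gt(est$de, 0)
  expect_equal(est$de, de_oracle, tolerance = 1e-6)
  expect_equal(est$method, "from_time_model")

  # a flat model must propagate the degenerate/invalid-direction errors
  flat <- fit_time_model("linear", tgrid, rep(0.04, length(tgrid)))
  expect_error(de_from_time_model(flat, equilibrium_state(0.0055, 0.0675),
                                  0.01, tgrid),
               class = "invalid_direction")
})

test_that("windowed estimates are constant for constant De and track decay", {
  th <- seq(2, 24, by = 2)
  omy <- slope_line(1.29e-9, -0.05, 0.01, th)
  w <- windowed_de(th, omy, 0.01, window = 4)
  des <- vapply(w, function(e) e$de, numeric(1))
  expect_equal(max(des) - min(des), 0, tolerance = 1e-20)
  expect_equal(des[1], 1.29e-9, tolerance = 1e-6)

  # sub-sqrt growth mimics a diffusivity that falls over curing
  omy2 <- 0.05 * th^0.4
  des2 <- vapply(windowed_de(th, omy2, 0.01, window = 4),
                 function(e) e$de, numeric(1))
  expect_true(all(diff(des2) < 0))

  # one full-length window reduces to the plain slope method
  w1 <- windowed_de(th, omy, 0.01, window = length(th))
  expect_length(w1, 1)
  expect_equal(w1[[1]]$de, slope_method(th, omy, 0.01)$de)
})
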