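test_that("jet direction is recovered from phantom fields", {
  sim <- generate_phantom(compact_phantom_spec())
  d <- estimate_jet_direction(sim$dataset, c(0, 0, 0), 5)
  ang <- acos(sum(d * c(0, 0, 1))) * 180 / pi
  expect_lt(ang, 3)

  # an oblique static jet
  dir <- c(cos(1.1), 0, sin(1.1))
  sim2 <- generate_phantom(compact_phantom_spec(direction = dir))
  d2 <- estimate_jet_direction(sim2$dataset, c(0, 0, 0), 5)
  expect_lt(acos(sum(d2 * dir)) * 180 / pi, 3)

  # a zero field has no jet
  zero <- field_dataset(function(W) matrix(0, nrow(W), 3))
  expect_error(estimate_jet_direction(zero, c(0, 0, 0), 1), "no jet")
  expect_error(estimate_jet_direction(zero, c(1e5, 0, 0), 1), "sphere")
})

test_that("both jets of a two-jet phantom are recovered within 3 degrees", {
  spec <- two_jet_phantom_spec(seed = 6, noise_sd = 0)
  sim <- generate_phantom(spec)
  p <- 5
  truth1 <- sim$truth$jets[[1]]$directions[p, ]
  d1 <- estimate_jet_direction(sim$dataset, spec$jets[[1]]$orifice_center, p)
  expect_lt(acos(min(1, sum(d1 * truth1))) * 180 / pi, 3)
  truth2 <- sim$truth$jets[[2]]$directions[p, ]
  d2 <- estimate_jet_direction(sim$dataset, spec$jets[[2]]$orifice_center, p)
  expect_lt(acos(min(1, sum(d2 * truth2))) * 180 / pi, 3)
})

test_that("tracked planes follow the jet with the requested offset", {
  ann <- plane(origin = c(0, 0, 0), normal = c(0, 0, 1))
  dirs <- matrix(c(0, 0, 1), 3, 3, byrow = TRUE)
  ser <- build_tracked_planes(ann, dirs, 1:3, c(0, 93), offset_mm = 15)
  expect_s3_class(ser, "tracked_plane_series")
  for (pl in ser$planes) {
    expect_equal(pl$origin, c(0, 0, 15))
    expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-12)
  }
  # a 5 mm offset is outside the clinical 10-20 mm range: warn, still build
  expect_warning(ser5 <- build_tracked_planes(ann, dirs, 1:3, c(0, 93),
                                              offset_mm = 5), "10-20")
  expect_equal(ser5$planes[[1]]$origin, c(0, 0, 5))
  expect_error(build_tracked_planes(ann, dirs[1:2, ], 1:3, c(0, 93)),
               "per phase")
  expect_error(tracked_plane_series(list(), c(1, 3), c(0, 50)), "one plane")
})

test_that("per-phase plane normals track a programmed angle sweep", {
  spec <- default_phantom_spec(seed = 5, noise_sd = 0)
  sim <- generate_phantom(spec)
  sm <- smooth_flow_dataset(sim$dataset, 1)
  ser <- lavvflow:::track_jet(sm, c(0, 0, 0), 1:10, c(0, 300), 15, "jet")
  for (i in seq(1, 10, by = 3)) {
    truth <- sim$truth$jets[[1]]$directions[i, ]
    got <- ser$planes[[i]]$normal
    expect_lt(acos(min(1, sum(truth * got))) * 180 / pi, 3)
  }
})

test_that("background correction removes a uniform offset", {
  ds <- field_dataset(function(W) cbind(0 * W[, 1], 0 * W[, 1],
                                        rep(5, nrow(W))))
  pl <- plane(origin = c(0, 0, 0), normal = c(0, 0, 1), rows = 20, cols = 20)
  m <- reformat_plane(ds, pl, 1)
  tissue <- cbind(c(5, 9, 9, 5), c(5, 5, 9, 9))
  mc <- background_correct(m, tissue)
  expect_equal(attr(mc, "background_cm_s"), 5, tolerance = 1e-9)
  expect_equal(max(abs(mc$through_plane)), 0, tolerance = 1e-9)

  # zero-velocity tissue leaves the map unchanged
  m0 <- m; m0$through_plane[1:10, ] <- 0
  mc0 <- background_correct(m0, cbind(c(-9, -5, -5, -9), c(-9, -9, -5, -5)))
  expect_equal(mc0$through_plane, m0$through_plane)
  expect_error(background_correct(m, cbind(c(50, 51, 51), c(50, 50, 51))),
               "no pixel centers")
})

test_that("flow_rate converts velocity times area to mL/s", {
  ds <- field_dataset(function(W) cbind(0 * W[, 1], 0 * W[, 1],
                                        rep(50, nrow(W))))
  pl <- plane(origin = c(0, 0, 0), normal = c(0, 0, 1), rows = 30, cols = 30)
  m <- reformat_plane(ds, pl, 1)
  # a 20 x 20 mm square ROI = 4 cm^2 at 50 cm/s -> 200 mL/s
  roi <- cbind(c(-9.5, 10.4, 10.4, -9.5), c(-9.5, -9.5, 10.4, 10.4))
  expect_equal(as.numeric(flow_rate(m, roi)), 200, tolerance = 1e-9)
  m$through_plane[] <- 0
  expect_equal(as.numeric(flow_rate(m, roi)), 0)
})

test_that("integrate_volume applies the trapezoidal rule with unit care", {
  # constant 100 mL/s over 300 ms -> 30 mL
  expect_equal(integrate_volume(rep(100, 11), seq(0, 300, by = 30)), 30)
  # symmetric triangle peaking at 100 over 300 ms -> area 15 mL
  tri <- c(seq(0, 100, length.out = 6), seq(80, 0, length.out = 5))
  expect_equal(integrate_volume(tri, seq(0, 300, by = 30)), 15)
  # half-sine on 10 intervals vs the closed form 2/pi * peak * duration
  tt <- seq(0, 300, length.out = 11)
  hs <- 100 * sin(pi * tt / 300)
  expect_lt(abs(integrate_volume(hs, tt) - 2 / pi * 100 * 0.3) /
            (2 / pi * 100 * 0.3), 0.01)
  expect_error(integrate_volume(1:3, 1:4), "mismatch")
  expect_error(integrate_volume(1:3, c(1, 3, 2)), "increasing")
})

test_that("direction trajectories are denoised without bending clean ones", {
  tt <- seq(15.5, 294.5, by = 31)
  th <- seq(50, 86, length.out = 10) * pi / 180
  clean <- cbind(cos(th), 0, sin(th))
  ref <- refine_direction_trajectory(clean, tt)
  for (i in 1:10) {
    expect_lt(acos(min(1, sum(ref[i, ] * clean[i, ]))) * 180 / pi, 0.5)
  }
  set.seed(2)
  noisy <- clean + matrix(rnorm(30, sd = 0.05), 10, 3)
  noisy <- t(apply(noisy, 1, function(v) v / sqrt(sum(v^2))))
  ref2 <- refine_direction_trajectory(noisy, tt)
  err_raw <- sapply(1:10, function(i)
    acos(min(1, sum(noisy[i, ] * clean[i, ]))))
  err_ref <- sapply(1:10, function(i)
    acos(min(1, sum(ref2[i, ] * clean[i, ]))))
  expect_lt(mean(err_ref), mean(err_raw))
})

test_that("quantify_lavv derives volumes with exact identities", {
  spec <- default_phantom_spec(seed = 8, noise_sd = 0)
  rep <- run_pipeline(pipeline_config(seed = 8, phantom = spec))
  fl <- rep$flow
  expect_identical(fl$total_regurgitant, sum(fl$regurgitant_volumes))
  expect_identical(fl$effective_forward, fl$forward_volume - fl$total_regurgitant)
  expect_identical(fl$regurgitant_fraction,
                   fl$total_regurgitant / fl$forward_volume * 100)
  expect_identical(fl$internal_validation_diff,
                   fl$effective_forward - fl$aortic_volume)
  expect_true(all(c("phase", "time_ms", "series_label", "rate_ml_s") %in%
                  names(fl$per_phase)))
  # regurgitant 11 of forward 78 -> fraction ~14%, the clinical magnitude
  expect_lt(abs(fl$regurgitant_fraction - 14.1), 1.5)
})

test_that("a zero-regurgitation phantom yields fraction 0", {
  spec <- default_phantom_spec(seed = 12, regurgitant_volume = 0, noise_sd = 0)
  spec$jets <- list()
  rep <- run_pipeline(pipeline_config(seed = 12, phantom = spec))
  expect_identical(rep$flow$total_regurgitant, 0)
  expect_identical(rep$flow$regurgitant_fraction, 0)
  expect_identical(rep$flow$effective_forward, rep$flow$forward_volume)
  expect_length(rep$jets, 0)
})
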