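test_that("plane construction enforces orthonormal right-handed axes", {
  p <- plane(origin = c(0, 0, 0), normal = c(0, 0, 1))
  expect_equal(sum(p$u * p$v), 0, tolerance = 1e-12)
  expect_equal(p$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_error(plane(c(0, 0, 0), u = c(1, 0, 0), v = c(1, 1, 0) / sqrt(2)),
               "orthogonal")
  expect_error(plane(c(0, 0, 0), u = c(2, 0, 0), v = c(0, 1, 0)), "unit")
  expect_error(plane(c(0, 0, 0)), "normal")
})

test_that("MPR stacks are parallel, evenly spaced and centered", {
  ref <- plane(origin = c(1, 2, 3), normal = c(0, 1, 0))
  expect_error(make_mpr_stack(ref, 0), "n_slices")
  single <- make_mpr_stack(ref, 1, 3)
  expect_equal(single[[1]]$origin, ref$origin)

  st <- make_mpr_stack(ref, 5, 3)
  origins <- t(sapply(st, `[[`, "origin"))
  d <- diff(origins)
  expect_equal(d, matrix(rep(3 * ref$normal, 4), 4, byrow = TRUE),
               tolerance = 1e-12)
  for (a in st) for (b in st) {
    expect_equal(sum(a$normal * b$normal), 1, tolerance = 1e-12)
  }
})

test_that("reformatting a uniform field is exact and orientation-free", {
  V <- c(10, -4, 7)
  ds <- field_dataset(function(W) matrix(V, nrow(W), 3, byrow = TRUE))
  for (n in list(c(0, 0, 1), c(1, 1, 1) / sqrt(3), c(0.6, 0, 0.8))) {
    pl <- plane(origin = c(0, 0, 0), normal = n, rows = 8, cols = 8)
    m <- reformat_plane(ds, pl, 1)
    expect_equal(max(abs(sweep(matrix(m$velocity, ncol = 3), 2, V))), 0,
                 tolerance = 1e-9)
    expect_equal(max(abs(m$through_plane - sum(V * pl$normal))), 0,
                 tolerance = 1e-9)
  }
})

test_that("an axis-aligned plane on a voxel sheet returns stored values", {
  set.seed(11)
  vel <- array(rnorm(9 * 9 * 9 * 3), dim = c(9, 9, 9, 3, 1))
  ds <- flow_dataset(vel, c(2, 2, 2), 10, 900, 150)
  # sheet k=5 (1-based), i.e. voxel z index 4 (0-based): world z of that sheet
  z <- voxel_to_world_test(ds, c(4, 4, 4))[3]
  pl <- plane(origin = c(0, 0, z), u = c(1, 0, 0), v = c(0, 1, 0),
              rows = 5, cols = 5, pixel_spacing = 2)
  m <- reformat_plane(ds, pl, 1)
  # pixel grid coincides with voxel centers (odd raster, 2 mm spacing)
  expect_equal(m$through_plane, vel[3:7, 3:7, 5, 3, 1], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a 45-degree plane through an axial field projects s/sqrt(2)", {
  s <- 60
  ds <- field_dataset(function(W) cbind(0 * W[, 1], 0 * W[, 1],
                                        rep(s, nrow(W))))
  n <- c(0, 1, 1) / sqrt(2)
  pl <- plane(origin = c(0, 0, 0), normal = n, rows = 6, cols = 6)
  m <- reformat_plane(ds, pl, 1)
  expect_equal(max(abs(m$through_plane - s / sqrt(2))), 0, tolerance = 1e-9)
})

test_that("through-plane maps are invariant under in-plane axis rotation", {
  sim <- generate_phantom(compact_phantom_spec())
  n <- c(0, 0, 1)
  p1 <- plane(origin = c(0, 0, 10), normal = n, rows = 20, cols = 20)
  th <- 0.7
  u2 <- cos(th) * p1$u + sin(th) * p1$v
  v2 <- -sin(th) * p1$u + cos(th) * p1$v
  p2 <- plane(origin = c(0, 0, 10), u = u2, v = v2, rows = 20, cols = 20)
  m1 <- reformat_plane(sim$dataset, p1, 5)
  m2 <- reformat_plane(sim$dataset, p2, 5)
  roi <- circle_polygon(12)
  # same physical disc, rasterized on rotated pixel grids
  expect_lt(abs(through_plane_profile(m1, roi)$mean_velocity -
                through_plane_profile(m2, roi)$mean_velocity), 0.05)
})

test_that("through_plane_profile means and areas follow the polygon", {
  ds <- field_dataset(function(W) cbind(0 * W[, 1], 0 * W[, 1],
                                        rep(8, nrow(W))))
  pl <- plane(origin = c(0, 0, 0), normal = c(0, 0, 1), rows = 20, cols = 20)
  m <- reformat_plane(ds, pl, 1)
  pr <- through_plane_profile(m, circle_polygon(6))
  expect_equal(pr$mean_velocity, 8, tolerance = 1e-9)
  expect_equal(pr$area, pr$n_pixels * 1)

  # two-valued map split by a half-plane ROI covering equal pixel counts
  m$through_plane[, 1:10] <- 0
  roi <- cbind(c(-9.5, 9.5, 9.5, -9.5), c(-4.5, -4.5, 5.4, 5.4))
  pr2 <- through_plane_profile(m, roi)
  expect_equal(pr2$mean_velocity, 4, tolerance = 1e-9)
  expect_error(through_plane_profile(m, cbind(c(100, 101, 101),
                                              c(100, 100, 101))),
               "no pixel centers")
})

test_that("polygon pixel membership matches the even-odd oracle", {
  ds <- field_dataset(function(W) matrix(1, nrow(W), 3))
  pl <- plane(origin = c(0, 0, 0), normal = c(0, 0, 1), rows = 16, cols = 16)
  m <- reformat_plane(ds, pl, 1)
  set.seed(21)
  for (rep in 1:3) {
    th <- sort(runif(7, 0, 2 * pi))
    r <- runif(7, 2, 7.3)
    poly <- cbind(r * cos(th), r * sin(th))
    got <- lavvflow:::roi_mask(m, poly)
    off <- lavvflow:::plane_pixel_offsets(pl)
    g <- expand.grid(du = off$u, dv = off$v)
    want <- matrix(mapply(oracle_point_in_polygon, g$du, g$dv,
                          MoreArgs = list(poly = poly)), 16, 16)
    expect_identical(unname(got), unname(want))
  }
})

test_that("flux through parallel planes cutting the same jet agrees", {
  dvec <- c(0.6, 0, 0.8)
  sim <- generate_phantom(compact_phantom_spec(target_volume = 8,
                                               direction = dvec))
  f <- sapply(c(8, 16.5), function(s) {
    m <- reformat_plane(sim$dataset, plane(origin = s * dvec, normal = dvec), 5)
    as.numeric(flow_rate(m, default_jet_roi(m)))
  })
  expect_lt(abs(f[1] - f[2]) / f[1], 0.02)
})

test_that("planes serialize to JSON and back", {
  pls <- make_mpr_stack(plane(origin = c(1, 2, 3), normal = c(0, 1, 0)), 3, 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_planes(pls, path)
  back <- read_planes(path)
  expect_equal(length(back), 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$origin, pls[[i]]$origin, tolerance = 1e-12)
    expect_equal(back[[i]]$normal, pls[[i]]$normal, tolerance = 1e-12)
  }
})
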