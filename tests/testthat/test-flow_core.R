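test_that("flow_dataset validates its invariants", {
  vel <- array(0, dim = c(4, 4, 4, 3, 2))
  expect_s3_class(flow_dataset(vel, c(2, 2, 2), c(10, 40), 900, 150),
                  "flow_dataset")
  expect_error(flow_dataset(vel, c(2, -2, 2), c(10, 40), 900, 150), "positive")
  expect_error(flow_dataset(vel, c(2, 2, 2), c(40, 10), 900, 150), "increasing")
  expect_error(flow_dataset(vel, c(2, 2, 2), c(10, 950), 900, 150),
               "rr_interval")
  expect_error(flow_dataset(vel, c(2, 2, 2), c(10, 40), 900, -1), "venc")
  expect_error(flow_dataset(vel, c(2, 2, 2), c(10, 40, 70), 900, 150),
               "phase_times")
  # a wrapped dataset must store values inside [-venc, venc)
  vel[1] <- 200
  expect_error(flow_dataset(vel, c(2, 2, 2), c(10, 40), 900, 150,
                            wrapped = TRUE), "wrapped")
})

test_that("write/load round-trip preserves values and metadata exactly", {
  set.seed(42)
  vel <- array(rnorm(5 * 6 * 4 * 3 * 3), dim = c(5, 6, 4, 3, 3))
  ds <- flow_dataset(vel, spacing = c(2.3, 2.3, 3.0),
                     phase_times = c(15.5, 46.5, 77.5), rr_interval = 930,
                     venc = 150)
  dir <- withr::local_tempdir()
  write_flow_dataset(ds, dir)
  ds2 <- load_flow_dataset(dir)
  expect_identical(ds2$velocities, ds$velocities)
  expect_identical(ds2$phase_times, ds$phase_times)
  expect_identical(ds2$venc, ds$venc)
  expect_identical(ds2$rr_interval, ds$rr_interval)
  expect_equal(ds2$affine, ds$affine, tolerance = 1e-12)
  expect_false(ds2$wrapped)

  # writing the same dataset twice yields byte-identical sidecars
  dir2 <- withr::local_tempdir()
  write_flow_dataset(ds, dir2)
  expect_identical(readBin(file.path(dir, "flow.json"), "raw", 1e6),
                   readBin(file.path(dir2, "flow.json"), "raw", 1e6))
})

test_that("loading rejects missing sidecar keys and mismatched shapes", {
  vel <- array(0, dim = c(4, 4, 4, 3, 2))
  ds <- flow_dataset(vel, c(2, 2, 2), c(10, 40), 900, 150)
  dir <- withr::local_tempdir()
  write_flow_dataset(ds, dir)

  sc <- jsonlite::read_json(file.path(dir, "flow.json"))
  sc$venc_cm_s <- NULL
  jsonlite::write_json(sc, file.path(dir, "flow.json"), auto_unbox = TRUE)
  expect_error(load_flow_dataset(dir), "venc_cm_s")

  write_flow_dataset(ds, dir)  # restore
  bad <- RNifti::asNifti(array(0, dim = c(3, 4, 4, 2)))
  RNifti::writeNifti(bad, file.path(dir, "vx.nii.gz"))
  expect_error(load_flow_dataset(dir), "congruent")

  expect_error(load_flow_dataset(withr::local_tempdir()), "missing file")
})

test_that("default phantom writes and loads with 30 phases and venc 150", {
  sim <- generate_phantom(compact_phantom_spec())
  dir <- withr::local_tempdir()
  write_flow_dataset(sim$dataset, dir)
  sc <- jsonlite::read_json(file.path(dir, "flow.json"), simplifyVector = TRUE)
  expect_equal(sc$venc_cm_s, 150)
  ds <- load_flow_dataset(dir)
  expect_identical(dim(ds$velocities)[5], 30L)
})

test_that("sample_velocity interpolates trilinearly", {
  set.seed(7)
  vel <- array(rnorm(6 * 6 * 6 * 3), dim = c(6, 6, 6, 3, 1))
  ds <- flow_dataset(vel, c(2, 2, 2), 10, 900, 150)

  # a voxel center returns that voxel's stored vector
  p <- voxel_to_world_test(ds, c(2, 3, 1))
  expect_equal(as.numeric(sample_velocity(ds, p, 1)), vel[3, 4, 2, , 1])

  # midpoint between two voxels along one axis is their mean
  pmid <- voxel_to_world_test(ds, c(2.5, 3, 1))
  expect_equal(as.numeric(sample_velocity(ds, pmid, 1)),
               (vel[3, 4, 2, , 1] + vel[4, 4, 2, , 1]) / 2)

  # 100 random interior points against the brute-force oracle
  set.seed(1)
  vox <- cbind(runif(100, 0, 5), runif(100, 0, 5), runif(100, 0, 5))
  pts <- t(apply(vox, 1, function(v) voxel_to_world_test(ds, v)))
  got <- sample_velocity(ds, pts, 1)
  for (cc in 1:3) {
    want <- apply(vox, 1, function(v) oracle_trilinear(vel[, , , cc, 1],
                                                       v[1], v[2], v[3]))
    expect_lt(max(abs(got[, cc] - want)), 1e-9)
  }
})

test_that("out-of-grid samples return zero with a flag; bad input errors", {
  vel <- array(1, dim = c(4, 4, 4, 3, 1))
  ds <- flow_dataset(vel, c(2, 2, 2), 10, 900, 150)
  v <- sample_velocity(ds, c(100, 0, 0), 1)
  expect_equal(as.numeric(v), c(0, 0, 0))
  expect_true(attr(v, "out_of_bounds"))
  expect_error(sample_velocity(ds, c(NA, 0, 0), 1), "non-finite")
  expect_error(sample_velocity(ds, c(0, 0, 0), 5), "phase")
})

test_that("box smoothing preserves a constant field and reduces noise", {
  fun <- function(W) cbind(rep(3, nrow(W)), rep(-2, nrow(W)), rep(5, nrow(W)))
  ds <- field_dataset(fun, dim = c(10, 10, 10))
  sm <- smooth_flow_dataset(ds, 1)
  expect_equal(sm$velocities, ds$velocities, tolerance = 1e-12)

  set.seed(3)
  noisy <- ds
  noisy$velocities <- noisy$velocities +
    array(rnorm(length(noisy$velocities)), dim = dim(noisy$velocities))
  smn <- smooth_flow_dataset(noisy, 1)
  inner <- smn$velocities[3:8, 3:8, 3:8, 1, 1] - 3
  expect_lt(sd(inner), 0.5)  # ~1/sqrt(27) of unit noise, with margin
})
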