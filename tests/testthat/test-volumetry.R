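square_contour <- function(side_mm, cx = 0, cy = 0) {
  h <- side_mm / 2
  cbind(c(cx - h, cx + h, cx + h, cx - h), c(cy - h, cy - h, cy + h, cy + h))
}

test_that("Simpson summation multiplies traced areas by slice thickness", {
  # ten slices of 10 cm^2 at 8 mm -> 80 mL
  sq <- square_contour(sqrt(1000))  # 1000 mm^2 = 10 cm^2
  st <- contour_stack(rep(list(sq), 10), 8, "ED")
  expect_equal(simpson_volume(st), 80, tolerance = 1e-9)
  # one 40 x 40 mm square at 10 mm -> 16 mL
  st1 <- contour_stack(list(square_contour(40)), 10, "ES")
  expect_equal(simpson_volume(st1), 16, tolerance = 1e-12)
})

test_that("a sliced sphere recovers the analytic volume within 2%", {
  r <- 30; dz <- 3
  zc <- seq(-r + dz / 2, r - dz / 2, by = dz)
  contours <- lapply(zc, function(z) circle_polygon(sqrt(r^2 - z^2), n = 180))
  st <- contour_stack(contours, dz, "ED")
  expect_lt(abs(simpson_volume(st) - 4 / 3 * pi * r^3 / 1000) /
            (4 / 3 * pi * r^3 / 1000), 0.02)
})

test_that("simpson_volume is additive and rigid-motion invariant", {
  sq <- square_contour(25)
  st_all <- contour_stack(rep(list(sq), 6), 8, "ED")
  st_a <- contour_stack(rep(list(sq), 2), 8, "ED")
  st_b <- contour_stack(rep(list(sq), 4), 8, "ED")
  expect_equal(simpson_volume(st_all),
               simpson_volume(st_a) + simpson_volume(st_b), tolerance = 1e-12)
  th <- 0.63
  rot <- cbind(cos(th) * sq[, 1] - sin(th) * sq[, 2] + 12,
               sin(th) * sq[, 1] + cos(th) * sq[, 2] - 7)
  expect_equal(polygon_area(rot), polygon_area(sq), tolerance = 1e-9)
})

test_that("self-intersecting contours are rejected", {
  bow <- cbind(c(0, 10, 0, 10), c(0, 10, 10, 0))
  expect_error(contour_stack(list(bow), 8, "ED"), "self-intersecting")
  expect_error(contour_stack(list(square_contour(10)), 0, "ED"), "positive")
})

test_that("ejection fraction follows its defining formula", {
  expect_equal(ejection_fraction(100, 45), 0.55)
  expect_equal(ejection_fraction(100, 100), 0)
  expect_equal(ejection_fraction(120, 54), 0.55)
  expect_error(ejection_fraction(0, 10), "positive")
})

test_that("biplane area-length volume uses the 8/(3 pi) constant", {
  # hand evaluation: 8/(3*pi) * 20 * 18 / 5 = 0.8488... * 72
  expect_equal(la_biplane_volume(20, 18, 5), 8 / (3 * pi) * 20 * 18 / 5,
               tolerance = 1e-12)
  expect_equal(round(la_biplane_volume(20, 18, 5), 1), 61.1)
  # bilinearity: doubling both areas quadruples the volume
  expect_equal(la_biplane_volume(40, 36, 5), 4 * la_biplane_volume(20, 18, 5))
  # symmetric form
  expect_equal(la_biplane_volume(15, 15, 6), 8 / (3 * pi) * 15^2 / 6)
  expect_error(la_biplane_volume(-1, 2, 3), "positive")
})

test_that("Du Bois BSA matches its closed form and exponent laws", {
  expect_equal(bsa_du_bois(70, 180), 0.007184 * 70^0.425 * 180^0.725,
               tolerance = 1e-12)
  expect_equal(round(bsa_du_bois(70, 180), 3), 1.886)
  expect_equal(bsa_du_bois(140, 180) / bsa_du_bois(70, 180), 2^0.425,
               tolerance = 1e-12)
  expect_lt(bsa_du_bois(1e-6, 180), 1e-3)
  expect_error(bsa_du_bois(0, 180), "positive")
})

test_that("indirect regurgitant volume is stroke volume minus aortic flow", {
  expect_equal(indirect_regurgitant_volume(150, 70, 65), 15)
  expect_equal(indirect_regurgitant_volume(150, 70, 80), 0)
  expect_warning(v <- indirect_regurgitant_volume(150, 70, 90), "negative")
  expect_equal(v, -10)
  expect_error(indirect_regurgitant_volume(60, 70, 10), "LVEDV")
})

test_that("volumetry_result indexes by BSA and is internally consistent", {
  r <- volumetry_result(lvedv = 150, lvesv = 70, lav = 60, weight_kg = 70,
                        height_cm = 180, aortic_volume = 65)
  expect_equal(r$stroke_volume, 80)
  expect_equal(r$ef, 80 / 150)
  expect_equal(r$lvedv_bsa, 150 / bsa_du_bois(70, 180))
  expect_equal(r$indirect_regurgitant_volume, 15)
})

test_that("indirect and direct regurgitant volumes agree on the phantom", {
  spec <- default_phantom_spec(seed = 16, noise_sd = 0)
  rep <- run_pipeline(pipeline_config(seed = 16, phantom = spec))
  # the phantom's ventricle is declared through its flow balance: stroke
  # volume = forward inflow (steady state), aortic flow as measured
  indirect <- indirect_regurgitant_volume(rep$flow$forward_volume + 70, 70,
                                          rep$flow$aortic_volume)
  expect_lt(abs(indirect - rep$flow$total_regurgitant) /
            rep$flow$total_regurgitant, 0.10)
})

test_that("contour stacks round-trip through CSV + JSON header", {
  sq <- square_contour(30)
  tab <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(slice_index = i, x_mm = sq[, 1], y_mm = sq[, 2])
  }))
  csv <- withr::local_tempfile(fileext = ".csv")
  hdr <- withr::local_tempfile(fileext = ".json")
  utils::write.csv(tab, csv, row.names = FALSE)
  jsonlite::write_json(list(slice_thickness_mm = 8, phase = "ED"), hdr,
                       auto_unbox = TRUE)
  st <- read_contour_stack(csv, hdr)
  expect_equal(simpson_volume(st), 3 * 900 * 8 / 1000)
})
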