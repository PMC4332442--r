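test_that("streamlines are straight in uniform fields with fixed spacing", {
  dirv <- c(1, 2, 2) / 3
  ds <- field_dataset(function(W) matrix(20 * dirv, nrow(W), 3, byrow = TRUE),
                      dim = c(21, 21, 21))
  sl <- trace_streamline(ds, c(-10, -10, -10), 1, step_mm = 0.5)
  seg <- diff(unclass(sl))
  expect_equal(max(abs(sqrt(rowSums(seg^2)) - 0.5)), 0, tolerance = 1e-9)
  tang <- seg / sqrt(rowSums(seg^2))
  expect_lt(max(abs(sweep(tang, 2, dirv))), 1e-9)
  expect_equal(attr(sl, "termination"), "out_of_bounds")

  # a zero-velocity seed gives a single-point streamline
  zero <- field_dataset(function(W) matrix(0, nrow(W), 3))
  sl0 <- trace_streamline(zero, c(0, 0, 0), 1)
  expect_identical(nrow(sl0), 1L)
  expect_equal(attr(sl0, "termination"), "speed")
})

test_that("streamlines of a rigid rotation stay on the seed's circle", {
  omega <- 0.8
  ds <- field_dataset(function(W) cbind(-omega * W[, 2], omega * W[, 1],
                                        0 * W[, 3]),
                      dim = c(25, 25, 9), spacing = c(1.5, 1.5, 2))
  r0 <- 8
  sl <- trace_streamline(ds, c(r0, 0, 0), 1, step_mm = 0.5, max_steps = 120)
  radii <- sqrt(sl[, 1]^2 + sl[, 2]^2)
  expect_lt(max(abs(radii - r0)) / r0, 0.001)
})

test_that("streamline endpoints converge as the step is refined", {
  sim <- generate_phantom(compact_phantom_spec(direction = c(0.6, 0, 0.8)))
  seed <- c(2, 0, 3)
  end <- lapply(c(1, 0.5), function(st) {
    sl <- trace_streamline(sim$dataset, seed, 5, step_mm = st, max_steps = 16 / st)
    sl[nrow(sl), ]
  })
  expect_lt(sqrt(sum((end[[1]] - end[[2]])^2)), 0.05)
})

test_that("view projection is idempotent and flags degeneracy", {
  vp <- phantom_view_plane("2ch")
  d <- c(1, 0, 0)
  expect_equal(project_to_view(d, vp), c(1, 0))
  expect_error(project_to_view(c(0, 1, 0), vp), "degenerate")
  set.seed(5)
  for (i in 1:10) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    if (abs(d[2]) > 0.99) next
    p <- project_to_view(d, vp)
    re <- p[1] * vp$u + p[2] * vp$v
    expect_equal(project_to_view(re, vp), p, tolerance = 1e-9)
  }
})

test_that("jet angles follow the perpendicular-reads-90 convention", {
  vp <- phantom_view_plane("2ch")
  line <- c(1, 0, 0)
  expect_equal(jet_angle(c(0, 0, 1), line, vp), 90)
  expect_equal(jet_angle(c(1, 0, 0), line, vp), 0)
  # angles beyond 90 are not folded
  d <- c(cos(2.0), 0, sin(2.0))
  expect_equal(jet_angle(d, line, vp), 2.0 * 180 / pi, tolerance = 1e-9)
})

test_that("angle_dynamics summarizes min, max and difference", {
  d <- angle_dynamics(c(50, 60, 86))
  expect_equal(c(d$min, d$max, d$difference), c(50, 86, 36))
  d1 <- angle_dynamics(75)
  expect_equal(d1$difference, 0)
  expect_error(angle_dynamics(numeric(0)), "empty")
})

test_that("circularity is 1 for discs and b/a for ellipses", {
  mk_map <- function(fun) {
    ds <- field_dataset(function(W) cbind(0 * W[, 1], 0 * W[, 1], fun(W)),
                        dim = c(41, 41, 7), spacing = c(1.5, 1.5, 2))
    pl <- plane(origin = c(0, 0, 0), normal = c(0, 0, 1), rows = 56, cols = 56)
    reformat_plane(ds, pl, 1)
  }
  disc <- mk_map(function(W) 50 * (W[, 1]^2 + W[, 2]^2 <= 14^2))
  ci_d <- circularity_index(disc)
  expect_lt(abs(ci_d - 1.00), 0.05)

  ell <- mk_map(function(W) 50 * ((W[, 1] / 20)^2 + (W[, 2] / 10)^2 <= 1))
  ci_e <- circularity_index(ell)
  expect_lt(abs(ci_e - 0.50), 0.05)

  zero <- mk_map(function(W) 0 * W[, 1])
  expect_error(circularity_index(zero), "empty segmentation")
})

test_that("circularity is invariant under 90-degree rotation and rescaling", {
  mk_map <- function(a, b, spacing) {
    ds <- field_dataset(function(W) cbind(0 * W[, 1], 0 * W[, 1],
                                          50 * ((W[, 1] / a)^2 +
                                                (W[, 2] / b)^2 <= 1)),
                        dim = c(41, 41, 7), spacing = c(1.5, 1.5, 2))
    pl <- plane(origin = c(0, 0, 0), normal = c(0, 0, 1), rows = 56,
                cols = 56, pixel_spacing = spacing)
    reformat_plane(ds, pl, 1)
  }
  ci <- circularity_index(mk_map(18, 11, 1))
  ci_rot <- circularity_index(mk_map(11, 18, 1))   # axes swapped
  expect_equal(as.numeric(ci), as.numeric(ci_rot), tolerance = 0.03)
  ci_scaled <- circularity_index(mk_map(18, 11, 0.8))
  expect_equal(as.numeric(ci), as.numeric(ci_scaled), tolerance = 0.03)
})

test_that("the MPR slice with the largest jet projection is found", {
  sim <- generate_phantom(compact_phantom_spec(direction = c(0, 0, 1)))
  # stack of y-normal slices; the jet is centered at y = 0, the middle slice
  ref <- plane(origin = c(0, 0, 12), u = c(1, 0, 0), v = c(0, 0, 1),
               rows = 40, cols = 40)
  stack <- make_mpr_stack(ref, 5, 6)
  idx <- select_largest_projection(stack, sim$dataset, 5)
  expect_identical(idx, 3L)
  expect_identical(select_largest_projection(stack[2], sim$dataset, 5), 1L)
  zero <- field_dataset(function(W) matrix(0, nrow(W), 3))
  expect_error(select_largest_projection(stack, zero, 1), "no plane")
  expect_error(select_largest_projection(list(), zero, 1), "empty")
})

test_that("characterize_jet recovers programmed sweep, peak and circularity", {
  spec <- default_phantom_spec(seed = 14, noise_sd = 0)
  sim <- generate_phantom(spec)
  sm <- smooth_flow_dataset(sim$dataset, 1)
  ch <- characterize_jet(sm, c(0, 0, 0), 1:10, circ_dataset = sim$dataset,
                         rates = sim$truth$rates[1:10, 1])
  truth_ang <- sim$truth$jets[[1]]$angle_2ch
  expect_lt(max(abs(ch$angles[["2ch"]] - truth_ang)), 3)
  expect_lt(abs(ch$dynamics[["2ch"]]$difference - 36), 3)
  expect_lt(abs(ch$circularity_index - 0.61), 0.08)
  expect_identical(ch$peak_phase, sim$truth$peak_phase)
})
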