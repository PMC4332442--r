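# Independent oracles used to pin down expected values. These deliberately
# re-derive results with the most literal (often brute-force) formulation
# available, separate from the package's implementation paths.

# Brute-force trilinear interpolation of one velocity component at a
# continuous 0-based voxel coordinate.
oracle_trilinear <- function(vol, x, y, z) {
  d <- dim(vol)
  i0 <- min(max(floor(x), 0), d[1] - 2); fx <- x - i0
  j0 <- min(max(floor(y), 0), d[2] - 2); fy <- y - j0
  k0 <- min(max(floor(z), 0), d[3] - 2); fz <- z - k0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
         (if (dz) fz else 1 - fz)
    acc <- acc + w * vol[i0 + dx + 1, j0 + dy + 1, k0 + dz + 1]
  }
  acc
}

# Even-odd (ray crossing) point-in-polygon test.
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

grid_dim_test <- function(ds) dim(ds$velocities)[1:3]

# world coordinate of a continuous voxel index
voxel_to_world_test <- function(ds, vox) {
  as.numeric((ds$affine %*% c(vox, 1))[1:3])
}

circle_polygon <- function(r, n = 72, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Build a single-phase dataset from an analytic vector field sampled at
# voxel centers (world mm).
field_dataset <- function(fun, dim = c(17, 17, 17), spacing = c(2, 2, 2),
                          n_phases = 1, venc = 150) {
  origin <- -(dim - 1) / 2 * spacing
  affine <- rbind(cbind(diag(spacing), origin), c(0, 0, 0, 1))
  idx <- as.matrix(expand.grid(x = 0:(dim[1] - 1), y = 0:(dim[2] - 1),
                               z = 0:(dim[3] - 1)))
  W <- t(affine %*% rbind(t(idx), 1))[, 1:3]
  V <- fun(W)  # n x 3
  vel <- array(0, dim = c(dim, 3, n_phases))
  for (p in seq_len(n_phases)) for (cc in 1:3) {
    vel[, , , cc, p] <- array(V[, cc], dim = dim)
  }
  flow_dataset(vel, spacing = spacing,
               phase_times = (seq_len(n_phases) - 0.5) * 30,
               rr_interval = n_phases * 30 + 1, venc = venc, affine = affine)
}

# A compact phantom for unit tests: small grid, no aortic jet, single
# static regurgitant jet plus inflow, noise-free unless stated.
compact_phantom_spec <- function(seed = 1, noise_sd = 0, direction = c(0, 0, 1),
                                 target_volume = 8, semi_axes = c(9, 9),
                                 inflow_volume = 40, edge_width = 2) {
  jet <- jet_spec(orifice_center = c(0, 0, 0), direction = direction,
                  semi_axes = semi_axes, target_volume = target_volume,
                  edge_width = edge_width,
                  active_interval = c(0, 300), polarity = "regurgitant",
                  length_mm = 30)
  inflow <- jet_spec(orifice_center = c(0, 0, 0), direction = c(0, 0, -1),
                     semi_axes = c(11, 11), target_volume = inflow_volume,
                     active_interval = c(350, 800), polarity = "inflow",
                     length_mm = 30)
  no_aortic <- jet_spec(orifice_center = c(100, 100, 0), direction = c(0, 0, 1),
                        target_volume = 0, active_interval = c(0, 300),
                        polarity = "inflow")
  phantom_spec(grid_dim = c(26, 26, 26), jets = list(jet = jet),
               inflow = inflow, aortic = no_aortic, noise_sd = noise_sd,
               seed = seed)
}
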