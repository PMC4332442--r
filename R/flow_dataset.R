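#' Construct a 4D three-directional velocity dataset
#'
#' The central container of the package: a velocity field sampled on a
#' regular voxel grid over one cardiac cycle, with three velocity components
#' (along the world x, y, z axes, in cm/s) per voxel and cardiac phase, plus
#' the geometry and velocity-encoding metadata needed to interpret it.
#'
#' @param velocities 5-d numeric array with dimensions
#'   `(nx, ny, nz, component, phase)`; `component` has length 3 (x, y, z
#'   world axes); values in cm/s.
#' @param spacing numeric length-3, voxel size in mm (strictly positive).
#' @param phase_times numeric, mid-phase trigger times in ms from the R-wave;
#'   strictly increasing and all below `rr_interval`.
#' @param rr_interval cardiac cycle length in ms.
#' @param venc velocity-encoding limit in cm/s (positive). Velocities beyond
#'   `venc` alias (wrap) into `[-venc, venc)` on the scanner.
#' @param affine 4x4 matrix mapping homogeneous 0-based voxel indices to
#'   world coordinates in mm. Defaults to a grid centered on the world
#'   origin with axes along the world axes.
#' @param wrapped logical; `TRUE` when the stored values are phase-wrapped
#'   (all within `[-venc, venc)`) and still require unwrapping.
#' @return An object of class `flow_dataset`.
#' @seealso [write_flow_dataset()], [sample_velocity()], [unwrap_velocity()]
#' @export
flow_dataset <- function(velocities, spacing, phase_times, rr_interval, venc,
                         affine = NULL, wrapped = FALSE) {
  stopifnot(is.array(velocities), length(dim(velocities)) == 5L)
  d <- dim(velocities)
  if (d[4] != 3L) stop("velocities must have 3 components on axis 4")
  if (d[5] != length(phase_times)) {
    stop("number of phases in velocities (", d[5], ") does not match phase_times (",
         length(phase_times), ")")
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three strictly positive voxel sizes in mm")
  }
  if (any(diff(phase_times) <= 0)) stop("phase_times must be strictly increasing")
  if (any(phase_times >= rr_interval)) stop("all phase_times must be < rr_interval")
  if (!is.finite(venc) || venc <= 0) stop("venc must be positive (cm/s)")
  if (is.null(affine)) {
    origin <- -(d[1:3] - 1) / 2 * spacing
    affine <- rbind(cbind(diag(spacing), origin), c(0, 0, 0, 1))
  }
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine)) < 1e-12) {
    stop("affine must be an invertible 4x4 voxel-to-world matrix")
  }
  if (wrapped) {
    v <- velocities
    if (any(v < -venc - 1e-9) || any(v >= venc + 1e-9)) {
      stop("a dataset flagged 'wrapped' must store all values within [-venc, +venc)")
    }
  }
  structure(
    list(velocities = velocities, spacing = as.numeric(spacing),
         phase_times = as.numeric(phase_times),
         rr_interval = as.numeric(rr_interval), venc = as.numeric(venc),
         affine = affine, affine_inv = solve(affine), wrapped = isTRUE(wrapped)),
    class = "flow_dataset"
  )
}

#' @export
print.flow_dataset <- function(x, ...) {
  d <- dim(x$velocities)
  cat("<flow_dataset> ", d[1], "x", d[2], "x", d[3], " voxels, ",
      d[5], " phases\n", sep = "")
  cat("  spacing: ", paste(x$spacing, collapse = " x "), " mm;  venc: ",
      x$venc, " cm/s;  RR: ", x$rr_interval, " ms\n", sep = "")
  cat("  wrapped: ", x$wrapped, "\n", sep = "")
  invisible(x)
}

n_phases <- function(dataset) dim(dataset$velocities)[5]
grid_dim <- function(dataset) dim(dataset$velocities)[1:3]

#' Map world coordinates (mm) to continuous 0-based voxel indices
#' @keywords internal
world_to_voxel <- function(dataset, points) {
  pts <- rbind(t(points), 1)
  t(dataset$affine_inv %*% pts)[, 1:3, drop = FALSE]
}

#' Map 0-based voxel indices to world coordinates (mm)
#' @keywords internal
voxel_to_world <- function(dataset, idx) {
  pts <- rbind(t(idx), 1)
  t(dataset$affine %*% pts)[, 1:3, drop = FALSE]
}

# World coordinates (n_voxels x 3) of every voxel center, in grid order
# (x fastest). Used by the phantom generator and direction estimation.
all_voxel_world <- function(dataset_or_dim, affine = NULL) {
  if (inherits(dataset_or_dim, "flow_dataset")) {
    d <- grid_dim(dataset_or_dim)
    affine <- dataset_or_dim$affine
  } else {
    d <- dataset_or_dim
  }
  idx <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1), z = 0:(d[3] - 1)))
  pts <- rbind(t(idx), 1)
  t(affine %*% pts)[, 1:3, drop = FALSE]
}

#' Spatially smooth a flow dataset (separable box filter)
#'
#' Running-mean smoothing of every component and phase with a
#' `(2r+1)^3` voxel box (truncated at the grid edge). Used as a denoising
#' step before jet-direction estimation and streamline visualization, where
#' single-voxel velocity noise would otherwise dominate slow phases; flux
#' quantification stays on the raw data.
#'
#' @param dataset a [flow_dataset()].
#' @param radius_vox box radius in voxels (default 1; 0 returns the input).
#' @return A smoothed [flow_dataset()].
#' @export
smooth_flow_dataset <- function(dataset, radius_vox = 1) {
  if (radius_vox == 0) return(dataset)
  d <- grid_dim(dataset)
  for (p in seq_len(n_phases(dataset))) {
    for (cc in 1:3) {
      vol <- dataset$velocities[, , , cc, p]
      dim(vol) <- d
      dataset$velocities[, , , cc, p] <- box_smooth3(vol, radius_vox)
    }
  }
  dataset
}

# Separable running-mean over a (2r+1)^3 box, truncated at edges.
box_smooth3 <- function(vol, r) {
  smooth_axis <- function(a, axis) {
    d <- dim(a)
    n <- d[axis]
    acc <- array(0, d)
    cnt <- array(0, d)
    idx <- lapply(d, seq_len)
    for (s in -r:r) {
      src <- idx
      keep <- idx
      sel <- seq_len(n) + s
      ok <- sel >= 1 & sel <= n
      src[[axis]] <- sel[ok]
      keep[[axis]] <- which(ok)
      block <- do.call(`[`, c(list(a), src, list(drop = FALSE)))
      part <- do.call(`[`, c(list(acc), keep, list(drop = FALSE)))
      acc <- assign_block(acc, keep, part + block)
      cpart <- do.call(`[`, c(list(cnt), keep, list(drop = FALSE)))
      cnt <- assign_block(cnt, keep, cpart + 1)
    }
    acc / cnt
  }
  for (ax in 1:3) vol <- smooth_axis(vol, ax)
  vol
}

assign_block <- function(a, idx, value) {
  a[idx[[1]], idx[[2]], idx[[3]]] <- value
  a
}

#' Sample the velocity field at arbitrary world points
#'
#' Trilinear interpolation of each velocity component in voxel space.
#' Points outside the voxel grid return the zero vector and are flagged in
#' the `out_of_bounds` attribute, so that reformatting planes may slightly
#' overhang the imaged volume, as clinical multiplanar reformatting does.
#'
#' @param dataset a [flow_dataset()].
#' @param points numeric 3-vector or `n x 3` matrix of world coordinates (mm).
#' @param phase 1-based cardiac phase index.
#' @return `n x 3` matrix of velocity vectors (cm/s) with a logical
#'   attribute `out_of_bounds` of length `n`.
#' @export
sample_velocity <- function(dataset, points, phase) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (ncol(points) != 3L) stop("points must be a 3-vector or n x 3 matrix")
  if (any(!is.finite(points))) stop("non-finite sampling point")
  np <- n_phases(dataset)
  if (length(phase) != 1L || phase < 1 || phase > np) {
    stop("phase out of range 1..", np)
  }
  d <- grid_dim(dataset)
  vox <- world_to_voxel(dataset, points)
  oob <- vox[, 1] < 0 | vox[, 1] > d[1] - 1 |
         vox[, 2] < 0 | vox[, 2] > d[2] - 1 |
         vox[, 3] < 0 | vox[, 3] > d[3] - 1
  n <- nrow(vox)
  out <- matrix(0, n, 3)
  inb <- which(!oob)
  if (length(inb)) {
    v <- vox[inb, , drop = FALSE]
    i0 <- pmin(floor(v[, 1]), d[1] - 2); i0 <- pmax(i0, 0)
    j0 <- pmin(floor(v[, 2]), d[2] - 2); j0 <- pmax(j0, 0)
    k0 <- pmin(floor(v[, 3]), d[3] - 2); k0 <- pmax(k0, 0)
    fx <- v[, 1] - i0; fy <- v[, 2] - j0; fz <- v[, 3] - k0
    vol <- dataset$velocities
    nxy <- d[1] * d[2]
    nxyz <- nxy * d[3]
    base_phase <- (phase - 1) * nxyz * 3
    acc <- matrix(0, length(inb), 3)
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
           (if (dz) fz else 1 - fz)
      lin <- (i0 + dx) + d[1] * (j0 + dy) + nxy * (k0 + dz) + 1
      for (cc in 1:3) {
        acc[, cc] <- acc[, cc] + w * vol[lin + (cc - 1) * nxyz + base_phase]
      }
    }
    out[inb, ] <- acc
  }
  attr(out, "out_of_bounds") <- oob
  out
}
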