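# Jet characterization: instantaneous streamlines, per-phase jet-annulus
# angles in the 2- and 4-chamber projections, angle dynamics across systole,
# and the cross-sectional circularity index of the jet core.

#' Trace an instantaneous streamline
#'
#' Integrates `dx/ds = v(x, t_phase) / |v(x, t_phase)|` with classical
#' 4th-order Runge-Kutta at a fixed arc-length step. Terminates on leaving
#' the grid, on local speed below `min_speed_cm_s`, or at `max_steps`.
#'
#' @param dataset a [flow_dataset()].
#' @param seed world-mm 3-vector inside the grid.
#' @param phase cardiac phase index.
#' @param step_mm integration step (default 0.5 mm).
#' @param max_steps step cap (default 400).
#' @param min_speed_cm_s termination speed (default 1 cm/s).
#' @return A `streamline`: matrix of world points (one row per point) with
#'   attributes `phase`, `seed` and `termination`
#'   (`"speed"`, `"out_of_bounds"` or `"max_steps"`).
#' @export
trace_streamline <- function(dataset, seed, phase, step_mm = 0.5,
                             max_steps = 400, min_speed_cm_s = 1) {
  vdir <- function(x) {
    v <- sample_velocity(dataset, x, phase)
    oob <- attr(v, "out_of_bounds")[1]
    sp <- vnorm(v[1, ])
    list(dir = if (sp > 0) v[1, ] / sp else c(0, 0, 0), speed = sp, oob = oob)
  }
  pts <- matrix(seed, 1, 3)
  x <- as.numeric(seed)
  term <- "max_steps"
  for (s in seq_len(max_steps)) {
    k1 <- vdir(x)
    if (k1$oob) { term <- "out_of_bounds"; break }
    if (k1$speed < min_speed_cm_s) { term <- "speed"; break }
    k2 <- vdir(x + step_mm / 2 * k1$dir)
    k3 <- vdir(x + step_mm / 2 * k2$dir)
    k4 <- vdir(x + step_mm * k3$dir)
    if (k2$oob || k3$oob || k4$oob) { term <- "out_of_bounds"; break }
    x <- x + step_mm / 6 * (k1$dir + 2 * k2$dir + 2 * k3$dir + k4$dir)
    pts <- rbind(pts, x)
  }
  structure(unname(pts), phase = phase, seed = as.numeric(seed),
            termination = term, class = c("streamline", "matrix"))
}

# Mean unit tangent of a streamline over its first `arc_mm` of arc length;
# the jet direction as read from a streamline plot near the orifice.
streamline_direction <- function(sl, arc_mm = 10) {
  if (nrow(sl) < 2) stop("streamline has a single point (termination: ",
                         attr(sl, "termination"), ")")
  seg <- diff(unclass(sl))
  lens <- sqrt(rowSums(seg^2))
  keep <- which(cumsum(lens) <= arc_mm + 1e-9)
  if (!length(keep)) keep <- 1L
  tangents <- seg[keep, , drop = FALSE] / lens[keep]
  unitize(colSums(tangents))
}

#' Project a 3D direction into a view plane
#'
#' Orthogonal projection onto the plane's in-plane axes `(u, v)`,
#' normalized. Errors when the direction is (near-)perpendicular to the
#' view plane.
#'
#' @param direction unit 3-vector.
#' @param view_plane a [plane()].
#' @return in-plane unit 2-vector `(u, v)` components.
#' @export
project_to_view <- function(direction, view_plane) {
  p <- c(sum(direction * view_plane$u), sum(direction * view_plane$v))
  n <- vnorm(p)
  if (n < 1e-6) stop("degenerate projection: direction is perpendicular to the view plane")
  p / n
}

#' Jet-annulus angle in a projection view
#'
#' Angle in degrees, in [0, 180), between the jet direction projected into
#' the view plane and the annulus line of that view. A jet entering the
#' atrium along the annulus normal reads 90 degrees; angles are not folded
#' to [0, 90] since eccentric jets can exceed it.
#'
#' @param jet_direction unit 3-vector (pointing into the receiving chamber).
#' @param annulus_line unit 3-vector along the annulus within the view
#'   plane, or an in-plane unit 2-vector.
#' @param view_plane a [plane()].
#' @return angle in degrees.
#' @export
jet_angle <- function(jet_direction, annulus_line, view_plane) {
  j2 <- project_to_view(jet_direction, view_plane)
  a2 <- if (length(annulus_line) == 3) {
    project_to_view(annulus_line, view_plane)
  } else {
    unitize(annulus_line)
  }
  rad2deg(acos(max(-1, min(1, sum(j2 * a2)))))
}

#' Summarize per-phase angle dynamics
#'
#' @param angles per-phase angles in degrees (>= 1 value).
#' @return list with `min`, `max` and `difference` (max - min).
#' @export
angle_dynamics <- function(angles) {
  if (!length(angles)) stop("empty angle list")
  list(min = min(angles), max = max(angles),
       difference = max(angles) - min(angles))
}

#' Cross-sectional circularity index of a jet
#'
#' Segments the jet core on a through-plane velocity map (|velocity| at or
#' above `core_threshold` of the frame peak), keeps the largest 8-connected
#' component, and returns the ratio of minimum to maximum Feret diameter of
#' its convex hull (1 = circular). Feret diameters are measured on the hull
#' of the pixel centers at 1-degree rotation granularity.
#'
#' @param map a `planar_velocity_map` (typically at the phase of maximum
#'   regurgitant flow).
#' @param core_threshold fraction of the peak (default 0.5, half-max).
#' @return circularity index in (0, 1], with attribute `feret_mm`
#'   (`c(min, max)` diameters in mm).
#' @export
circularity_index <- function(map, core_threshold = 0.5) {
  tp <- abs(map$through_plane)
  peak <- max(tp)
  if (peak <= 0) stop("empty segmentation: map has no nonzero velocities")
  seg <- tp >= core_threshold * peak
  lab <- label_components8(seg)
  if (max(lab) == 0) stop("empty segmentation")
  sizes <- tabulate(lab[lab > 0])
  comp <- which(lab == which.max(sizes), arr.ind = TRUE)
  pts <- cbind(comp[, 1], comp[, 2]) * map$plane$pixel_spacing
  feret <- feret_diameters(pts)
  structure(feret["min"] / feret["max"], feret_mm = unname(feret))
}

# 8-connected component labeling of a binary mask (pixels touching by edge
# or corner belong to one component), by breadth-first flood fill.
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  todo <- which(mask & lab == 0L)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      q <- queue
      queue <- integer(0)
      i <- (q - 1L) %% nr + 1L
      j <- (q - 1L) %/% nr + 1L
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0L && dj == 0L) next
        ii <- i + di; jj <- j + dj
        ok <- ii >= 1L & ii <= nr & jj >= 1L & jj <= nc
        nb <- (jj[ok] - 1L) * nr + ii[ok]
        nb <- nb[mask[nb] & lab[nb] == 0L]
        if (length(nb)) {
          lab[nb] <- cur
          queue <- c(queue, nb)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

# Min/max Feret diameter of a point set: extent of the convex hull's
# projection onto directions swept at 1-degree granularity.
feret_diameters <- function(pts, step_deg = 1) {
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  ang <- deg2rad(seq(0, 180 - step_deg, by = step_deg))
  widths <- vapply(ang, function(th) {
    proj <- hull %*% c(cos(th), sin(th))
    max(proj) - min(proj)
  }, numeric(1))
  c(min = min(widths), max = max(widths))
}

#' Select the MPR slice with the largest jet projection
#'
#' Reformats every plane of a parallel stack at one phase and returns the
#' index of the plane showing the most pixels with speed (velocity
#' magnitude, the quantity streamline visualization renders) at or above
#' `jet_threshold` of the global (stack-wide) peak. Ties go to the lowest
#' index.
#'
#' @param mpr_stack list of [plane()]s from [make_mpr_stack()].
#' @param dataset a [flow_dataset()].
#' @param phase cardiac phase index.
#' @param jet_threshold fraction of the global peak (default 0.5).
#' @return 1-based index into `mpr_stack`.
#' @export
select_largest_projection <- function(mpr_stack, dataset, phase,
                                      jet_threshold = 0.5) {
  if (!length(mpr_stack)) stop("empty MPR stack")
  maps <- lapply(mpr_stack, function(p) {
    v <- reformat_plane(dataset, p, phase)$velocity
    sqrt(v[, , 1]^2 + v[, , 2]^2 + v[, , 3]^2)
  })
  peak <- max(vapply(maps, max, numeric(1)))
  if (peak <= 0) stop("no plane shows jet pixels")
  counts <- vapply(maps, function(m) sum(m >= jet_threshold * peak), numeric(1))
  if (all(counts == 0)) stop("no plane shows jet pixels")
  which.max(counts)
}

#' Characterize a regurgitant jet across systole
#'
#' Per systolic phase, the jet direction is measured as the
#' streamline-averaged tangent over the first 10 mm from the orifice and
#' projected into the 2- and 4-chamber views to obtain the jet-annulus
#' angle; angle dynamics (min, max, difference) are summarized per view; and
#' the circularity index is measured on the tracked measurement plane at the
#' phase of maximum |regurgitant flow rate|.
#'
#' @param dataset a [flow_dataset()].
#' @param orifice_center world-mm 3-vector of the regurgitant orifice.
#' @param phases systolic phase indices.
#' @param views named list of view [plane()]s (default the phantom's
#'   canonical `2ch`/`4ch` planes).
#' @param annulus_lines named list of annulus line unit 3-vectors per view.
#' @param rates per-phase regurgitant flow rates (mL/s, same length as
#'   `phases`) used to locate the peak phase; when `NULL` the phase with the
#'   fastest in-sphere speed is used.
#' @param tracked_series optional [tracked_plane_series()]; its plane at the
#'   peak phase is used for the circularity cross-section (otherwise a plane
#'   perpendicular to the measured jet direction, 15 mm from the orifice).
#' @param seed_offset_mm streamline seed offset from the orifice along the
#'   estimated jet direction (default 3 mm).
#' @param core_threshold circularity segmentation threshold (default 0.5).
#' @param circ_dataset dataset used for the circularity cross-section
#'   (default `dataset`). When `dataset` is a denoised copy for direction
#'   estimation, pass the raw data here: spatial smoothing is anisotropic in
#'   mm on anisotropic voxels and would bias the half-max contour, while the
#'   half-max threshold is well above the noise floor anyway.
#' @return A `jet_characterization`: per-phase angle table, per-view
#'   dynamics, circularity index, peak phase.
#' @export
characterize_jet <- function(dataset, orifice_center, phases,
                             views = list("2ch" = phantom_view_plane("2ch"),
                                          "4ch" = phantom_view_plane("4ch")),
                             annulus_lines = list("2ch" = c(1, 0, 0),
                                                  "4ch" = c(0, 1, 0)),
                             rates = NULL, tracked_series = NULL,
                             seed_offset_mm = 3, core_threshold = 0.5,
                             circ_dataset = dataset) {
  angs <- matrix(NA_real_, length(phases), length(views),
                 dimnames = list(NULL, names(views)))
  dirs <- matrix(NA_real_, length(phases), 3)
  wts <- numeric(length(phases))
  for (i in seq_along(phases)) {
    ph <- phases[i]
    d0 <- estimate_jet_direction(dataset, orifice_center, ph)
    sl <- trace_streamline(dataset, orifice_center + seed_offset_mm * d0, ph)
    dirs[i, ] <- if (nrow(sl) >= 2) streamline_direction(sl) else as.numeric(d0)
    wts[i] <- attr(d0, "n_voxels") * attr(d0, "mean_speed")^2
  }
  # the jet direction evolves smoothly; regularize the trajectory so that
  # quiet endpoint phases (near the velocity noise floor) are anchored by
  # the well-resolved mid-systolic phases
  dirs <- refine_direction_trajectory(dirs, dataset$phase_times[phases], wts)
  for (i in seq_along(phases)) {
    for (vn in names(views)) {
      angs[i, vn] <- jet_angle(dirs[i, ], annulus_lines[[vn]], views[[vn]])
    }
  }
  dynamics <- lapply(names(views), function(vn) angle_dynamics(angs[, vn]))
  names(dynamics) <- names(views)
  peak_i <- if (!is.null(rates)) which.max(abs(rates)) else {
    speeds <- vapply(seq_along(phases), function(i) {
      v <- sample_velocity(dataset, orifice_center + seed_offset_mm * dirs[i, ],
                           phases[i])
      vnorm(v[1, ])
    }, numeric(1))
    which.max(speeds)
  }
  peak_phase <- phases[peak_i]
  circ_plane <- if (!is.null(tracked_series)) {
    tracked_series$planes[[match(peak_phase, tracked_series$phases)]]
  } else {
    plane(origin = orifice_center + 15 * dirs[peak_i, ], normal = dirs[peak_i, ])
  }
  circ_map <- reformat_plane(circ_dataset, circ_plane, peak_phase)
  # confine the cross-section to the tracked jet (other flows may clip the
  # raster corners) before segmenting its core
  jet_region <- default_jet_roi(circ_map, frac = 0.1)
  circ_map$through_plane[!jet_region] <- 0
  ci <- circularity_index(circ_map, core_threshold)
  structure(list(
    angles = data.frame(phase = phases,
                        time_ms = dataset$phase_times[phases], angs,
                        check.names = FALSE),
    directions = dirs, dynamics = dynamics,
    circularity_index = as.numeric(ci),
    feret_mm = attr(ci, "feret_mm"), peak_phase = peak_phase
  ), class = "jet_characterization")
}

#' @export
print.jet_characterization <- function(x, ...) {
  cat("<jet_characterization> ", nrow(x$angles), " systolic phases\n", sep = "")
  for (vn in names(x$dynamics)) {
    d <- x$dynamics[[vn]]
    cat(sprintf("  %s: min %.1f, max %.1f, difference %.1f deg\n",
                vn, d$min, d$max, d$difference))
  }
  cat(sprintf("  circularity index: %.2f (peak phase %d)\n",
              x$circularity_index, x$peak_phase))
  invisible(x)
}
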