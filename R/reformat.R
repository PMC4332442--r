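# Multiplanar reformatting (MPR): resampling the velocity volume onto
# arbitrary oriented planes and reducing vectors to their through-plane
# component, the quantity integrated for transvalvular flow.

#' Construct an oriented reformatting plane
#'
#' A plane is defined by its origin (the raster center, world mm), two
#' orthonormal in-plane axes `u`, `v`, the raster size and pixel spacing.
#' The plane normal is `u x v` (right-handed). Either supply `u` and `v`,
#' or just `normal` and let the deterministic in-plane frame rule pick them
#' (world x-axis projected into the plane, falling back to y).
#'
#' @param origin world-mm 3-vector (raster center).
#' @param normal plane normal (used when `u`, `v` are absent).
#' @param u,v orthonormal in-plane unit vectors.
#' @param rows,cols raster size in pixels (default 64 x 64).
#' @param pixel_spacing pixel edge length in mm (default 1).
#' @return A `plane` object.
#' @export
plane <- function(origin, normal = NULL, u = NULL, v = NULL,
                  rows = 64, cols = 64, pixel_spacing = 1) {
  if (is.null(u) || is.null(v)) {
    if (is.null(normal)) stop("supply either normal or both u and v")
    fr <- orthonormal_frame(normal)
    u <- fr$u; v <- fr$v
  }
  if (abs(vnorm(u) - 1) > 1e-9 || abs(vnorm(v) - 1) > 1e-9) {
    stop("u and v must be unit vectors")
  }
  if (abs(sum(u * v)) > 1e-9) stop("u and v must be orthogonal")
  n <- cross3(u, v)
  structure(list(origin = as.numeric(origin), u = as.numeric(u),
                 v = as.numeric(v), normal = n, rows = as.integer(rows),
                 cols = as.integer(cols),
                 pixel_spacing = as.numeric(pixel_spacing)),
            class = "plane")
}

#' @export
print.plane <- function(x, ...) {
  cat("<plane> origin (", paste(round(x$origin, 2), collapse = ", "),
      ") mm, normal (", paste(round(x$normal, 3), collapse = ", "),
      "), ", x$rows, "x", x$cols, " px @ ", x$pixel_spacing, " mm\n", sep = "")
  invisible(x)
}

# In-plane pixel-center offsets (mm) along u and v, raster centered on the
# plane origin.
plane_pixel_offsets <- function(plane) {
  ui <- (seq_len(plane$rows) - (plane$rows + 1) / 2) * plane$pixel_spacing
  vj <- (seq_len(plane$cols) - (plane$cols + 1) / 2) * plane$pixel_spacing
  list(u = ui, v = vj)
}

# World coordinates (rows*cols x 3) of every pixel center, row index fastest.
plane_pixel_world <- function(plane) {
  off <- plane_pixel_offsets(plane)
  g <- expand.grid(du = off$u, dv = off$v)
  sweep(outer(g$du, plane$u) + outer(g$dv, plane$v), 2, plane$origin, `+`)
}

#' Build a stack of parallel reformatting planes
#'
#' `n_slices` copies of the reference plane, spaced `slice_gap_mm` along its
#' normal and centered on it, as used to find the slice with the largest jet
#' projection in a 2- or 4-chamber orientation.
#'
#' @param reference a [plane()], or `"2ch"` / `"4ch"` for the phantom's
#'   canonical view planes through the annulus center.
#' @param n_slices number of parallel planes (>= 1).
#' @param slice_gap_mm spacing along the normal.
#' @return list of [plane()]s, ordered along the normal.
#' @export
make_mpr_stack <- function(reference, n_slices, slice_gap_mm = 3) {
  if (is.character(reference)) reference <- phantom_view_plane(reference)
  stopifnot(inherits(reference, "plane"))
  if (n_slices < 1) stop("n_slices must be >= 1")
  offsets <- (seq_len(n_slices) - (n_slices + 1) / 2) * slice_gap_mm
  lapply(offsets, function(o) {
    p <- reference
    p$origin <- reference$origin + o * reference$normal
    p
  })
}

#' Reformat the velocity field onto a plane
#'
#' Samples the velocity vector at every pixel center by trilinear
#' interpolation and projects it onto the plane normal to obtain the
#' through-plane velocity map. Pixels outside the voxel grid are masked.
#'
#' @param dataset a [flow_dataset()].
#' @param plane a [plane()].
#' @param phase 1-based cardiac phase.
#' @return A `planar_velocity_map`: list with `velocity`
#'   (rows x cols x 3 cm/s), `through_plane` (rows x cols, cm/s; positive
#'   along the plane normal), `oob` (logical mask), `pixel_area` (mm^2),
#'   `plane`, `phase`.
#' @export
reformat_plane <- function(dataset, plane, phase) {
  stopifnot(inherits(plane, "plane"))
  pts <- plane_pixel_world(plane)
  vel <- sample_velocity(dataset, pts, phase)
  oob <- attr(vel, "out_of_bounds")
  varr <- array(vel, dim = c(plane$rows, plane$cols, 3))
  tp <- matrix(vel %*% plane$normal, plane$rows, plane$cols)
  structure(list(velocity = varr, through_plane = tp,
                 oob = matrix(oob, plane$rows, plane$cols),
                 pixel_area = plane$pixel_spacing^2,
                 plane = plane, phase = phase),
            class = "planar_velocity_map")
}

# ---- regions of interest on a map ---------------------------------------

# ROI argument convention used across the package: either a logical
# rows x cols pixel mask, or a closed polygon given as a 2-column matrix /
# data.frame of in-plane coordinates (mm along u and v, origin at the plane
# center). Polygon membership is by pixel-center containment, even-odd rule.
roi_mask <- function(map, roi) {
  if (is.logical(roi) && is.matrix(roi)) {
    if (!all(dim(roi) == dim(map$through_plane))) {
      stop("ROI mask shape does not match the map raster")
    }
    return(roi)
  }
  poly <- as.matrix(roi)
  if (ncol(poly) != 2L) stop("polygon ROI must have two columns (u_mm, v_mm)")
  off <- plane_pixel_offsets(map$plane)
  g <- expand.grid(du = off$u, dv = off$v)
  inside <- pracma::inpolygon(g$du, g$dv, poly[, 1], poly[, 2],
                              boundary = TRUE)
  m <- matrix(inside, map$plane$rows, map$plane$cols)
  if (!any(m)) stop("ROI encloses no pixel centers")
  m
}

#' Mean through-plane velocity and area over an ROI
#'
#' @param map a `planar_velocity_map` from [reformat_plane()].
#' @param roi polygon (2-column, in-plane mm) or logical pixel mask.
#' @return list with `mean_velocity` (cm/s), `area` (mm^2) and `n_pixels`.
#' @export
through_plane_profile <- function(map, roi) {
  m <- roi_mask(map, roi)
  list(mean_velocity = mean(map$through_plane[m]),
       area = sum(m) * map$pixel_area, n_pixels = sum(m))
}

#' Serialize / deserialize planes as JSON
#' @param planes a [plane()] or list of planes.
#' @param path JSON file path.
#' @export
write_planes <- function(planes, path) {
  if (inherits(planes, "plane")) planes <- list(planes)
  jsonlite::write_json(lapply(planes, unclass), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_planes
#' @export
read_planes <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow_or_len(raw)), function(i) {
    r <- if (is.data.frame(raw)) lapply(raw, function(col) col[[i]]) else raw[[i]]
    plane(origin = unlist(r$origin), u = unlist(r$u), v = unlist(r$v),
          rows = r$rows, cols = r$cols, pixel_spacing = r$pixel_spacing)
  })
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
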