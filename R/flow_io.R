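#' Write a flow dataset to NIfTI files with a JSON sidecar
#'
#' Stores the three velocity components as separate 4D NIfTI volumes
#' (`vx.nii.gz`, `vy.nii.gz`, `vz.nii.gz`; x/y/z/time) plus a `flow.json`
#' sidecar carrying the quantities NIfTI cannot: the velocity-encoding
#' limit, phase timing, cycle length and the wrapped flag. Values are
#' written as 64-bit floats so the round trip is lossless.
#'
#' @param dataset a [flow_dataset()].
#' @param directory output directory, created if needed.
#' @return Invisibly, the paths written (named character vector).
#' @export
write_flow_dataset <- function(dataset, directory) {
  stopifnot(inherits(dataset, "flow_dataset"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory)) stop("cannot create directory: ", directory)
  }
  comp_files <- c(x = "vx.nii.gz", y = "vy.nii.gz", z = "vz.nii.gz")
  paths <- file.path(directory, comp_files)
  names(paths) <- names(comp_files)
  pixdim <- c(dataset$spacing, diff(dataset$phase_times[1:2]))
  aff <- structure(dataset$affine, code = 2L)
  for (cc in 1:3) {
    arr <- dataset$velocities[, , , cc, , drop = TRUE]
    dim(arr) <- c(grid_dim(dataset), n_phases(dataset))
    img <- RNifti::asNifti(arr, pixdim = pixdim)
    RNifti::sform(img) <- aff
    RNifti::writeNifti(img, paths[cc], datatype = "double")
  }
  sidecar <- list(
    venc_cm_s = dataset$venc,
    phase_times_ms = dataset$phase_times,
    rr_ms = dataset$rr_interval,
    spacing_mm = dataset$spacing,
    # NIfTI stores the sform in float32; carry the exact affine here
    affine = as.vector(dataset$affine),
    wrapped = dataset$wrapped
  )
  sidecar_path <- file.path(directory, "flow.json")
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, sidecar = sidecar_path))
}

#' Load a flow dataset written by [write_flow_dataset()]
#'
#' @param directory directory holding `vx/vy/vz.nii.gz` and `flow.json`.
#' @return A [flow_dataset()].
#' @export
load_flow_dataset <- function(directory) {
  comp_files <- file.path(directory, c("vx.nii.gz", "vy.nii.gz", "vz.nii.gz"))
  sidecar_path <- file.path(directory, "flow.json")
  missing <- c(comp_files, sidecar_path)[!file.exists(c(comp_files, sidecar_path))]
  if (length(missing)) stop("missing file(s): ", paste(missing, collapse = ", "))
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (key in c("venc_cm_s", "phase_times_ms", "rr_ms")) {
    if (is.null(sidecar[[key]])) stop("sidecar missing required key: ", key)
  }
  if (any(diff(sidecar$phase_times_ms) <= 0)) {
    stop("sidecar phase_times_ms must be strictly increasing")
  }
  imgs <- lapply(comp_files, RNifti::readNifti)
  dims <- lapply(imgs, function(i) dim(i))
  if (!all(vapply(dims, function(d) identical(d, dims[[1]]), logical(1)))) {
    stop("velocity component volumes are not congruent: ",
         paste(vapply(dims, function(d) paste(d, collapse = "x"), character(1)),
               collapse = " vs "))
  }
  d <- dims[[1]]
  if (length(d) != 4L) stop("expected 4D component volumes, got ", length(d), "D")
  if (d[4] != length(sidecar$phase_times_ms)) {
    stop("volume has ", d[4], " phases but sidecar lists ",
         length(sidecar$phase_times_ms))
  }
  vel <- array(0, dim = c(d[1:3], 3, d[4]))
  for (cc in 1:3) {
    a <- as.array(imgs[[cc]])
    vel[, , , cc, ] <- a
  }
  aff <- if (!is.null(sidecar$affine)) {
    matrix(sidecar$affine, 4, 4)
  } else {
    unclass(RNifti::xform(imgs[[1]]))[1:4, 1:4]
  }
  spacing <- sidecar$spacing_mm %||% sqrt(colSums(aff[1:3, 1:3]^2))
  flow_dataset(vel, spacing = as.numeric(spacing),
               phase_times = as.numeric(sidecar$phase_times_ms),
               rr_interval = as.numeric(sidecar$rr_ms),
               venc = as.numeric(sidecar$venc_cm_s),
               affine = aff, wrapped = isTRUE(sidecar$wrapped))
}

#' Write / read a voxel mask as uint8 NIfTI
#' @param mask logical 3-d array congruent with one phase of the dataset.
#' @param dataset the dataset supplying geometry.
#' @param path output `.nii.gz` path.
#' @export
write_voxel_mask <- function(mask, dataset, path) {
  stopifnot(identical(dim(mask), grid_dim(dataset)))
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)),
                         pixdim = dataset$spacing)
  RNifti::sform(img) <- structure(dataset$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_voxel_mask
#' @export
read_voxel_mask <- function(path) {
  as.array(RNifti::readNifti(path)) > 0
}
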