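# Venc aliasing: velocities beyond the encoding limit wrap into
# [-venc, venc) because phase is measured modulo 2*pi, i.e. modulo 2*venc on
# the velocity scale. Unwrapping exploits the linear relation between the
# stored value and true velocity: a wrapped voxel differs from its true value
# by an integer multiple of 2*venc.

#' Wrap velocities into the encoded range (simulate Venc aliasing)
#'
#' Maps every velocity value into `[-venc, venc)` by adding the unique
#' required multiple of `2*venc`, and flags the dataset as wrapped. This is
#' the forward model of the aliasing artifact that [unwrap_velocity()]
#' corrects.
#'
#' @param dataset a [flow_dataset()].
#' @return The dataset with aliased values and `wrapped = TRUE`.
#' @export
apply_aliasing <- function(dataset) {
  stopifnot(inherits(dataset, "flow_dataset"))
  venc <- dataset$venc
  v <- dataset$velocities
  v <- ((v + venc) %% (2 * venc)) - venc
  dataset$velocities <- v
  dataset$wrapped <- TRUE
  dataset
}

#' Phase-unwrap one velocity component within a region
#'
#' Continuity-guided region growing: trusted seed voxels (everything outside
#' `region`, or the grid boundary faces when the region covers the whole
#' grid) are taken as unwrapped, and the correction front grows inwards by
#' breadth-first sweeps. Each newly reached voxel is corrected by the single
#' multiple of `2*venc` that brings it closest to the mean of its
#' already-unwrapped 6-neighbors -- the linear relation between stored value
#' and the velocity scale between -Venc and +Venc guarantees the true value
#' differs from the stored one by an integer multiple of `2*venc`. One
#' growth pass resolves wrapped blobs including their interiors, provided
#' the true field is continuous at the voxel scale (|neighbor difference| <
#' venc) and wrapped blobs do not touch the trusted seeds.
#'
#' Assumes a single wrap at most (true speeds below `3*venc`) in the
#' default clinical setting, though multiple wraps are corrected too as
#' long as continuity holds. Voxels outside `region` are never modified.
#'
#' @param dataset a [flow_dataset()] flagged as wrapped.
#' @param component which component to unwrap: 1/2/3 or "x"/"y"/"z".
#' @param region logical 3-d mask of voxels eligible for correction
#'   (congruent with the grid). Must select at least one voxel.
#' @param max_iter cap on growth sweeps per cardiac phase (default: enough
#'   to cross the grid).
#' @return The dataset with the component corrected and `wrapped = FALSE`.
#' @export
unwrap_velocity <- function(dataset, component, region, max_iter = NULL) {
  stopifnot(inherits(dataset, "flow_dataset"))
  if (!dataset$wrapped) {
    warning("dataset is not flagged as wrapped; unwrapping anyway")
  }
  if (is.character(component)) component <- match(component, c("x", "y", "z"))
  stopifnot(component %in% 1:3)
  d <- grid_dim(dataset)
  if (!identical(dim(region), d)) stop("region mask shape must match the grid")
  if (!any(region)) stop("region is empty")
  if (is.null(max_iter)) max_iter <- sum(d)
  venc <- dataset$venc

  # trusted seeds: outside the region; or the grid faces if region is all
  seed <- !region
  if (!any(seed)) {
    seed <- array(FALSE, dim = d)
    seed[c(1, d[1]), , ] <- TRUE
    seed[, c(1, d[2]), ] <- TRUE
    seed[, , c(1, d[3])] <- TRUE
  }

  shift6 <- function(a, fill = 0) {
    z <- function(axis, by) {
      idx <- lapply(d, seq_len)
      src <- idx
      sel <- idx[[axis]] + by
      ok <- sel >= 1 & sel <= d[axis]
      out <- array(fill, d)
      src[[axis]] <- sel[ok]
      dst <- idx; dst[[axis]] <- which(ok)
      out[dst[[1]], dst[[2]], dst[[3]]] <-
        a[src[[1]], src[[2]], src[[3]], drop = FALSE]
      out
    }
    list(z(1, -1), z(1, 1), z(2, -1), z(2, 1), z(3, -1), z(3, 1))
  }

  neighborhood_mean26 <- function(vol) {
    acc <- array(0, d); cnt <- array(0, d)
    idx <- lapply(d, seq_len)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      src <- idx; dst <- idx
      ok <- TRUE
      for (ax in 1:3) {
        by <- c(dx, dy, dz)[ax]
        sel <- idx[[ax]] + by
        inb <- sel >= 1 & sel <= d[ax]
        src[[ax]] <- sel[inb]
        dst[[ax]] <- which(inb)
      }
      block <- vol[src[[1]], src[[2]], src[[3]], drop = FALSE]
      acc[dst[[1]], dst[[2]], dst[[3]]] <-
        acc[dst[[1]], dst[[2]], dst[[3]]] + block
      cnt[dst[[1]], dst[[2]], dst[[3]]] <-
        cnt[dst[[1]], dst[[2]], dst[[3]]] + 1
    }
    acc / cnt
  }

  has_jump <- function(vol) {
    for (axis in 1:3) {
      idx <- lapply(d, seq_len)
      lo <- idx; lo[[axis]] <- seq_len(d[axis] - 1L)
      hi <- idx; hi[[axis]] <- seq_len(d[axis] - 1L) + 1L
      a <- vol[lo[[1]], lo[[2]], lo[[3]], drop = FALSE]
      b <- vol[hi[[1]], hi[[2]], hi[[3]], drop = FALSE]
      if (any(abs(a - b) > venc)) return(TRUE)
    }
    FALSE
  }

  residual <- 0L
  for (p in seq_len(n_phases(dataset))) {
    vol <- dataset$velocities[, , , component, p]
    dim(vol) <- d
    # a wrap forces a > venc discontinuity somewhere (the true field is
    # continuous at the voxel scale); phases without one need no growth
    if (!has_jump(vol)) next
    done <- seed
    iter <- 0L
    while (!all(done | !region)) {
      iter <- iter + 1L
      if (iter > max_iter) break
      sh_done <- shift6(done, FALSE)
      sh_val <- shift6(vol * done, 0)
      cnt <- Reduce(`+`, sh_done)
      tot <- Reduce(`+`, sh_val)
      frontier <- region & !done & cnt > 0
      if (!any(frontier)) break
      ref <- tot[frontier] / cnt[frontier]
      k <- round((ref - vol[frontier]) / (2 * venc))
      vol[frontier] <- vol[frontier] + 2 * k * venc
      done <- done | frontier
    }
    residual <- residual + sum(region & !done)
    # consistency cleanup: the growth pass decides each voxel from the
    # first neighbors reached, which can misfire where the true field has
    # steps near venc (e.g. a fast plug core against near-static blood).
    # Sweep until every region voxel agrees with its 26-neighborhood mean
    # to within venc, correcting by the closest 2*venc multiple.
    for (sweep in seq_len(20L)) {
      nb <- neighborhood_mean26(vol)
      k <- round((nb - vol) / (2 * venc))
      upd <- region & k != 0 & (abs(vol + 2 * k * venc - nb) < abs(vol - nb))
      if (!any(upd)) break
      vol[upd] <- vol[upd] + 2 * k[upd] * venc
    }
    dataset$velocities[, , , component, p] <- vol
  }
  if (residual > 0L) {
    stop("phase unwrapping stopped with ", residual,
         " unreached/unresolved voxel(s)")
  }
  dataset$wrapped <- FALSE
  dataset
}
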