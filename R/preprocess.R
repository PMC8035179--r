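#' Soft-tissue mask of a CT volume
#'
#' Flags voxels whose HU lies inside the soft-tissue display window
#' (level 40, width 400), i.e. `[-160, 240]` HU — the band used both for
#' manual gland delineation and for locating the head-and-neck soft tissue
#' when cropping.
#'
#' @param ct a CT `sq_volume`.
#' @return Logical 3D array.
#' @export
soft_tissue_mask <- function(ct) {
  stopifnot(inherits(ct, "sq_volume"))
  if (ct$modality != "CT") stop("soft_tissue_mask requires a CT volume")
  ct$voxels >= -160 & ct$voxels <= 240
}

#' Plan a crop to the network's fixed matrix
#'
#' Chooses the axial (z) window of `target_shape[3]` slices maximising the
#' summed soft-tissue z-profile (per-slice soft-tissue voxel count) over all
#' contiguous windows, then centres the x/y window on the bounding box of
#' the axial maximum-intensity projection of the soft-tissue mask, clipping
#' to the volume and recording symmetric padding where the source is smaller
#' than the target. Deterministic; ties resolve to the first window.
#'
#' @param ct a CT `sq_volume`.
#' @param target_shape integer triple, default the full-fidelity
#'   `c(256, 128, 64)` training matrix.
#' @return An object of class `sq_crop_plan` with per-axis 1-based
#'   `start`/`stop` indices, `pad_before`/`pad_after`, `target` and
#'   `src_shape`; `(stop - start + 1) + pad_before + pad_after == target`.
#' @export
plan_crop <- function(ct, target_shape = c(256L, 128L, 64L)) {
  target_shape <- as.integer(target_shape)
  stopifnot(length(target_shape) == 3L, all(target_shape > 0))
  mask <- soft_tissue_mask(ct)
  if (!any(mask)) stop("empty soft-tissue mask; cannot plan crop")
  d <- dim(mask)

  start <- integer(3); stop_ <- integer(3)
  pad_b <- integer(3); pad_a <- integer(3)

  # z: contiguous window maximising the soft-tissue profile sum
  zprof <- apply(mask, 3, sum)
  tz <- target_shape[3]
  if (d[3] <= tz) {
    start[3] <- 1L; stop_[3] <- d[3]
    extra <- tz - d[3]
    pad_b[3] <- extra %/% 2L; pad_a[3] <- extra - pad_b[3]
  } else {
    csum <- cumsum(c(0, zprof))
    wins <- csum[(tz + 1):(d[3] + 1)] - csum[1:(d[3] - tz + 1)]
    start[3] <- which.max(wins)
    stop_[3] <- start[3] + tz - 1L
  }

  # x/y: centre on the bounding box of the axial MIP of the mask
  mip <- apply(mask, c(1, 2), any)
  for (a in 1:2) {
    prof <- if (a == 1) apply(mip, 1, any) else apply(mip, 2, any)
    bb <- range(which(prof))
    tgt <- target_shape[a]
    if (d[a] <= tgt) {
      start[a] <- 1L; stop_[a] <- d[a]
      extra <- tgt - d[a]
      pad_b[a] <- extra %/% 2L; pad_a[a] <- extra - pad_b[a]
    } else {
      ctr <- mean(bb)
      s <- as.integer(round(ctr - tgt / 2 + 0.5))
      s <- max(1L, min(s, d[a] - tgt + 1L))
      start[a] <- s; stop_[a] <- s + tgt - 1L
    }
  }
  structure(list(start = start, stop = stop_, pad_before = pad_b,
                 pad_after = pad_a, target = target_shape,
                 src_shape = as.integer(d)), class = "sq_crop_plan")
}

#' @export
print.sq_crop_plan <- function(x, ...) {
  cat("<sq_crop_plan>\n")
  for (a in 1:3)
    cat(sprintf("  %s: [%d, %d] of %d, pad %d+%d -> %d\n",
                c("x", "y", "z")[a], x$start[a], x$stop[a], x$src_shape[a],
                x$pad_before[a], x$pad_after[a], x$target[a]))
  invisible(x)
}

default_pad <- function(vol) {
  if (inherits(vol, "sq_labels")) 0
  else if (vol$modality == "CT") -1000
  else 0
}

#' Apply (or invert) a crop plan
#'
#' `apply_crop` extracts the planned window and pads to the target shape;
#' `uncrop` places a cropped volume back into the source grid. Any voxel
#' inside the window round-trips exactly. Cropped volumes keep a consistent
#' world origin so they can be resampled against the originals.
#'
#' @param vol `sq_volume` or `sq_labels` on the grid the plan was built for.
#' @param plan an `sq_crop_plan`.
#' @param pad_value value for padded/out-of-window voxels; defaults to
#'   -1000 for CT and 0 for SPECT and labels.
#' @return Object of the same kind as `vol`.
#' @export
apply_crop <- function(vol, plan, pad_value = NULL) {
  stopifnot(inherits(plan, "sq_crop_plan"))
  dat <- if (inherits(vol, "sq_labels")) vol$labels else vol$voxels
  if (!identical(dim(dat), plan$src_shape))
    stop("crop plan was built for a different grid")
  if (is.null(pad_value)) pad_value <- default_pad(vol)
  out <- array(pad_value, dim = plan$target)
  win <- dat[plan$start[1]:plan$stop[1], plan$start[2]:plan$stop[2],
             plan$start[3]:plan$stop[3], drop = FALSE]
  out[plan$pad_before[1] + seq_len(dim(win)[1]),
      plan$pad_before[2] + seq_len(dim(win)[2]),
      plan$pad_before[3] + seq_len(dim(win)[3])] <- win
  origin <- vol$origin + (plan$start - 1 - plan$pad_before) * vol$spacing
  if (inherits(vol, "sq_labels"))
    sq_labels(out, spacing = vol$spacing, origin = origin)
  else
    sq_volume(out, spacing = vol$spacing, origin = origin,
              modality = vol$modality, units = vol$units,
              time_min = vol$time_min)
}

#' @rdname apply_crop
#' @param cropped the cropped volume to restore.
#' @export
uncrop <- function(cropped, plan, pad_value = NULL) {
  stopifnot(inherits(plan, "sq_crop_plan"))
  dat <- if (inherits(cropped, "sq_labels")) cropped$labels else cropped$voxels
  if (!identical(dim(dat), plan$target))
    stop("volume does not match the plan's target shape")
  if (is.null(pad_value)) pad_value <- default_pad(cropped)
  out <- array(pad_value, dim = plan$src_shape)
  nw <- plan$stop - plan$start + 1L
  win <- dat[plan$pad_before[1] + seq_len(nw[1]),
             plan$pad_before[2] + seq_len(nw[2]),
             plan$pad_before[3] + seq_len(nw[3]), drop = FALSE]
  out[plan$start[1]:plan$stop[1], plan$start[2]:plan$stop[2],
      plan$start[3]:plan$stop[3]] <- win
  origin <- cropped$origin - (plan$start - 1 - plan$pad_before) * cropped$spacing
  if (inherits(cropped, "sq_labels"))
    sq_labels(out, spacing = cropped$spacing, origin = origin)
  else
    sq_volume(out, spacing = cropped$spacing, origin = origin,
              modality = cropped$modality, units = cropped$units,
              time_min = cropped$time_min)
}

#' Normalise a cropped CT for the network
#'
#' Clips HU to the soft-tissue window `[-160, 240]` and maps it linearly to
#' `[0, 1]` (so 40 HU, the window level, maps to 0.5).
#'
#' @param ct_cropped a CT `sq_volume`.
#' @return Numeric 3D array in `[0, 1]`.
#' @export
normalize_for_network <- function(ct_cropped) {
  stopifnot(inherits(ct_cropped, "sq_volume"))
  if (ct_cropped$modality != "CT") stop("expected a CT volume")
  (pmin(pmax(ct_cropped$voxels, -160), 240) + 160) / 400
}

#' World origin of a cropped volume
#'
#' Origin (mm) of the volume that [apply_crop()] produces from `vol` under
#' `plan`; useful to attach correct geometry to arrays (e.g. predicted label
#' maps) created on the cropped grid before [uncrop()]ing them.
#'
#' @param plan an `sq_crop_plan`.
#' @param vol the uncropped `sq_volume`/`sq_labels` the plan was built for.
#' @return Numeric length-3 origin.
#' @export
crop_origin <- function(plan, vol) {
  vol$origin + (plan$start - 1 - plan$pad_before) * vol$spacing
}

#' Read/write a crop plan as JSON
#'
#' @param plan an `sq_crop_plan`; `path` file path.
#' @return `read_crop_plan` returns an `sq_crop_plan`.
#' @export
write_crop_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_crop_plan
#' @export
read_crop_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(lapply(x, as.integer), class = "sq_crop_plan")
}
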