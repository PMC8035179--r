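#' Calibrated 3D volume
#'
#' Container for a 3D scalar grid with voxel geometry and acquisition
#' metadata. CT volumes are stored in Hounsfield units (HU), SPECT volumes in
#' activity concentration (Bq/mL). Voxel indices are 1-based in R; world
#' coordinates are mm offsets of voxel centres from the volume `origin`
#' (position of voxel (1,1,1)), with the CT frame serving as the study frame.
#'
#' @param voxels numeric 3D array.
#' @param spacing per-axis voxel size in mm (length 3, strictly positive).
#' @param origin world position (mm) of the first voxel, default `c(0,0,0)`.
#' @param modality `"CT"` or `"SPECT"`.
#' @param units measurement units; defaults to `"HU"` for CT, `"Bq/mL"` for
#'   SPECT and must be consistent with the modality.
#' @param time_min acquisition time in minutes post injection (typically 20
#'   or 40); `NA` when irrelevant (CT).
#' @return An object of class `sq_volume`.
#' @export
sq_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                      modality = c("CT", "SPECT"), units = NULL,
                      time_min = NA_real_) {
  modality <- match.arg(modality)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  if (anyNA(voxels)) stop("voxels contain NA/NaN")
  if (modality == "SPECT" && min(voxels) < 0)
    stop("SPECT voxels must be non-negative (activity concentration)")
  if (modality == "CT" && min(voxels) < -1024)
    stop("CT voxels must be >= -1024 HU")
  default_units <- if (modality == "CT") "HU" else "Bq/mL"
  if (is.null(units)) units <- default_units
  if (units != default_units)
    stop(sprintf("units '%s' inconsistent with modality %s", units, modality))
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin), modality = modality,
                 units = units, time_min = as.numeric(time_min)),
            class = "sq_volume")
}

#' @export
print.sq_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<sq_volume> %s [%s] %dx%dx%d, spacing %.3gx%.3gx%.3g mm",
              x$modality, x$units, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  if (!is.na(x$time_min)) cat(sprintf(", t = %g min p.i.", x$time_min))
  cat(sprintf("\n  range [%.4g, %.4g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Gland label map
#'
#' Integer volume labelling the four salivary glands on the grid of a
#' reference volume. Codes: 0 background, 1 right parotid, 2 left parotid,
#' 3 right submandibular, 4 left submandibular (see [gland_codes()]).
#'
#' @param labels integer 3D array with values in 0..4.
#' @param reference optional `sq_volume` supplying the grid geometry; its
#'   shape must match `labels`.
#' @param spacing,origin geometry used when no reference is given.
#' @return An object of class `sq_labels`.
#' @export
sq_labels <- function(labels, reference = NULL, spacing = NULL,
                      origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  if (anyNA(labels)) stop("labels contain NA")
  u <- unique(as.vector(labels))
  if (!all(u %in% 0:4)) stop("label values must be in {0,1,2,3,4}")
  storage.mode(labels) <- "integer"
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "sq_volume"))
    if (!identical(dim(labels), dim(reference$voxels)))
      stop("label grid shape differs from reference volume")
    spacing <- reference$spacing
    origin <- reference$origin
  }
  if (is.null(spacing)) stop("spacing required when no reference is given")
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  structure(list(labels = labels, spacing = spacing,
                 origin = as.numeric(origin)), class = "sq_labels")
}

#' @export
print.sq_labels <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<sq_labels> %dx%dx%d, spacing %.3gx%.3gx%.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  counts <- tabulate(x$labels + 1L, nbins = 5L)
  for (g in seq_along(GLAND_CODES))
    cat(sprintf("  %s: %d voxels (%.2f mL)\n", names(GLAND_CODES)[g],
                counts[g + 1L], counts[g + 1L] * prod(x$spacing) / 1000))
  invisible(x)
}

# voxel volume in mm^3
vox_mm3 <- function(x) prod(x$spacing)

grid_dim <- function(x) if (inherits(x, "sq_labels")) dim(x$labels) else dim(x$voxels)

same_grid <- function(a, b, tol = 1e-6) {
  identical(grid_dim(a), grid_dim(b)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Read a volume or label map from NIfTI
#'
#' Reads a NIfTI-1 file into the package's canonical representation, taking
#' voxel spacing and origin from the header. For SPECT a calibration factor
#' (Bq/mL per stored unit) converts stored values to activity concentration;
#' absolute scanner calibration is out of scope, so the default factor is 1.
#'
#' @param path file path to a `.nii`/`.nii.gz` file.
#' @param modality `"CT"`, `"SPECT"`, or `"labels"`.
#' @param calibration Bq/mL per stored unit (SPECT only), default 1.
#' @param time_min acquisition time (min post injection) to attach.
#' @return An `sq_volume` (CT/SPECT) or `sq_labels` (labels).
#' @export
read_volume <- function(path, modality = c("CT", "SPECT", "labels"),
                        calibration = 1.0, time_min = NA_real_) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img), dim = dim(img))
  if (length(dim(vox)) != 3L) stop("expected a 3D volume in ", path)
  pix <- attr(img, "pixdim")
  if (is.null(pix) || length(pix) < 3L) stop("geometry fields absent in header")
  spacing <- abs(as.numeric(pix[1:3]))
  if (any(spacing <= 0)) stop("non-positive voxel spacing in header")
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  if (modality == "labels")
    return(sq_labels(round(vox), spacing = spacing, origin = origin))
  if (modality == "SPECT") {
    if (!is.numeric(calibration) || length(calibration) != 1L || calibration <= 0)
      stop("SPECT calibration factor must be a positive scalar")
    if (min(vox) < 0)
      stop("calibration error: stored values are negative; not a calibratable SPECT volume")
    vox <- vox * calibration
  }
  sq_volume(vox, spacing = spacing, origin = origin, modality = modality,
            time_min = time_min)
}

#' Write a volume or label map to NIfTI
#'
#' @param vol an `sq_volume` or `sq_labels`.
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ",
                                       dirname(path))
  is_lab <- inherits(vol, "sq_labels")
  if (!is_lab && !inherits(vol, "sq_volume"))
    stop("vol must be an sq_volume or sq_labels")
  dat <- if (is_lab) vol$labels else vol$voxels
  if (anyNA(dat) || any(!is.finite(dat))) stop("volume contains NA/NaN/Inf")
  img <- RNifti::asNifti(dat)
  sp <- vol$spacing
  RNifti::pixdim(img) <- sp
  xf <- diag(c(sp, 1))
  xf[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path, datatype = if (is_lab) "int16" else "double")
  invisible(path)
}

#' Resample a volume onto the grid of a reference volume
#'
#' Pulls `src` onto `ref`'s grid through world coordinates (axis-aligned
#' grids; rigid motion is handled by [apply_alignment()]). Out-of-field
#' voxels are set to 0. With linear interpolation of a smooth field, total
#' activity (value x voxel volume) is conserved to within ~1%.
#'
#' @param src `sq_volume` or `sq_labels` to resample.
#' @param ref `sq_volume` defining the output grid.
#' @param interp `"linear"` or `"nearest"`; label maps always use nearest.
#' @return Same kind of object as `src`, on `ref`'s grid.
#' @export
resample_to_grid <- function(src, ref, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(inherits(ref, "sq_volume"))
  is_lab <- inherits(src, "sq_labels")
  if (is_lab) interp <- "nearest"
  dat <- if (is_lab) src$labels else src$voxels
  # out voxel index (0-based) -> world -> src voxel index (0-based)
  M <- matrix(0, 3, 4)
  for (a in 1:3) {
    M[a, a] <- ref$spacing[a] / src$spacing[a]
    M[a, 4] <- (ref$origin[a] - src$origin[a]) / src$spacing[a]
  }
  out <- resample_affine_cpp(as.numeric(dat), dim(dat), dim(ref$voxels), M,
                             if (interp == "nearest") 0L else 1L, 0)
  dim(out) <- dim(ref$voxels)
  if (is_lab)
    sq_labels(round(out), spacing = ref$spacing, origin = ref$origin)
  else
    sq_volume(out, spacing = ref$spacing, origin = ref$origin,
              modality = src$modality, units = src$units,
              time_min = src$time_min)
}
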