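# Volume and mask I/O: NIfTI / DICOM-series reading, mask binarization and
# geometric alignment checks, and the cohort manifest.
#
# Internal array convention: voxels are indexed (slice, row, col); the axial
# axis is always the first. Spacing is (dz, dy, dx) in mm. NIfTI stores the
# fastest-varying axis first, so arrays are permuted on read/write.

#' Construct a CT volume
#'
#' A `ct_volume` is a 3D intensity grid (Hounsfield units, or phantom
#' intensity units) with physical voxel spacing. Arrays are indexed
#' `(slice, row, col)` with the axial axis first.
#'
#' @param voxels 3D numeric array indexed `(slice, row, col)`.
#' @param spacing numeric length-3 `(dz, dy, dx)` in mm, all positive.
#' @param sample_id sample identifier string.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, sample_id = "") {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive values (dz, dy, dx) in mm")
  if (dim(voxels)[1] < 1L)
    stop("volume must contain at least one slice")
  structure(
    list(voxels = voxels, spacing = spacing, slice_axis = 1L,
         sample_id = as.character(sample_id)),
    class = "ct_volume")
}

#' Construct a segmentation mask
#'
#' Binary 3D grid aligned to a [ct_volume()]. Values are coerced to 0/1.
#'
#' @param voxels 3D array; any value `> 0` becomes foreground.
#' @param spacing numeric length-3 `(dz, dy, dx)` in mm.
#' @param sample_id sample identifier string.
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(voxels, spacing, sample_id = "") {
  if (length(dim(voxels)) != 3L)
    stop("mask voxels must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive values (dz, dy, dx) in mm")
  vox <- array(as.integer(voxels > 0), dim(voxels))
  structure(
    list(voxels = vox, spacing = spacing, sample_id = as.character(sample_id)),
    class = "seg_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume '%s': %d x %d x %d (slice,row,col), spacing %s mm\n",
              x$sample_id, d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x ")))
  invisible(x)
}

#' @export
print.seg_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("seg_mask '%s': %d x %d x %d, %d foreground voxels\n",
              x$sample_id, d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

#' Read a CT volume from disk
#'
#' Reads a NIfTI file (`.nii` / `.nii.gz`) or a directory holding an
#' uncompressed single-frame DICOM series. Spacing is taken from file
#' metadata; for DICOM, the rescale slope/intercept is applied so that
#' intensities are in Hounsfield units, and the slice spacing is derived
#' from the slice positions (which must be uniform).
#'
#' @param path file (NIfTI) or directory (DICOM series).
#' @param format `"nifti"` or `"dicom_series"`; default guesses from `path`.
#' @param sample_id identifier attached to the returned volume.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom_series"),
                        sample_id = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_series" else "nifti"
  if (format == "nifti") {
    if (!file.exists(path)) stop("volume file not found: ", path)
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
      arr <- arr[, , , 1, drop = TRUE]
    if (length(dim(arr)) != 3L)
      stop("expected a 3D image, got ", length(dim(arr)), "D: ", path)
    pd <- RNifti::pixdim(img)[1:3]          # (dx, dy, dz)
    vox <- aperm(arr, c(3, 2, 1))           # -> (slice, row, col)
    ct_volume(vox, spacing = rev(pd),
              sample_id = sample_id %||% sub("\\.nii(\\.gz)?$", "",
                                             basename(path)))
  } else {
    read_dicom_series(path, sample_id = sample_id)
  }
}

#' Write a CT volume or mask to a NIfTI file
#'
#' Integer-valued data are stored as `int16` (masks as `uint8`) so that a
#' write/read round trip is bit-exact; doubles are stored as `float64`.
#'
#' @param x a [ct_volume()] or [seg_mask()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "ct_volume") || inherits(x, "seg_mask"))
  arr <- aperm(x$voxels, c(3, 2, 1))        # back to (x, y, z)
  datatype <- if (inherits(x, "seg_mask")) {
    "uint8"
  } else if (is.integer(x$voxels) ||
             all(x$voxels == round(x$voxels) & abs(x$voxels) < 32767)) {
    storage.mode(arr) <- "integer"
    "int16"
  } else "double"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(x$spacing)     # (dx, dy, dz)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a segmentation mask aligned to a reference volume
#'
#' The mask grid must match the reference shape, and its stored spacing must
#' agree with the reference within `tol` mm (the reference spacing is then
#' used). Values are binarized: anything `> 0` becomes 1.
#'
#' @param path NIfTI mask file.
#' @param reference the paired [ct_volume()].
#' @param tol spacing agreement tolerance in mm (default `1e-3`).
#' @return A [seg_mask()].
#' @export
read_mask <- function(path, reference, tol = 1e-3) {
  stopifnot(inherits(reference, "ct_volume"))
  if (!file.exists(path)) stop("mask file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L) stop("mask must be a 3D image: ", path)
  vox <- aperm(arr, c(3, 2, 1))
  if (!identical(dim(vox), dim(reference$voxels)))
    stop(sprintf("mask shape (%s) does not match volume shape (%s)",
                 paste(dim(vox), collapse = ","),
                 paste(dim(reference$voxels), collapse = ",")))
  sp <- rev(RNifti::pixdim(img)[1:3])
  if (any(abs(sp - reference$spacing) > tol))
    stop(sprintf("mask spacing (%s) disagrees with volume spacing (%s) beyond %g mm",
                 paste(signif(sp, 6), collapse = ","),
                 paste(signif(reference$spacing, 6), collapse = ","), tol))
  seg_mask(vox, spacing = reference$spacing, sample_id = reference$sample_id)
}

#' Load a cohort manifest
#'
#' Reads a CSV with columns `sample_id, site, label, ais_grade, volume_path,
#' mask_path` into one record per row. Healthy samples must carry AIS grade
#' 0 and lacerated samples a grade in 2..5 (one scan per patient: duplicate
#' sample IDs are rejected).
#'
#' @param path CSV manifest path.
#' @return A `data.frame` with one `SampleRecord` per row.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sample_id = "character"))
  required <- c("sample_id", "site", "label", "ais_grade",
                "volume_path", "mask_path")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("manifest is empty")
    return(df[, required])
  }
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicate sample_id (one scan per patient): ",
         paste(unique(dup), collapse = ", "))
  bad_label <- setdiff(unique(df$label), c("healthy", "lacerated"))
  if (length(bad_label))
    stop("unknown label values: ", paste(bad_label, collapse = ", "))
  df$ais_grade <- as.integer(df$ais_grade)
  inconsistent <- (df$label == "healthy" & df$ais_grade != 0L) |
    (df$label == "lacerated" & !(df$ais_grade %in% 2:5))
  if (any(inconsistent))
    stop("label/ais_grade inconsistency for: ",
         paste(df$sample_id[inconsistent], collapse = ", "))
  bad_site <- setdiff(unique(df$site), c("site_A", "site_B"))
  if (length(bad_site))
    stop("unknown site values: ", paste(bad_site, collapse = ", "))
  df[, required]
}

#' Write a cohort manifest
#' @param records manifest `data.frame` as from [load_manifest()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
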