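# Minimal DICOM series reader.
#
# Supports uncompressed single-frame CT images in the little-endian transfer
# syntaxes (implicit VR 1.2.840.10008.1.2 and explicit VR 1.2.840.10008.1.2.1).
# Only the handful of tags the pipeline needs are interpreted; everything
# else is skipped by length. Encapsulated (compressed) pixel data and
# undefined-length sequences are rejected.

DICOM_TAGS <- list(
  instance_number   = c(0x0020L, 0x0013L),
  image_position    = c(0x0020L, 0x0032L),
  rows              = c(0x0028L, 0x0010L),
  cols              = c(0x0028L, 0x0011L),
  pixel_spacing     = c(0x0028L, 0x0030L),
  slice_thickness   = c(0x0018L, 0x0050L),
  bits_allocated    = c(0x0028L, 0x0100L),
  pixel_rep         = c(0x0028L, 0x0103L),
  rescale_intercept = c(0x0028L, 0x1052L),
  rescale_slope     = c(0x0028L, 0x1053L),
  pixel_data        = c(0x7FE0L, 0x0010L)
)

dcm_uint16 <- function(raw, at) {
  as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
}

dcm_uint32 <- function(raw, at) {
  sum(as.numeric(raw[at + 0:3]) * c(1, 256, 65536, 16777216))
}

# Parse one DICOM file; returns the tags above plus raw pixel data.
read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  out <- list()
  explicit <- TRUE          # file meta group is always explicit LE
  transfer_syntax <- NULL
  while (pos + 7L <= length(raw)) {
    group <- dcm_uint16(raw, pos)
    element <- dcm_uint16(raw, pos + 2L)
    pos <- pos + 4L
    # After the meta group, switch VR mode per the transfer syntax.
    if (group != 2L && !is.null(transfer_syntax)) {
      explicit <- transfer_syntax != "1.2.840.10008.1.2"
      if (!(transfer_syntax %in%
            c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1")))
        stop("unsupported DICOM transfer syntax: ", transfer_syntax)
      transfer_syntax <- NULL
    }
    if (explicit || group == 2L) {
      vr <- rawToChar(raw[pos + 0:1])
      if (vr %in% long_vrs) {
        len <- dcm_uint32(raw, pos + 4L)
        pos <- pos + 8L
      } else {
        len <- dcm_uint16(raw, pos + 2L)
        pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- dcm_uint32(raw, pos)
      pos <- pos + 4L
    }
    if (len == 4294967295)
      stop("undefined-length DICOM element (encapsulated data?) unsupported")
    value <- raw[seq.int(pos, length.out = len)]
    pos <- pos + len
    if (group == 2L && element == 0x0010L)
      transfer_syntax <- sub("\\x00$", "", rawToChar(value))
    for (nm in names(DICOM_TAGS)) {
      tg <- DICOM_TAGS[[nm]]
      if (group == tg[1] && element == tg[2]) {
        out[[nm]] <- if (nm == "pixel_data") {
          value
        } else if (nm %in% c("rows", "cols", "bits_allocated", "pixel_rep")) {
          dcm_uint16(value, 1L)                      # US
        } else {
          # DS / IS string values, possibly backslash-separated
          as.numeric(strsplit(trimws(rawToChar(value)), "\\\\")[[1]])
        }
      }
    }
    if (group == 0x7FE0L && element == 0x0010L) break
  }
  needed <- c("rows", "cols", "pixel_spacing", "bits_allocated", "pixel_data")
  miss <- needed[!needed %in% names(out)]
  if (length(miss))
    stop("DICOM file missing required elements (", paste(miss, collapse = ", "),
         "): ", path)
  out
}

# Read a directory of DICOM slices into a ct_volume.
read_dicom_series <- function(dir, sample_id = NULL, tol = 1e-3) {
  if (!dir.exists(dir)) stop("DICOM directory not found: ", dir)
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no files in DICOM directory: ", dir)
  slices <- lapply(files, read_dicom_file)

  rows <- unique(vapply(slices, `[[`, 0L, "rows"))
  cols <- unique(vapply(slices, `[[`, 0L, "cols"))
  psp <- unique(do.call(rbind, lapply(slices, `[[`, "pixel_spacing")))
  if (length(rows) != 1L || length(cols) != 1L || nrow(psp) != 1L)
    stop("DICOM series slices disagree on shape or pixel spacing")

  z <- vapply(slices, function(s) {
    if (!is.null(s$image_position)) s$image_position[3]
    else if (!is.null(s$instance_number)) as.numeric(s$instance_number)
    else NA_real_
  }, 0)
  if (anyNA(z)) stop("DICOM slices lack position/instance ordering")
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]
  if (length(z) > 1L) {
    dz <- diff(z)
    if (any(abs(dz - dz[1]) > tol))
      stop("inconsistent DICOM slice spacing (missing or duplicated slice?)")
    dz <- abs(dz[1])
  } else {
    dz <- slices[[1]]$slice_thickness %||% 1
  }

  vox <- array(0, c(length(slices), rows, cols))
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    if (s$bits_allocated != 16L)
      stop("only 16-bit DICOM pixel data supported")
    signed <- isTRUE((s$pixel_rep %||% 1L) == 1L)
    px <- readBin(s$pixel_data, "integer", n = rows * cols, size = 2L,
                  signed = signed, endian = "little")
    slope <- (s$rescale_slope %||% 1)[1]
    intercept <- (s$rescale_intercept %||% 0)[1]
    # DICOM pixel data is row-major (within a row, columns vary fastest)
    vox[i, , ] <- matrix(px * slope + intercept, nrow = rows, ncol = cols,
                         byrow = TRUE)
  }
  ct_volume(vox, spacing = c(dz, psp[1, 1], psp[1, 2]),
            sample_id = sample_id %||% basename(dir))
}
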