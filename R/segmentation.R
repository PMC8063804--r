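# Segmentation quality control and scoring.
#
# Masks with a segmented volume below a threshold (default 80 cm^3; a
# plausible spleen cannot be that small, so such masks are treated as
# segmentation failures) are filtered out before feature extraction.
# An optional region-based active-contour stage can refine a seed mask;
# precomputed masks are the primary input path.

#' Segmented volume of a mask in cubic centimetres
#'
#' @param mask a [seg_mask()].
#' @return Foreground voxel count times the voxel volume, in cm^3.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  sum(mask$voxels) * prod(mask$spacing) / 1000
}

#' Quality-control filter on segmented spleen volume
#'
#' Excludes records whose mask volume falls below `threshold_cm3`
#' (segmentation failures). Every sample receives a QC row; records without
#' a mask fail with reason `"no_mask"`.
#'
#' @param records manifest `data.frame` (see [load_manifest()]).
#' @param masks named list of [seg_mask()] keyed by `sample_id`, or `NULL`
#'   to load each record's `mask_path` (with its `volume_path` as reference).
#' @param threshold_cm3 minimum acceptable volume; default 80.
#' @return `list(kept = <records subset>, qc = <data.frame>)` where `qc` has
#'   columns `sample_id, volume_cm3, passed, reason`.
#' @export
qc_filter <- function(records, masks = NULL, threshold_cm3 = 80) {
  qc <- data.frame(sample_id = records$sample_id,
                   volume_cm3 = NA_real_,
                   passed = FALSE,
                   reason = "",
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(records))) {
    m <- if (!is.null(masks)) {
      masks[[records$sample_id[i]]]
    } else if (file.exists(records$mask_path[i])) {
      vol <- read_volume(records$volume_path[i],
                         sample_id = records$sample_id[i])
      read_mask(records$mask_path[i], vol)
    } else NULL
    if (is.null(m)) {
      qc$reason[i] <- "no_mask"
      next
    }
    v <- mask_volume(m)
    qc$volume_cm3[i] <- v
    if (v >= threshold_cm3) {
      qc$passed[i] <- TRUE
      qc$reason[i] <- "ok"
    } else {
      qc$reason[i] <- sprintf("volume %.1f cm3 below threshold %.1f cm3",
                              v, threshold_cm3)
    }
  }
  list(kept = records[qc$passed, , drop = FALSE], qc = qc)
}

#' Dice similarity between two masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b [seg_mask()] objects of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "seg_mask"), inherits(b, "seg_mask"))
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("mask shapes differ")
  na <- sum(a$voxels)
  nb <- sum(b$voxels)
  if (na + nb == 0L) {
    message("dice: both masks empty; returning 1 by convention")
    return(1)
  }
  2 * sum(a$voxels == 1L & b$voxels == 1L) / (na + nb)
}

#' Refine a seed mask by region-based contour evolution
#'
#' A morphological Chan--Vese-style evolution: at each iteration, boundary
#' voxels are added to (or removed from) the region according to whether
#' their intensity is closer to the current interior or exterior mean.
#' Every `reinit_every` iterations the contour is reinitialized: a
#' morphological open/close smooths the surface, the region statistics are
#' recomputed from scratch, and the mask is reduced to the single connected
#' component containing the seed.
#'
#' @param volume a [ct_volume()].
#' @param seed nonempty [seg_mask()] inside the volume.
#' @param iterations number of evolution steps (0 returns the seed).
#' @param reinit_every reinitialization period in iterations.
#' @param max_fraction divergence guard: error if the mask exceeds this
#'   fraction of the image (default 0.5).
#' @param denoise apply a 3x3 in-plane median filter before evolving.
#' @param normalize linearly rescale intensities to `[0, 1]` first.
#' @return A refined [seg_mask()] (single connected component).
#' @export
refine_mask <- function(volume, seed, iterations = 10L, reinit_every = 5L,
                        max_fraction = 0.5, denoise = FALSE,
                        normalize = TRUE) {
  stopifnot(inherits(volume, "ct_volume"), inherits(seed, "seg_mask"))
  if (sum(seed$voxels) == 0L) stop("seed mask is empty")
  if (!identical(dim(seed$voxels), dim(volume$voxels)))
    stop("seed shape does not match volume")
  img <- volume$voxels
  if (denoise) {
    for (i in seq_len(dim(img)[1]))
      img[i, , ] <- median_filter3x3(img[i, , ])
  }
  if (normalize) {
    rng <- range(img)
    if (diff(rng) > 0) img <- (img - rng[1]) / diff(rng)
  }
  mask <- seed$voxels == 1L
  if (iterations == 0L)
    return(seg_mask(array(as.integer(mask), dim(mask)), seed$spacing,
                    seed$sample_id))
  mu_in <- mean(img[mask])
  mu_out <- outside_mean(img, mask)
  for (it in seq_len(iterations)) {
    grown <- dilate6(mask)
    cand_add <- grown & !mask
    add <- cand_add & (abs(img - mu_in) < abs(img - mu_out))
    inner <- mask & !erode6(mask)
    drop <- inner & (abs(img - mu_out) < abs(img - mu_in))
    mask <- (mask | add) & !drop
    if (mean(mask) > max_fraction)
      stop(sprintf(
        "refine_mask diverged: region covers %.0f%% of the image (limit %.0f%%)",
        100 * mean(mask), 100 * max_fraction))
    if (it %% reinit_every == 0L || it == iterations) {
      mask <- dilate6(erode6(mask))        # open
      mask <- erode6(dilate6(mask))        # close
      mask <- component_containing(mask, seed$voxels == 1L)
      mu_in <- mean(img[mask])
      mu_out <- outside_mean(img, mask)
    }
  }
  seg_mask(array(as.integer(mask), dim(mask)), seed$spacing, seed$sample_id)
}

# Mean intensity in a 5-voxel-wide shell outside the mask (falls back to the
# global exterior when the shell is empty).
outside_mean <- function(img, mask) {
  shell <- mask
  for (i in 1:5) shell <- dilate6(shell)
  shell <- shell & !mask
  if (!any(shell)) shell <- !mask
  mean(img[shell])
}

# Connected component (6-connectivity) of `mask` overlapping `seed`.
component_containing <- function(mask, seed) {
  comp <- seed & mask
  if (!any(comp)) comp <- mask & dilate6(seed)
  if (!any(comp)) return(mask)
  repeat {
    grown <- dilate6(comp) & mask
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  comp
}

# 3x3 median filter on a matrix (replicated edges).
median_filter3x3 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  pad <- m[c(1, 1:n1, n1), c(1, 1:n2, n2)]
  stack <- vapply(1:9, function(k) {
    i <- (k - 1) %/% 3; j <- (k - 1) %% 3
    as.vector(pad[i + 1:n1, j + 1:n2])
  }, numeric(n1 * n2))
  matrix(apply(stack, 1, stats::median), n1, n2)
}
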