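# Per-sample feature extraction: run every extractor over each usable mask
# slice, aggregate per-slice values across slices (mean, SD, max by
# default), and assemble a cohort feature table.

#' Feature extraction configuration
#'
#' @param histogram a [histogram_config()], or `NULL` to disable the block.
#' @param gabor a [gabor_config()], or `NULL` to disable.
#' @param fractal `list(r_max =)` (default 512), or `NULL` to disable.
#' @param shape `list()` to enable shape features (default), `NULL` disables.
#' @param aggregators subset of `c("mean", "sd", "max")` applied across
#'   slices; default all three.
#' @param min_pixels minimum foreground pixels for a slice to be used
#'   (default 32; smaller slices near the organ poles give degenerate
#'   shape/fractal estimates).
#' @param gabor_normalize divide Gabor sums by masked-pixel count
#'   (default `TRUE`).
#' @return A `feature_config` list.
#' @export
feature_config <- function(histogram = histogram_config(),
                           gabor = gabor_config(),
                           fractal = list(r_max = 512L),
                           shape = list(),
                           aggregators = c("mean", "sd", "max"),
                           min_pixels = 32L,
                           gabor_normalize = TRUE) {
  aggregators <- match.arg(aggregators, c("mean", "sd", "max"),
                           several.ok = TRUE)
  structure(list(histogram = histogram, gabor = gabor, fractal = fractal,
                 shape = shape, aggregators = aggregators,
                 min_pixels = as.integer(min_pixels),
                 gabor_normalize = isTRUE(gabor_normalize)),
            class = "feature_config")
}

# Per-slice feature vector (named), given precomputed bank.
slice_features <- function(img, msk, config, bank) {
  out <- numeric(0)
  if (!is.null(config$histogram)) {
    h <- histogram_features(img[msk > 0], config$histogram)
    out <- c(out, hist_mean = h$mean, hist_variance = h$variance,
             hist_skewness = h$skewness, hist_kurtosis = h$kurtosis,
             hist_renyi = h$renyi_entropy)
  }
  if (!is.null(config$fractal)) {
    f <- slice_fractal(msk, r_max = config$fractal$r_max %||% 512L)
    out <- c(out, frac_df_perimeter = f$df_perimeter,
             frac_df_area = f$df_area, frac_fit_r2 = f$fit_r2)
  }
  if (!is.null(config$gabor)) {
    g <- gabor_features(img, msk, bank, normalize = config$gabor_normalize)
    en <- g$local_energy
    am <- g$mean_amplitude
    names(en) <- paste0("gabor_energy_", names(en))
    names(am) <- paste0("gabor_amp_", names(am))
    out <- c(out, en, am)
  }
  if (!is.null(config$shape)) {
    s <- shape_features(msk)
    out <- c(out, shape_circularity = s$circularity,
             shape_eccentricity = s$eccentricity,
             shape_orientation = s$orientation_deg,
             shape_convex_area_diff = s$convex_area_diff)
  }
  out
}

#' Extract the per-sample feature vector
#'
#' Features are computed on every axial slice whose mask has at least
#' `min_pixels` foreground pixels, then aggregated across slices by the
#' configured aggregators (SD is 0 when only one slice is usable).
#' Extraction is a pure function of `(volume, mask, config)`.
#'
#' @param volume a [ct_volume()].
#' @param mask the QC-passed [seg_mask()] paired with it.
#' @param config a [feature_config()].
#' @return Named numeric vector with deterministic ordering
#'   (`<feature>_<aggregator>`), with attribute `n_slices`.
#' @export
extract_sample <- function(volume, mask, config = feature_config()) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "seg_mask"))
  if (!identical(dim(volume$voxels), dim(mask$voxels)))
    stop("volume and mask shapes differ")
  counts <- apply(mask$voxels, 1, sum)
  usable <- which(counts >= config$min_pixels)
  if (!length(usable))
    stop("no usable mask slice (>= ", config$min_pixels,
         " foreground pixels) for sample ", volume$sample_id)
  bank <- if (!is.null(config$gabor)) build_gabor_bank(config$gabor) else NULL
  rows <- lapply(usable, function(i)
    slice_features(volume$voxels[i, , ], mask$voxels[i, , ], config, bank))
  mat <- do.call(rbind, rows)
  agg <- list(mean = function(v) mean(v),
              sd = function(v) if (length(v) > 1L) stats::sd(v) else 0,
              max = function(v) max(v))
  out <- numeric(0)
  for (j in seq_len(ncol(mat))) {
    for (a in config$aggregators) {
      val <- agg[[a]](mat[, j])
      names(val) <- paste0(colnames(mat)[j], "_", a)
      out <- c(out, val)
    }
  }
  if (any(!is.finite(out)))
    stop("non-finite feature values for sample ", volume$sample_id, ": ",
         paste(names(out)[!is.finite(out)], collapse = ", "))
  attr(out, "n_slices") <- length(usable)
  out
}

#' Build the cohort feature table
#'
#' Runs [extract_sample()] for every record, loading volumes and masks from
#' the manifest paths. Samples without a usable slice are collected in an
#' exclusion report (attribute `excluded`), never silently dropped.
#'
#' @param records QC-passed manifest `data.frame`.
#' @param config a [feature_config()].
#' @param verbose print one line per sample.
#' @return `data.frame` with columns
#'   `sample_id, site, label, ais_grade, <features...>`; attribute
#'   `excluded` lists failed sample IDs with reasons.
#' @export
build_feature_table <- function(records, config = feature_config(),
                                verbose = FALSE) {
  feats <- vector("list", nrow(records))
  excluded <- data.frame(sample_id = character(0), reason = character(0))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    res <- tryCatch({
      vol <- read_volume(rec$volume_path, sample_id = rec$sample_id)
      msk <- read_mask(rec$mask_path, vol)
      extract_sample(vol, msk, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded <- rbind(excluded, data.frame(sample_id = rec$sample_id,
                                             reason = conditionMessage(res)))
    } else {
      feats[[i]] <- res
    }
    if (verbose)
      message(sprintf("[%d/%d] %s %s", i, nrow(records), rec$sample_id,
                      if (inherits(res, "error")) "EXCLUDED" else "ok"))
  }
  ok <- !vapply(feats, is.null, TRUE)
  fmat <- do.call(rbind, feats[ok])
  tab <- cbind(records[ok, c("sample_id", "site", "label", "ais_grade")],
               as.data.frame(fmat))
  rownames(tab) <- NULL
  attr(tab, "excluded") <- excluded
  tab
}

#' Names of the feature columns of a feature table
#' @param table feature table from [build_feature_table()].
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("sample_id", "site", "label", "ais_grade"))
}

#' Write / read a feature table as CSV
#'
#' @param table feature table.
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(sample_id = "character"))
}
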