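# Synthetic CT-like phantom cohorts: smooth superellipsoidal healthy
# spleens versus jagged / notched lacerated spleens with graded severity,
# two acquisition "sites" with a mild distribution shift, and fractal
# fixtures of analytically known box-counting dimension.
#
# The generator is a pure function of (config, seed): identical inputs give
# bit-identical volumes, masks and manifests.

#' Phantom cohort configuration
#'
#' Defaults mirror the study conditions the pipeline targets: 54 healthy and
#' 45 lacerated samples with AIS grade counts 15/16/10/4 (grades 2/3/4/5),
#' axial stacks of 5 mm slices, and two sites where `site_B` carries a mild
#' intensity offset and noise inflation.
#'
#' @param n_healthy,n_lacerated cohort class counts (defaults 54 / 45).
#' @param grade_counts named counts for AIS grades `"2".."5"`; must sum to
#'   `n_lacerated`.
#' @param image_shape `(slices, rows, cols)`; default `c(64, 256, 256)`
#'   (512 x 512 in-plane is available but 256 keeps full-cohort runs fast;
#'   Gabor wavelengths and box sizes are expressed in pixels and scale with
#'   the grid).
#' @param spacing `(dz, dy, dx)` in mm; default `c(5, 0.8, 0.8)`.
#' @param seed master seed; every sample derives its own stream from it.
#' @param volume_range_cm3 physiologic spleen volume band sampled per
#'   phantom (default `c(160, 320)`).
#' @param parenchyma_mean,parenchyma_sd sample-level parenchyma intensity
#'   draw, HU-equivalents (default 100 +- 15).
#' @param noise_sd voxel Gaussian noise SD (default 12 HU).
#' @param healthy_undulation relative amplitude of the smooth low-frequency
#'   boundary undulation every spleen carries (default 0.02).
#' @param severity per-grade laceration parameters: for each grade a list
#'   `roughness_amp` (relative amplitude of the band-limited boundary jag),
#'   `n_notches`, `notch_depth` (fraction of local radius), `notch_width`
#'   (radians), `track_width_mm` (hypodense track width). Strictly monotone
#'   in grade.
#' @param site_shift `list(intensity_offset =, noise_factor =)` applied to
#'   `site_B` (defaults +10 HU and x1.2).
#' @param site_a_fraction probability a sample is assigned to `site_A`.
#' @param n_undersized number of deliberately undersized (QC-failing,
#'   ~40-60 cm^3) masks injected into the healthy stratum (default 0).
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_healthy = 54L, n_lacerated = 45L,
                           grade_counts = c("2" = 15L, "3" = 16L,
                                            "4" = 10L, "5" = 4L),
                           image_shape = c(64L, 256L, 256L),
                           spacing = c(5, 0.8, 0.8),
                           seed = 1L,
                           volume_range_cm3 = c(160, 320),
                           parenchyma_mean = 100, parenchyma_sd = 15,
                           noise_sd = 12,
                           healthy_undulation = 0.02,
                           severity = default_severity(),
                           site_shift = list(intensity_offset = 10,
                                             noise_factor = 1.2),
                           site_a_fraction = 0.55,
                           n_undersized = 0L) {
  if (!all(names(grade_counts) %in% c("2", "3", "4", "5")))
    stop("grade_counts keys must be in 2..5")
  if (any(grade_counts < 0)) stop("grade counts must be >= 0")
  if (sum(grade_counts) != n_lacerated)
    stop("grade_counts must sum to n_lacerated")
  depth <- vapply(severity, `[[`, 0, "notch_depth")
  amp <- vapply(severity, `[[`, 0, "roughness_amp")
  if (any(diff(depth[order(as.integer(names(severity)))]) <= 0) ||
      any(diff(amp[order(as.integer(names(severity)))]) <= 0))
    stop("severity parameters must be strictly monotone in grade")
  structure(list(n_healthy = as.integer(n_healthy),
                 n_lacerated = as.integer(n_lacerated),
                 grade_counts = grade_counts,
                 image_shape = as.integer(image_shape), spacing = spacing,
                 seed = as.integer(seed),
                 volume_range_cm3 = volume_range_cm3,
                 parenchyma_mean = parenchyma_mean,
                 parenchyma_sd = parenchyma_sd,
                 noise_sd = noise_sd,
                 healthy_undulation = healthy_undulation,
                 severity = severity, site_shift = site_shift,
                 site_a_fraction = site_a_fraction,
                 n_undersized = as.integer(n_undersized)),
            class = "phantom_config")
}

#' Default laceration severity mapping
#'
#' Boundary roughness, notch geometry and hypodense-track width per AIS
#' grade; strictly monotone so that higher grades always show rougher,
#' deeper contour disruption.
#' @return Named list over grades `"2".."5"`.
#' @export
default_severity <- function() {
  list("2" = list(roughness_amp = 0.035, n_notches = 1L, notch_depth = 0.12,
                  notch_width = 0.30, track_width_mm = 2),
       "3" = list(roughness_amp = 0.07, n_notches = 2L, notch_depth = 0.18,
                  notch_width = 0.40, track_width_mm = 3),
       "4" = list(roughness_amp = 0.12, n_notches = 2L, notch_depth = 0.28,
                  notch_width = 0.50, track_width_mm = 4),
       "5" = list(roughness_amp = 0.20, n_notches = 3L, notch_depth = 0.38,
                  notch_width = 0.60, track_width_mm = 6))
}

# Shared geometry/texture draw for one phantom. Returns everything needed
# to rasterize, so healthy and lacerated phantoms with the same seed share
# their base anatomy.
draw_anatomy <- function(config, undersized = FALSE) {
  vol_band <- if (undersized) c(40, 60) else config$volume_range_cm3
  V <- stats::runif(1, vol_band[1], vol_band[2]) * 1000   # mm^3
  a <- stats::runif(1, 0.45, 0.58) * (3 * V / (4 * pi))^(1 / 3) * 1.55
  bc <- 3 * V / (4 * pi * a)
  q <- stats::runif(1, 1.15, 1.45)
  cc <- sqrt(bc / q)
  b <- q * cc
  shape <- config$image_shape
  list(V = V, a = a, b = b, c = cc,
       z0 = shape[1] / 2 + stats::runif(1, -3, 3),
       y0 = shape[2] / 2 + stats::runif(1, -10, 10),
       x0 = shape[3] / 2 + stats::runif(1, -10, 10),
       rot = stats::runif(1, 0, pi),
       und_amp = stats::rnorm(3, 0, config$healthy_undulation / 2),
       und_ph = stats::runif(3, 0, 2 * pi),
       parenchyma = stats::rnorm(1, config$parenchyma_mean,
                                 config$parenchyma_sd),
       blobs = lapply(1:3, function(i)
         list(y = stats::runif(1, 0.15, 0.85), x = stats::runif(1, 0.15, 0.85),
              r = stats::runif(1, 15, 40), int = stats::runif(1, -20, 180))))
}

# Rasterize one phantom. `lac` is NULL for healthy, otherwise the drawn
# laceration parameters.
rasterize_phantom <- function(config, anat, lac, site, sample_id) {
  shape <- config$image_shape
  sp <- config$spacing
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  X <- matrix((seq_len(nx) - anat$x0) * sp[3], ny, nx, byrow = TRUE)
  Y <- matrix((seq_len(ny) - anat$y0) * sp[2], ny, nx)
  phi <- atan2(Y, X) - anat$rot
  rr <- sqrt(X^2 + Y^2)
  # organ-level angular boundary profile (relative multiplier)
  u <- 1
  for (k in 1:3)
    u <- u + anat$und_amp[k] * cos((k + 1) * phi + anat$und_ph[k])
  if (!is.null(lac)) {
    for (k in seq_along(lac$rough_freq))
      u <- u + lac$rough_amp[k] * cos(lac$rough_freq[k] * phi + lac$rough_ph[k])
  }
  # base in-plane ellipse radius at angle phi (semi-axes c along x, b along y)
  R0 <- 1 / sqrt((cos(phi) / anat$c)^2 + (sin(phi) / anat$b)^2)

  noise_sd <- config$noise_sd *
    if (site == "site_B") config$site_shift$noise_factor else 1
  offset <- if (site == "site_B") config$site_shift$intensity_offset else 0

  vox <- array(0, c(nz, ny, nx))
  msk <- array(0L, c(nz, ny, nx))
  # background: fat-like base plus a few organ-like blobs
  bg <- matrix(-60, ny, nx)
  for (bl in anat$blobs) {
    d2 <- (X - (bl$x - 0.5) * nx * sp[3])^2 + (Y - (bl$y - 0.5) * ny * sp[2])^2
    bg[d2 < bl$r^2] <- bl$int
  }
  for (iz in seq_len(nz)) {
    frac <- 1 - ((iz - anat$z0) * sp[1] / anat$a)^2
    slice <- bg
    if (frac > 0) {
      rho <- sqrt(frac) * R0 * u
      if (!is.null(lac)) {
        zr <- (iz - anat$z0) * sp[1] / anat$a          # in [-1, 1]
        for (j in seq_len(nrow(lac$notches))) {
          nt <- lac$notches[j, ]
          if (zr >= nt[["z_lo"]] && zr <= nt[["z_hi"]]) {
            dphi <- ((phi - nt[["phi0"]] + pi) %% (2 * pi)) - pi
            tri <- pmax(0, 1 - abs(dphi) / nt[["width"]])
            rho <- rho * (1 - nt[["depth"]] * tri)
          }
        }
      }
      inside <- rr <= rho
      slice[inside] <- anat$parenchyma
      if (!is.null(lac)) {
        for (j in seq_len(nrow(lac$tracks))) {
          tk <- lac$tracks[j, ]
          in_track <- inside &
            abs(X * cos(tk[["psi"]]) + Y * sin(tk[["psi"]]) - tk[["off"]]) <
              tk[["width_mm"]] / 2
          slice[in_track] <- anat$parenchyma - lac$track_contrast
        }
      }
      msk[iz, , ] <- inside
    }
    vox[iz, , ] <- slice
  }
  if (noise_sd > 0)
    vox <- vox + stats::rnorm(length(vox), 0, noise_sd)
  vox <- round(vox + offset)
  list(volume = ct_volume(array(as.integer(vox), dim(vox)), sp, sample_id),
       mask = seg_mask(msk, sp, sample_id))
}

#' Generate a healthy spleen phantom
#'
#' Smooth ellipsoidal spleen with a low-amplitude boundary undulation and
#' homogeneous parenchyma over a structured background; the mask is the
#' generator's ground-truth region and its volume falls in the configured
#' physiologic band by construction.
#'
#' @param config a [phantom_config()].
#' @param sample_id identifier for the sample.
#' @param site `"site_A"` or `"site_B"`.
#' @param seed per-sample RNG seed.
#' @param undersized generate a deliberately small (QC-failing) organ.
#' @return `list(volume =, mask =, record =)`.
#' @export
generate_healthy <- function(config = phantom_config(), sample_id = "H001",
                             site = "site_A", seed = 1L,
                             undersized = FALSE) {
  check_fits(config)
  anat <- with_seed(seed, draw_anatomy(config, undersized))
  out <- with_seed(derive_seed(seed, 7L),
                   rasterize_phantom(config, anat, NULL, site, sample_id))
  out$record <- data.frame(sample_id = sample_id, site = site,
                           label = "healthy", ais_grade = 0L,
                           volume_path = "", mask_path = "",
                           stringsAsFactors = FALSE)
  out
}

#' Generate a lacerated spleen phantom
#'
#' A healthy phantom modified by (i) band-limited radial boundary
#' roughening, (ii) one to three wedge notches, and (iii) a hypodense
#' linear (branching at higher grades) track crossing the capsular
#' surface, all scaled by the grade's severity mapping. The mask follows
#' the disrupted contour and remains a single connected component.
#'
#' @inheritParams generate_healthy
#' @param grade AIS grade in `{2, 3, 4, 5}`.
#' @param severity_scale multiplier on the grade's severity (0 reproduces
#'   the healthy phantom exactly at the same seed).
#' @return `list(volume =, mask =, record =)`.
#' @export
generate_lacerated <- function(config = phantom_config(), grade,
                               sample_id = "L001", site = "site_A",
                               seed = 1L, severity_scale = 1) {
  if (!grade %in% 2:5) stop("grade must be in {2, 3, 4, 5}")
  check_fits(config)
  sev <- config$severity[[as.character(grade)]]
  # anatomy and noise use the same streams as the healthy phantom at this
  # seed, so severity_scale = 0 reproduces it exactly
  anat <- with_seed(seed, draw_anatomy(config, FALSE))
  lac <- with_seed(derive_seed(seed, 11L), draw_laceration(sev, severity_scale))
  out <- with_seed(derive_seed(seed, 7L),
                   rasterize_phantom(config, anat, lac, site, sample_id))
  out$record <- data.frame(sample_id = sample_id, site = site,
                           label = "lacerated", ais_grade = as.integer(grade),
                           volume_path = "", mask_path = "",
                           stringsAsFactors = FALSE)
  out
}

draw_laceration <- function(sev, scale) {
  n_rough <- 6L
  freqs <- sample(8:16, n_rough)
  amps <- abs(stats::rnorm(n_rough, 0, 1))
  amps <- amps / sqrt(sum(amps^2) / 2) * sev$roughness_amp * scale
  notches <- do.call(rbind, lapply(seq_len(sev$n_notches), function(i) {
    zc <- stats::runif(1, -0.3, 0.3)
    c(phi0 = stats::runif(1, 0, 2 * pi),
      width = sev$notch_width,
      depth = sev$notch_depth * scale,
      z_lo = zc - 0.45, z_hi = zc + 0.45)
  }))
  n_tracks <- if (sev$track_width_mm >= 4) 2L else 1L
  tracks <- do.call(rbind, lapply(seq_len(n_tracks), function(i) {
    c(psi = stats::runif(1, 0, pi),
      off = stats::runif(1, -10, 10),
      width_mm = sev$track_width_mm * scale)
  }))
  list(rough_freq = freqs, rough_amp = amps,
       rough_ph = stats::runif(n_rough, 0, 2 * pi),
       notches = notches, tracks = tracks,
       track_contrast = 60 * scale)
}

check_fits <- function(config) {
  shape <- config$image_shape
  sp <- config$spacing
  # largest in-plane semi-axis must fit with margin
  max_b <- 1.3 * (3 * max(config$volume_range_cm3) * 1000 /
                    (4 * pi * 40))^(1 / 2)
  if (max_b / min(sp[2], sp[3]) > min(shape[2], shape[3]) / 2 - 8)
    stop("image_shape too small to contain the organ")
  invisible(TRUE)
}

#' Generate a phantom cohort on disk
#'
#' Writes one NIfTI volume and mask per sample plus a `manifest.csv`
#' compatible with [load_manifest()]. Deterministic given the config seed.
#' When `n_undersized > 0`, that many healthy samples receive deliberately
#' undersized organs so the downstream [qc_filter()] has failures to catch.
#'
#' @param config a [phantom_config()].
#' @param out_dir output directory (created if needed).
#' @param overwrite allow writing into a directory that already holds a
#'   manifest (default `FALSE`: collision is an error).
#' @param verbose print progress.
#' @return The manifest `data.frame` (invisibly also written to
#'   `<out_dir>/manifest.csv`).
#' @export
generate_cohort <- function(config = phantom_config(), out_dir,
                            overwrite = FALSE, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite)
    stop("output collision: ", manifest_path, " already exists")
  plan <- cohort_plan(config)
  records <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    pl <- plan[i, ]
    smp <- if (pl$label == "healthy") {
      generate_healthy(config, pl$sample_id, pl$site, seed = pl$seed,
                       undersized = pl$undersized)
    } else {
      generate_lacerated(config, pl$ais_grade, pl$sample_id, pl$site,
                         seed = pl$seed)
    }
    vp <- file.path(out_dir, paste0(pl$sample_id, "_vol.nii.gz"))
    mp <- file.path(out_dir, paste0(pl$sample_id, "_mask.nii.gz"))
    write_volume(smp$volume, vp)
    write_volume(smp$mask, mp)
    rec <- smp$record
    rec$volume_path <- vp
    rec$mask_path <- mp
    records[[i]] <- rec
    if (verbose) message(sprintf("[%d/%d] %s", i, nrow(plan), pl$sample_id))
  }
  manifest <- do.call(rbind, records)
  write_manifest(manifest, manifest_path)
  invisible(manifest)
}

# Deterministic cohort layout: IDs, grades, sites, per-sample seeds.
cohort_plan <- function(config) {
  grades <- rep(as.integer(names(config$grade_counts)), config$grade_counts)
  n <- config$n_healthy + config$n_lacerated
  plan <- data.frame(
    sample_id = sprintf("SPL%03d", seq_len(n)),
    label = c(rep("healthy", config$n_healthy),
              rep("lacerated", config$n_lacerated)),
    ais_grade = c(rep(0L, config$n_healthy), grades),
    undersized = FALSE,
    stringsAsFactors = FALSE)
  if (config$n_undersized > 0) {
    if (config$n_undersized > config$n_healthy)
      stop("n_undersized exceeds n_healthy")
    plan$undersized[seq_len(config$n_undersized)] <- TRUE
  }
  plan$site <- with_seed(derive_seed(config$seed, 0L),
    ifelse(stats::runif(n) < config$site_a_fraction, "site_A", "site_B"))
  plan$seed <- vapply(seq_len(n), function(i) derive_seed(config$seed, i), 0L)
  plan
}

#' Binary fixtures with analytically known box-counting dimension
#'
#' * `line`: one full row of pixels (dimension 1);
#' * `filled_square`: all pixels set (dimension 2);
#' * `disk`: filled disk of radius `size/2 - 2` (area dimension 2,
#'   boundary dimension 1);
#' * `koch_curve`: the triadic Koch curve of order `log3(size)`
#'   (dimension `log(4)/log(3)`), rasterized from unit segments;
#' * `sierpinski_carpet`: order `log3(size)` carpet (dimension
#'   `log(8)/log(3)`), with `8^order` foreground pixels.
#'
#' @param kind fixture type.
#' @param size grid size; must be a power of 3 for `koch_curve` and
#'   `sierpinski_carpet`.
#' @return Binary matrix (0/1).
#' @export
fractal_fixture <- function(kind = c("line", "filled_square", "disk",
                                     "koch_curve", "sierpinski_carpet"),
                            size = 243L) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (kind %in% c("koch_curve", "sierpinski_carpet")) {
    ord <- round(log(size) / log(3))
    if (3^ord != size)
      stop(kind, " requires size to be a power of 3, got ", size)
  }
  switch(kind,
    line = {
      m <- matrix(0L, size, size)
      m[size %/% 2L, ] <- 1L
      m
    },
    filled_square = matrix(1L, size, size),
    disk = {
      r <- size / 2 - 2
      ctr <- (size + 1) / 2
      d2 <- outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, "+")
      matrix(as.integer(d2 <= r^2), size, size)
    },
    sierpinski_carpet = {
      ord <- round(log(size) / log(3))
      keep <- matrix(TRUE, size, size)
      idx <- seq_len(size) - 1L
      for (l in seq_len(ord) - 1L) {
        d <- (idx %/% 3L^l) %% 3L
        keep <- keep & !outer(d == 1L, d == 1L, "&")
      }
      matrix(as.integer(keep), size, size)
    },
    koch_curve = {
      ord <- round(log(size) / log(3))
      ang <- 0
      for (i in seq_len(ord))
        ang <- as.vector(vapply(ang, function(a) c(a, a + 60, a - 60, a),
                                numeric(4)))
      th <- ang * pi / 180
      xs <- cumsum(c(0, cos(th)))
      ys <- cumsum(c(0, sin(th)))
      nr <- max(3L, ceiling(max(ys)) - floor(min(ys)) + 3L)
      m <- matrix(0L, nr, size)
      col <- pmin(size, pmax(1L, round(xs) + 1L))
      row <- pmin(nr, pmax(1L, nr - 1L - round(ys - min(ys))))
      m[cbind(row, col)] <- 1L
      m
    })
}
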