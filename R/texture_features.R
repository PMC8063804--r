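# Texture features of the masked spleen region, per axial slice:
# histogram statistics (mean, variance, skewness, kurtosis, Renyi entropy)
# and Gabor filter-bank responses (local energy, mean amplitude).

#' Histogram feature configuration
#'
#' @param n_bins number of histogram bins (>= 2); default 64.
#' @param intensity_range `(lo, hi)` in HU for a fixed abdominal window
#'   (default `c(-150, 250)`), or `NULL` to use each sample's min/max.
#'   Values outside the window are clamped into the edge bins.
#' @param renyi_alpha Renyi order `alpha > 0`, `alpha != 1`; default 2
#'   (collision entropy). `alpha = 1` is accepted and computed as the
#'   Shannon limit.
#' @return A `histogram_config` list.
#' @export
histogram_config <- function(n_bins = 64L, intensity_range = c(-150, 250),
                             renyi_alpha = 2) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (!is.null(intensity_range)) {
    if (length(intensity_range) != 2L || intensity_range[1] >= intensity_range[2])
      stop("intensity_range must be (lo, hi) with lo < hi")
  }
  if (renyi_alpha <= 0) stop("renyi_alpha must be positive")
  structure(list(n_bins = as.integer(n_bins),
                 intensity_range = intensity_range,
                 renyi_alpha = renyi_alpha),
            class = "histogram_config")
}

#' Renyi entropy of a probability vector
#'
#' `H_alpha = log(sum(p^alpha)) / (1 - alpha)` in nats, with zero-probability
#' terms dropped. `alpha = 1` returns the Shannon entropy
#' `-sum(p * log(p))`, the limit of `H_alpha` as `alpha -> 1`.
#'
#' @param p nonnegative weights (normalized internally).
#' @param alpha positive order.
#' @return Entropy in nats, in `[0, log(length(p))]`.
#' @export
renyi_entropy <- function(p, alpha) {
  if (alpha <= 0) stop("alpha must be positive")
  p <- p[p > 0]
  if (!length(p)) stop("empty distribution")
  p <- p / sum(p)
  if (alpha == 1) return(-sum(p * log(p)))
  log(sum(p^alpha)) / (1 - alpha)
}

#' Histogram features of masked intensities
#'
#' Mean, variance, skewness, kurtosis and Renyi entropy of the intensity
#' values inside the mask on one slice. Moments are population central
#' moments (`m_k = mean((x - mean(x))^k)`); skewness is `m3 / m2^1.5` and
#' kurtosis is the excess kurtosis `m4 / m2^2 - 3` (0 for a normal
#' distribution). When the variance is 0, skewness and kurtosis are
#' reported as 0 by convention. Entropy is computed over the normalized
#' `n_bins` histogram of the configured intensity window.
#'
#' @param intensities numeric vector of masked voxel intensities (length >= 1).
#' @param config a [histogram_config()].
#' @return Named list `mean, variance, skewness, kurtosis, renyi_entropy`.
#' @export
histogram_features <- function(intensities, config = histogram_config()) {
  x <- as.numeric(intensities)
  if (!length(x)) stop("histogram_features: empty intensity set")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 > 0) {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  rng <- config$intensity_range %||% range(x)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  xc <- pmin(pmax(x, rng[1]), rng[2])
  bin <- pmin(floor((xc - rng[1]) / diff(rng) * config$n_bins),
              config$n_bins - 1L)
  counts <- tabulate(bin + 1L, nbins = config$n_bins)
  list(mean = mu, variance = m2, skewness = skew, kurtosis = kurt,
       renyi_entropy = renyi_entropy(counts, config$renyi_alpha))
}

#' Gabor filter-bank configuration
#'
#' The bank holds `n_scales * n_orientations` complex filters. Each filter
#' is a Gaussian envelope modulated by a complex plane wave:
#' `g(x, y) = exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) *
#'            exp(i (2 pi x' / lambda + psi))`
#' with `x' = x cos(theta) + y sin(theta)`, `y' = -x sin(theta) + y cos(theta)`.
#'
#' @param n_scales number of scales (default 5).
#' @param n_orientations number of orientations (default 8);
#'   `theta_k = k * pi / n_orientations`, `k = 0 .. n_orientations - 1`.
#' @param wavelengths sinusoid wavelengths in pixels, one per scale;
#'   default geometric progression `4 * sqrt(2)^s`.
#' @param sigma_ratio Gaussian envelope width as a fraction of the
#'   wavelength, `sigma = sigma_ratio * lambda`; default 0.56 (about one
#'   octave of spatial-frequency bandwidth).
#' @param gamma spatial aspect ratio of the envelope (default 0.5).
#' @param psi phase offset of the sinusoid (default 0).
#' @return A `gabor_config` list.
#' @export
gabor_config <- function(n_scales = 5L, n_orientations = 8L,
                         wavelengths = 4 * sqrt(2)^(seq_len(n_scales) - 1),
                         sigma_ratio = 0.56, gamma = 0.5, psi = 0) {
  if (n_scales < 1L || n_orientations < 1L)
    stop("need at least one scale and one orientation")
  if (length(wavelengths) != n_scales)
    stop("wavelengths must have one entry per scale")
  if (any(wavelengths <= 0) || sigma_ratio <= 0)
    stop("wavelengths and sigma_ratio must be positive")
  structure(list(n_scales = as.integer(n_scales),
                 n_orientations = as.integer(n_orientations),
                 wavelengths = wavelengths, sigma_ratio = sigma_ratio,
                 gamma = gamma, psi = psi),
            class = "gabor_config")
}

#' Build the Gabor filter bank
#'
#' One complex kernel per (scale, orientation) pair, evaluated on a square
#' support truncated at three Gaussian standard deviations (`+- 3 sigma`).
#'
#' @param config a [gabor_config()].
#' @return List of complex matrices with attributes `lambda`, `theta`,
#'   `scale`, `orientation`; length `n_scales * n_orientations`.
#' @export
build_gabor_bank <- function(config = gabor_config()) {
  bank <- vector("list", config$n_scales * config$n_orientations)
  k <- 0L
  for (s in seq_len(config$n_scales)) {
    lambda <- config$wavelengths[s]
    sigma <- config$sigma_ratio * lambda
    half <- max(2L, ceiling(3 * sigma))
    xs <- seq(-half, half)
    x <- matrix(xs, 2 * half + 1, 2 * half + 1, byrow = TRUE)   # column coord
    y <- matrix(xs, 2 * half + 1, 2 * half + 1)                 # row coord
    for (o in seq_len(config$n_orientations)) {
      theta <- (o - 1) * pi / config$n_orientations
      xp <- x * cos(theta) + y * sin(theta)
      yp <- -x * sin(theta) + y * cos(theta)
      env <- exp(-(xp^2 + config$gamma^2 * yp^2) / (2 * sigma^2))
      kern <- env * exp(1i * (2 * pi * xp / lambda + config$psi))
      k <- k + 1L
      attr(kern, "lambda") <- lambda
      attr(kern, "theta") <- theta
      attr(kern, "scale") <- s
      attr(kern, "orientation") <- o
      bank[[k]] <- kern
    }
  }
  bank
}

# FFT-size candidates (products of small primes) for fast convolution.
good_fft_size <- function(n) {
  sizes <- sort(unique(as.vector(outer(
    outer(2^(0:12), 3^(0:7)), 5^(0:4)))))
  sizes <- sizes[sizes <= 16384]
  min(sizes[sizes >= n])
}

# Cache of kernel FFTs keyed by (bank identity, canvas size).
.gabor_cache <- new.env(parent = emptyenv())

bank_ffts <- function(bank, n) {
  key <- paste0("b", format(length(bank)), "_",
                format(sum(vapply(bank, function(k) Re(k[1, 1]), 0))),
                "_n", n)
  hit <- .gabor_cache[[key]]
  if (!is.null(hit)) return(hit)
  ffts <- lapply(bank, function(kern) {
    kk <- nrow(kern)
    half <- (kk - 1L) %/% 2L
    canvas <- matrix(0 + 0i, n, n)
    canvas[1:kk, 1:kk] <- kern
    # center the kernel at (1,1) so circular convolution aligns with "same"
    idx <- c((half + 1):n, 1:half)
    stats::fft(canvas[idx, idx])
  })
  .gabor_cache[[key]] <- ffts
  ffts
}

#' Gabor texture features of one masked slice
#'
#' The slice is cropped to the mask bounding box with the background zeroed,
#' convolved (complex, zero-padded linear convolution via FFT) with every
#' filter in the bank, and summarized over the masked pixels: local energy
#' is the sum of squared response magnitudes and mean amplitude the sum of
#' magnitudes, each divided by the masked-pixel count when
#' `normalize = TRUE` (the default, making features ROI-size independent;
#' `FALSE` gives the raw sums).
#'
#' @param slice_image 2D numeric matrix.
#' @param mask_slice 2D binary matrix of the same shape, nonempty.
#' @param bank filter bank from [build_gabor_bank()].
#' @param normalize divide by masked-pixel count (default `TRUE`).
#' @return `list(local_energy =, mean_amplitude =)`, vectors of bank length
#'   named `s<scale>_o<orientation>`.
#' @export
gabor_features <- function(slice_image, mask_slice, bank = build_gabor_bank(),
                           normalize = TRUE) {
  stopifnot(identical(dim(slice_image), dim(mask_slice)))
  msk <- mask_slice > 0
  if (!any(msk)) stop("gabor_features: empty mask slice")
  bb <- bbox2d(msk)
  img <- slice_image[bb$r[1]:bb$r[2], bb$c[1]:bb$c[2], drop = FALSE]
  m <- msk[bb$r[1]:bb$r[2], bb$c[1]:bb$c[2], drop = FALSE]
  img[!m] <- 0
  ksize <- max(vapply(bank, nrow, 0L))
  n <- good_fft_size(max(dim(img)) + ksize)
  canvas <- matrix(0, n, n)
  canvas[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  f_img <- stats::fft(canvas)
  ffts <- bank_ffts(bank, n)
  midx <- which(m)                      # within the bbox block
  mask_lin <- as.vector(outer(seq_len(nrow(img)) - 1L,
                              (seq_len(ncol(img)) - 1L) * n, `+`) + 1L)[midx]
  npix <- length(midx)
  nb <- length(bank)
  energy <- amp <- numeric(nb)
  for (j in seq_len(nb)) {
    resp <- stats::fft(f_img * ffts[[j]], inverse = TRUE) / (n * n)
    mag <- Mod(resp[mask_lin])
    energy[j] <- sum(mag^2)
    amp[j] <- sum(mag)
  }
  if (normalize) {
    energy <- energy / npix
    amp <- amp / npix
  }
  nm <- vapply(bank, function(k)
    sprintf("s%d_o%d", attr(k, "scale"), attr(k, "orientation")), "")
  names(energy) <- names(amp) <- nm
  list(local_energy = energy, mean_amplitude = amp)
}
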