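# Shared fixtures, all generated in code at test time.

# Small, fast phantom configuration for unit tests (coarser in-plane grid).
tiny_phantom_config <- function(seed = 7L, ...) {
  phantom_config(n_healthy = 3L, n_lacerated = 3L,
                 grade_counts = c("2" = 1L, "3" = 1L, "5" = 1L),
                 image_shape = c(24L, 96L, 96L), spacing = c(5, 2, 2),
                 seed = seed, ...)
}

# Rasterized disk of radius r (pixel centers within r of the center).
raster_disk <- function(r, pad = 4L) {
  n <- 2L * r + 2L * pad + 1L
  ctr <- r + pad + 1
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")
  matrix(as.integer(d2 <= r^2), n, n)
}

# Disk with an angular boundary perturbation rho(phi) = r (1 + amp f(phi)).
raster_wavy_disk <- function(r, amp, freqs = c(11, 15), pad = 8L) {
  n <- 2L * r + 2L * pad + 1L
  ctr <- r + pad + 1
  y <- matrix(seq_len(n) - ctr, n, n)
  x <- t(y)
  phi <- atan2(y, x)
  rr <- sqrt(x^2 + y^2)
  mod <- 1
  for (i in seq_along(freqs))
    mod <- mod + amp / length(freqs) * cos(freqs[i] * phi + i)
  matrix(as.integer(rr <= r * mod), n, n)
}

# The full-size study cohort used by the acceptance tests, built once per
# session (54 healthy + 45 lacerated, grade mix 15/16/10/4, 6 undersized
# masks injected into the healthy stratum).
.study_memo <- new.env(parent = emptyenv())

study_cohort <- function() {
  if (!is.null(.study_memo$res)) return(.study_memo$res)
  dir <- file.path(tempdir(), "splenometrics_study_cohort")
  config <- phantom_config(seed = 101L, n_undersized = 6L)
  manifest <- generate_cohort(config, dir, overwrite = TRUE)
  qc <- qc_filter(manifest)
  features <- build_feature_table(qc$kept)
  .study_memo$res <- list(config = config, manifest = manifest, qc = qc,
                          features = features)
  .study_memo$res
}

# Feature table with a controllable class separation, for classifier tests.
synthetic_feature_table <- function(n, sep = 1.5, p = 20L, seed = 1L,
                                    site_prob = 0.5) {
  splenometrics:::with_seed(seed, {
    lab <- rep(c("healthy", "lacerated"), length.out = n)
    grade <- ifelse(lab == "healthy", 0L, sample(2:5, n, replace = TRUE))
    X <- matrix(rnorm(n * p), n, p)
    X[, 1] <- X[, 1] + sep * (lab == "lacerated")
    X[, 2] <- X[, 2] - sep * (lab == "lacerated")
    colnames(X) <- sprintf("f%02d", seq_len(p))
    cbind(data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                     site = ifelse(runif(n) < site_prob, "site_A", "site_B"),
                     label = lab, ais_grade = grade,
                     stringsAsFactors = FALSE),
          as.data.frame(X))
  })
}

write_manifest_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
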