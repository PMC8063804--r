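test_that("mask volume follows voxel count times voxel volume", {
  sp <- c(5, 1, 1)
  empty <- seg_mask(array(0L, c(12, 20, 20)), sp)
  expect_equal(mask_volume(empty), 0)

  block <- array(0L, c(12, 20, 20))
  block[1:10, 1:10, 1:10] <- 1L
  expect_equal(mask_volume(seg_mask(block, sp)), 5)  # 1000 voxels x 5 mm^3

  # analytic ellipsoid, semi-axes (30, 40, 50) mm at 1 mm isotropic
  a <- 30; b <- 40; cc <- 50
  n <- c(2 * a + 5, 2 * b + 5, 2 * cc + 5)
  ctr <- (n + 1) / 2
  z <- (seq_len(n[1]) - ctr[1]) / a
  y <- (seq_len(n[2]) - ctr[2]) / b
  x <- (seq_len(n[3]) - ctr[3]) / cc
  vox <- outer(outer(z^2, y^2, "+"), x^2, "+") <= 1
  ell <- seg_mask(array(as.integer(vox), n), c(1, 1, 1))
  analytic <- 4 / 3 * pi * a * b * cc / 1000
  expect_lt(abs(mask_volume(ell) - analytic) / analytic, 0.02)
})

test_that("QC filter partitions the cohort and is idempotent", {
  sp <- c(5, 1, 1)
  mk <- function(nvox) {
    m <- array(0L, c(20, 40, 40))
    if (nvox > 0) m[seq_len(nvox)] <- 1L   # nvox voxels of 5 mm^3 each
    seg_mask(m, sp)
  }
  # 5 samples: volumes 100, 90, 10, 0 cm^3, one missing mask
  masks <- list(a = mk(20000), b = mk(18000), c = mk(2000), d = mk(0))
  rec <- data.frame(sample_id = c("a", "b", "c", "d", "e"),
                    site = "site_A", label = "healthy", ais_grade = 0L,
                    volume_path = "", mask_path = "",
                    stringsAsFactors = FALSE)
  res <- qc_filter(rec, masks)
  expect_equal(res$kept$sample_id, c("a", "b"))
  expect_equal(nrow(res$qc), 5)
  expect_equal(res$qc$reason[res$qc$sample_id == "e"], "no_mask")
  # kept + excluded partition the input
  expect_setequal(c(res$kept$sample_id,
                    res$qc$sample_id[!res$qc$passed]), rec$sample_id)
  # idempotent on the kept set
  res2 <- qc_filter(res$kept, masks)
  expect_identical(res2$kept$sample_id, res$kept$sample_id)
  # threshold 0 keeps everything with a mask
  expect_equal(nrow(qc_filter(rec[1:4, ], masks, threshold_cm3 = 0)$kept), 4)
  # all-empty masks are all excluded
  empties <- list(a = mk(0), b = mk(0))
  expect_equal(nrow(qc_filter(rec[1:2, ], empties)$kept), 0)
})

test_that("Dice matches direct overlap counts and is symmetric", {
  sp <- c(1, 1, 1)
  blk <- function(z, y, x) {
    m <- array(0L, c(6, 6, 6))
    m[z, y, x] <- 1L
    seg_mask(m, sp)
  }
  a <- blk(2:3, 2:3, 2:3)
  expect_equal(dice(a, a), 1)
  b <- blk(2:3, 2:3, 3:4)          # shifted one voxel: overlap 4 of 8
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(b, a), dice(a, b))
  d <- blk(5:6, 5:6, 5:6)
  expect_equal(dice(a, d), 0)
  expect_message(val <- dice(blk(integer(0), 1, 1), blk(integer(0), 1, 1)),
                 "empty")
  expect_equal(val, 1)
  expect_error(dice(a, seg_mask(array(0L, c(5, 6, 6)), sp)), "shape")
  # property: dice in [0, 1] over random masks
  set.seed(4)
  for (i in 1:20) {
    m1 <- seg_mask(array(as.integer(runif(216) > 0.5), c(6, 6, 6)), sp)
    m2 <- seg_mask(array(as.integer(runif(216) > 0.5), c(6, 6, 6)), sp)
    dv <- dice(m1, m2)
    expect_gte(dv, 0)
    expect_lte(dv, 1)
  }
})

test_that("contour refinement recovers an eroded seed on a homogeneous phantom", {
  cfg <- tiny_phantom_config(seed = 7L)
  cfg$noise_sd <- 5
  h <- generate_healthy(cfg, seed = 7L)
  truth <- h$mask
  seedm <- truth
  for (i in 1:3)
    seedm$voxels <- array(as.integer(splenometrics:::erode6(seedm$voxels == 1L)),
                          dim(seedm$voxels))
  expect_lt(dice(seedm, truth), 0.6)
  refined <- refine_mask(h$volume, seedm, iterations = 8, reinit_every = 4)
  expect_gte(dice(refined, truth), 0.90)
  # single connected component
  comp <- splenometrics:::component_containing(refined$voxels == 1L,
                                               refined$voxels == 1L)
  expect_equal(sum(comp), sum(refined$voxels))
})

test_that("refinement with zero iterations is the identity and growth is monotone", {
  cfg <- tiny_phantom_config(seed = 9L)
  cfg$noise_sd <- 0
  h <- generate_healthy(cfg, seed = 9L)
  seedm <- h$mask
  for (i in 1:2)
    seedm$voxels <- array(as.integer(splenometrics:::erode6(seedm$voxels == 1L)),
                          dim(seedm$voxels))
  r0 <- refine_mask(h$volume, seedm, iterations = 0)
  expect_identical(r0$voxels, seedm$voxels)
  # volume non-decreasing for a seed strictly inside a homogeneous bright region
  vols <- vapply(c(1, 2, 4), function(it)
    mask_volume(refine_mask(h$volume, seedm, iterations = it,
                            reinit_every = 100)), 0)
  expect_true(all(diff(vols) >= 0))
  expect_error(refine_mask(h$volume,
                           seg_mask(array(0L, dim(h$mask$voxels)), h$mask$spacing)),
               "empty")
})
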