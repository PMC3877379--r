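test_that("voxelwise correlation matches the direct Pearson formula", {
  shape <- c(6, 6, 6)
  mask <- box_mask(shape, margin = 1L)
  set.seed(3)
  n <- 10
  vols <- array(rnorm(prod(shape) * n), dim = c(shape, n))
  y <- rnorm(n)
  # plant exact relationships at two voxels
  vols[3, 3, 3, ] <- y                    # r = 1
  vols[4, 4, 4, ] <- 5                    # zero variance -> r = 0
  cv <- correlationVolume(vols, y, mask)
  r <- volumeData(cv)
  expect_equal(r[3, 3, 3], 1)
  expect_equal(r[4, 4, 4], 0)
  expect_true(all(abs(r[volumeData(mask)]) <= 1))
  expect_true(all(r[!volumeData(mask)] == 0))
  # brute-force oracle at a handful of voxels
  for (idx in list(c(2, 5, 3), c(5, 2, 4), c(3, 4, 5))) {
    x <- vols[idx[1], idx[2], idx[3], ]
    expect_equal(r[idx[1], idx[2], idx[3]],
                 sum((x - mean(x)) * (y - mean(y))) /
                   ((n - 1) * sd(x) * sd(y)))
  }
  expect_error(correlationVolume(vols, y[1:5], mask), "mismatch")
  expect_error(correlationVolume(vols, rep(1, n), mask), "variance")
})

test_that("uniform relief collapses to a single cluster covering the mask", {
  shape <- c(12, 12, 12)
  mask <- box_mask(shape)
  cv <- BrainVolume(array(0.4, shape), volumeGrid(mask), "GM")
  at <- watershedCluster(cv, mask, minClusterVoxels = 10, preSmoothFwhm = 0)
  expect_equal(nrow(clusterTable(at)), 1L)
  expect_valid_atlas(at, mask, 10)
})

test_that("two separated bumps give two clusters containing their peaks", {
  shape <- c(24, 24, 24)
  g <- VolumeGrid(shape, 2)
  mask <- box_mask(shape, margin = 1L)
  a <- array(0, shape)
  peaks <- list(c(7, 7, 7), c(17, 17, 17))
  for (p in peaks) {
    ix <- expand.grid(x = 1:24, y = 1:24, z = 1:24)
    d2 <- (ix$x - p[1])^2 + (ix$y - p[2])^2 + (ix$z - p[3])^2
    a <- a + array(0.9 * exp(-d2 / 8), shape)
  }
  at <- watershedCluster(BrainVolume(a, g, "WM"), mask,
                         minClusterVoxels = 10, preSmoothFwhm = 0)
  expect_equal(nrow(clusterTable(at)), 2L)
  lab <- atlasLabels(at)
  expect_false(lab[7, 7, 7] == lab[17, 17, 17])
  expect_valid_atlas(at, mask, 10)
})

test_that("random reliefs always yield valid partitions (flood-fill oracle)", {
  shape <- c(14, 14, 14)
  for (seed in 1:6) {
    mask <- box_mask(shape)
    cv <- BrainVolume(random_corr_field(shape, seed), volumeGrid(mask), "GM")
    at <- watershedCluster(cv, mask, minClusterVoxels = 8, preSmoothFwhm = 4)
    expect_valid_atlas(at, mask, 8)
  }
})

test_that("watershed output is deterministic", {
  shape <- c(14, 14, 14)
  mask <- box_mask(shape)
  cv <- BrainVolume(random_corr_field(shape, 77), volumeGrid(mask), "GM")
  a1 <- watershedCluster(cv, mask, 8, 4)
  a2 <- watershedCluster(cv, mask, 8, 4)
  expect_identical(atlasLabels(a1), atlasLabels(a2))
  expect_identical(clusterTable(a1), clusterTable(a2))
})

test_that("regional features are per-cluster means (brute-force oracle)", {
  shape <- c(8, 8, 8)
  g <- VolumeGrid(shape, 2)
  labels <- array(0L, shape)
  labels[2:4, 2:4, 2:4] <- 1L
  labels[6, 6, 6] <- 2L       # single-voxel cluster
  at <- new("ClusterAtlas", grid = g, labels = labels,
            clusters = data.frame(label = 1:2, modality = "GM",
                                  nVoxels = c(27L, 1L),
                                  meanAbsR = c(0.5, 0.4)))
  set.seed(12)
  vols <- array(rnorm(prod(shape) * 3), dim = c(shape, 3))
  vols[, , , 3] <- 4.2        # constant subject volume
  fm <- extractFeatures(at, vols, subjects = c("a", "b", "c"))
  for (s in 1:2) {
    expect_equal(featureValues(fm)[s, 1], mean(vols[2:4, 2:4, 2:4, s]))
    expect_equal(featureValues(fm)[s, 2], vols[6, 6, 6, s])
  }
  expect_equal(unname(featureValues(fm)[3, ]), c(4.2, 4.2))
  expect_identical(subjectIds(fm), c("a", "b", "c"))
})

test_that("single-voxel clusters reproduce the voxelwise correlation", {
  shape <- c(6, 6, 6)
  g <- VolumeGrid(shape, 2)
  mask <- box_mask(shape, margin = 1L)
  set.seed(8)
  vols <- array(rnorm(prod(shape) * 12), dim = c(shape, 12))
  y <- rnorm(12)
  cv <- correlationVolume(vols, y, mask)
  labels <- array(0L, shape)
  labels[3, 3, 3] <- 1L
  at <- new("ClusterAtlas", grid = g, labels = labels,
            clusters = data.frame(label = 1L, modality = "GM", nVoxels = 1L,
                                  meanAbsR = NA_real_))
  fm <- extractFeatures(at, vols)
  expect_equal(cor(featureValues(fm)[, 1], y), volumeData(cv)[3, 3, 3])
})

test_that("ranking keeps the strongest features under the printed cap rule", {
  expect_equal(featureCap(80, 8), 216L)
  expect_equal(leaveOutSize(80), 8L)
  expect_equal(leaveOutSize(10), 1L)
  set.seed(5)
  n <- 20
  X <- matrix(rnorm(n * 10), n, 10)
  y <- rnorm(n)
  X[, 4] <- y                          # |r| = 1 must rank first
  fm <- new("FeatureMatrix", values = X,
            features = data.frame(modality = rep(c("GM", "WM"), each = 5),
                                  cluster = rep(1:5, 2)),
            subjects = sprintf("s%d", 1:n))
  sel <- rankAndSelect(fm, y, nC = 80, kC = 8)
  expect_length(sel, 10L)              # cap 216 exceeds the pool
  expect_equal(sel[1], 4L)
  expect_equal(order(-abs(attr(sel, "absR"))), seq_along(sel))
  # fMax truncates the pool deterministically
  expect_length(rankAndSelect(fm, y, nC = 80, kC = 8, fMax = 3), 3L)
  expect_error(rankAndSelect(fm, rep(2, n), nC = 80, kC = 8), "variance")
})

test_that("rank ties break by modality order then cluster label", {
  X <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  fm <- new("FeatureMatrix", values = X,
            features = data.frame(modality = c("PET", "GM", "WM"),
                                  cluster = c(1L, 2L, 1L)),
            subjects = sprintf("s%d", 1:4))
  sel <- rankAndSelect(fm, c(2, 4, 6, 8), nC = 10, kC = 1)
  expect_equal(as.integer(sel), c(2L, 3L, 1L))   # GM before WM before PET
})

test_that("pipeline clusters recover planted regions (Dice > 0)", {
  cfg <- tiny_cohort_config(seed = 2)
  coh <- preprocessCohort(generateCohort(cfg))
  gt <- groundTruth(coh)
  z <- gt$z
  for (m in c("GM", "PET")) {
    cv <- correlationVolume(coh@data[[m]], z, coh@mask, modality = m)
    at <- watershedCluster(cv, coh@mask)
    fm <- extractFeatures(at, coh@data[[m]], subjectIds(coh))
    sel <- rankAndSelect(fm, z, nC = cfg$nSubjects,
                         kC = leaveOutSize(cfg$nSubjects), fMax = 10)
    lab <- atlasLabels(at)
    for (region in 1:2) {
      overlaps <- vapply(featureInfo(fm)$cluster[sel], function(cl)
        sum(lab == cl & gt$labels[[m]] == region), numeric(1))
      expect_gt(max(overlaps), 0)   # some selected cluster hits the region
    }
  }
})
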