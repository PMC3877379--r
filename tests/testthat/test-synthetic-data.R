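test_that("generation is fully deterministic under a fixed seed", {
  cfg <- tiny_cohort_config(seed = 42)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(a@data, b@data)
  expect_identical(scoreTable(a), scoreTable(b))
  expect_identical(groundTruth(a)$z, groundTruth(b)$z)
  expect_identical(groundTruth(a)$labels, groundTruth(b)$labels)
})

test_that("planted regions are disjoint, inside the mask, and labelled", {
  coh <- generateCohort(tiny_cohort_config(seed = 7))
  gt <- groundTruth(coh)
  for (m in names(gt$labels)) {
    lab <- gt$labels[[m]]
    expect_setequal(unique(as.integer(lab)), 0:2)
    expect_true(all(volumeData(coh@mask)[lab > 0]))
  }
})

test_that("null cohort differs from the signal cohort only through beta", {
  cfg <- tiny_cohort_config(seed = 9)
  null <- makeNullCohort(cfg)
  gt <- groundTruth(null)
  expect_true(all(unlist(gt$beta) == 0))
  expect_setequal(unique(as.integer(gt$labels$GM)), 0:2)  # labels still emitted
  # same latent draw and icv stream as the signal cohort, volumes differ
  sig <- generateCohort(cfg)
  expect_identical(gt$z, groundTruth(sig)$z)
  expect_identical(gt$icv, groundTruth(sig)$icv)
  expect_false(identical(null@data$GM, sig@data$GM))
})

test_that("with beta = 0 and white noise the voxel-trait correlations average to zero", {
  nSims <- 2
  acc <- c()
  nVox <- 0
  for (s in 1:nSims) {
    cfg <- tiny_cohort_config(seed = 100 + s, noiseFwhm = c(0, 0, 0))
    null <- makeNullCohort(cfg)
    z <- groundTruth(null)$z
    cv <- correlationVolume(null@data$GM, z, null@mask)
    inMask <- volumeData(cv)[volumeData(null@mask)]
    acc <- c(acc, inMask)
    nVox <- length(inMask)
  }
  expect_lt(abs(mean(acc)), 3 / sqrt(nVox * nSims))
})

test_that("a planted-region centre voxel has the analytic trait correlation", {
  # after ICV normalization: value = base + beta z + e, so with beta = 1 and
  # white noise SD 1 the population correlation is 1/sqrt(2)
  cfg <- syntheticConfig(nSubjects = 200L, shape = c(16L, 16L, 16L),
                         maskFraction = 0.9, radius = 2,
                         noiseSD = c(1, 1, 1), noiseFwhm = c(0, 0, 0),
                         beta = c(1, 1, 1), seed = 13)
  coh <- preprocessCohort(generateCohort(cfg), smoothing = NULL,
                          referenceIcv = cfg$referenceIcv)
  gt <- groundTruth(coh)
  # pick a voxel at the core of region 1 (all planted voxels are equivalent)
  idx <- which(gt$labels$GM == 1L)[1]
  vals <- apply(coh@data$GM, 4, function(a) a[idx])
  rHat <- cor(vals, gt$z)
  fisherSE <- 1 / sqrt(200 - 3)
  expect_lt(abs(atanh(rHat) - atanh(1 / sqrt(2))), 1.96 * fisherSE)
})

test_that("test scores correlate with the latent trait as 1/sqrt(1+sigma_y^2)", {
  cfg <- syntheticConfig(nSubjects = 500L, shape = c(8L, 8L, 8L),
                         maskFraction = 0.9, radius = 1, nRegions = 1L,
                         noiseFwhm = c(0, 0, 0), scoreNoiseSD = 0.5,
                         seed = 17)
  coh <- generateCohort(cfg)
  z <- groundTruth(coh)$z
  expected <- 1 / sqrt(1 + cfg$scoreNoiseSD^2)
  fisherSE <- 1 / sqrt(500 - 3)
  for (test in defaultBatteries()$LTM) {
    rHat <- cor(scoreTable(coh)[[test]], z)
    expect_lt(abs(atanh(rHat) - atanh(expected)), 3 * fisherSE)
  }
})

test_that("regressing planted-region means on the trait recovers beta", {
  cfg <- syntheticConfig(nSubjects = 200L, shape = c(16L, 16L, 16L),
                         maskFraction = 0.9, radius = 2,
                         beta = c(GM = 1, WM = 0.5, PET = 2), seed = 23)
  coh <- preprocessCohort(generateCohort(cfg), smoothing = NULL,
                          referenceIcv = cfg$referenceIcv)
  gt <- groundTruth(coh)
  for (m in c("GM", "WM", "PET")) {
    sel <- gt$labels[[m]] == 1L
    means <- apply(coh@data[[m]], 4, function(a) mean(a[sel]))
    fit <- summary(lm(means ~ gt$z))
    est <- fit$coefficients["gt$z", ]
    expect_lt(abs(est["Estimate"] - gt$beta[[m]][1]), 2 * est["Std. Error"])
  }
})

test_that("a cohort directory round-trips through NIfTI and CSV", {
  cfg <- syntheticConfig(nSubjects = 3L, shape = c(10L, 10L, 10L),
                         maskFraction = 0.9, radius = 1, seed = 31)
  coh <- generateCohort(cfg)
  dir <- tempfile("cohort")
  writeCohort(coh, dir)
  expect_true(file.exists(file.path(dir, "scores.csv")))
  v <- readVolume(file.path(dir, "S002_pet.nii.gz"), "PET",
                  expectedGrid = coh@grid)
  expect_equal(volumeData(v), coh@data$PET[, , , 2], tolerance = 1e-6)
  tr <- jsonlite::read_json(file.path(dir, "truth", "truth.json"),
                            simplifyVector = TRUE)
  expect_equal(tr$z, groundTruth(coh)$z)
  lab <- readVolume(file.path(dir, "truth", "labels_gm.nii.gz"))
  expect_equal(volumeData(lab), groundTruth(coh)$labels$GM + 0)
})
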