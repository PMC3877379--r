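# independent finite-difference oracle for the discriminative direction
fd_contributions <- function(model, X, actual, h = 1e-5) {
  X <- as.matrix(X)
  pred <- predict(model, X)
  # gradients in standardized space: chain rule through the scaling
  G <- matrix(0, nrow(X), ncol(X))
  for (j in seq_len(ncol(X))) {
    up <- X; up[, j] <- up[, j] + h * model@scale[j]
    dn <- X; dn[, j] <- dn[, j] - h * model@scale[j]
    G[, j] <- (predict(model, up) - predict(model, dn)) / (2 * h)
  }
  nrm <- sqrt(rowSums(G^2))
  dir <- G * (sign(actual - pred) / nrm)
  colMeans(abs(dir))
}

test_that("linear-kernel contributions follow the weight structure", {
  set.seed(2)
  X <- cbind(rnorm(40), rnorm(40))
  y <- 2 * X[, 1]                      # feature 2 carries nothing
  m <- fitRVR(X, y, rvrKernel("linear"))
  con <- discriminativeDirection(m, X, y + 0.3)
  expect_gt(con[1], 0.9)
  expect_lt(con[2], 1e-6)
})

test_that("rbf contributions match the finite-difference oracle", {
  set.seed(15)
  X <- matrix(rnorm(50 * 3), 50, 3)
  y <- sin(X[, 1]) + 0.5 * X[, 2]^2 + rnorm(50, sd = 0.05)
  m <- fitRVR(X, y)
  con <- discriminativeDirection(m, X, y)
  expect_true(all(con >= 0))
  expect_equal(con, fd_contributions(m, X, y), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("contributions are invariant to pre-standardization feature scale", {
  set.seed(18)
  X <- matrix(rnorm(40 * 2), 40, 2)
  y <- X[, 1] * X[, 2] + rnorm(40, sd = 0.05)
  conA <- discriminativeDirection(fitRVR(X, y), X, y)
  X2 <- X; X2[, 2] <- 2 * X2[, 2]      # rescale one raw feature
  conB <- discriminativeDirection(fitRVR(X2, y), X2, y)
  expect_equal(conA, conB, tolerance = 1e-8)
})

test_that("intercept-only models yield flagged all-zero contributions", {
  set.seed(20)
  X <- matrix(rnorm(30), 15, 2)
  m <- fitRVR(X, rep(1.25, 15))
  if (!m@interceptOnly) {
    # constant fit may keep the bias basis; force the degenerate branch
    m@interceptOnly <- TRUE
  }
  con <- discriminativeDirection(m, X, rep(1.25, 15))
  expect_equal(as.numeric(con), c(0, 0))
  expect_true(isTRUE(attr(con, "flagged")))
})

test_that("contribution maps paint, average and normalize as specified", {
  shape <- c(6, 6, 6)
  g <- VolumeGrid(shape, 2)
  mask <- BrainMask(array(TRUE, shape), g)
  clus <- array(0, shape); clus[2:3, 2:3, 2:3] <- 0.4
  # single split, single painted cluster: its voxels become 1 after scaling
  cm <- contributionVolume(list(list(GM = clus, WM = array(0, shape))),
                           mask = mask, grid = g)
  expect_equal(max(contributionMaps(cm)$GM), 1)
  expect_equal(sum(contributionMaps(cm)$GM > 0), 8)
  expect_equal(contributionMaps(cm)$WM, array(0, shape))
  # all-zero contributions stay zero (no division by a zero range)
  cm0 <- contributionVolume(list(list(GM = array(0, shape))), mask = mask,
                            grid = g)
  expect_equal(contributionMaps(cm0)$GM, array(0, shape))
  # replicating a split leaves the normalized range unchanged
  cm2 <- contributionVolume(rep(list(list(GM = clus,
                                          WM = array(0, shape))), 4),
                            mask = mask, grid = g)
  expect_equal(contributionMaps(cm2), contributionMaps(cm))
})

test_that("the modality-maximum map applies the documented tie policy", {
  shape <- c(2, 2, 2)
  g <- VolumeGrid(shape, 2)
  gm <- array(0, shape); wm <- array(0, shape); pet <- array(0, shape)
  pet[1, 1, 1] <- 0.9                          # PET dominant -> code 3
  gm[2, 1, 1] <- 0.5; wm[2, 1, 1] <- 0.5       # exact tie -> GM (code 1)
  wm[1, 2, 1] <- 0.3; pet[1, 2, 1] <- 0.2      # WM dominant -> code 2
  cm <- new("ContributionMap", grid = g,
            maps = list(GM = gm, WM = wm, PET = pet),
            overlayThreshold = 0.2)
  mm <- modalityMaxMap(cm)
  expect_equal(mm$codes[1, 1, 1], 3L)
  expect_equal(mm$codes[2, 1, 1], 1L)
  expect_equal(mm$codes[1, 2, 1], 2L)
  expect_equal(mm$codes[2, 2, 2], 0L)          # all-zero voxel stays none
  single <- new("ContributionMap", grid = g, maps = list(GM = gm),
                overlayThreshold = 0.2)
  expect_error(modalityMaxMap(single), "2 modalities")
})

test_that("evaluation reproduces the textbook correlation test", {
  expect_equal(evaluateModel(1:5, 1:5)$r, 1)
  expect_equal(evaluateModel(-(1:5), 1:5)$r, -1)
  set.seed(33)
  a <- rnorm(10); b <- a + rnorm(10)
  ev <- evaluateModel(b, a, splitMSE = c(1, 2, 3, 4))
  ct <- cor.test(b, a)
  expect_equal(ev$r, unname(ct$estimate))
  expect_equal(ev$p, ct$p.value)
  expect_equal(ev$mse$mean, 2.5)
  expect_equal(ev$mse$ci, unname(quantile(1:4, c(0.025, 0.975))))
  expect_error(evaluateModel(1:3, 1:4), "aligned")
})

test_that("permutation comparison is valid on trivial cases and deterministic", {
  set.seed(40)
  y <- rnorm(20); a <- y + rnorm(20)
  same <- permutationCompare(a, a, y, nIterations = 200)
  expect_equal(same$observed, 0)
  expect_equal(same$p, 1)
  b <- rnorm(20)
  pc <- permutationCompare(a, b, y, nIterations = 500, seed = 7)
  expect_gte(pc$p, 1 / 501)
  expect_lte(pc$p, 1)
  expect_identical(permutationCompare(a, b, y, nIterations = 500, seed = 7)$p,
                   pc$p)
  # observed statistic is exactly invariant to subject reordering
  perm <- sample(20)
  pc2 <- permutationCompare(a[perm], b[perm], y[perm], nIterations = 500,
                            seed = 7)
  expect_equal(pc2$observed, pc$observed)
  # both statistics and the score-permutation scheme are available
  pm <- permutationCompare(a, b, y, nIterations = 200,
                           statistic = "delta_mse")
  expect_equal(pm$observed, mean((b - y)^2) - mean((a - y)^2))
  ps <- permutationCompare(a, b, y, nIterations = 200,
                           scheme = "score_permute")
  expect_true(ps$p > 0 && ps$p <= 1)
  expect_error(permutationCompare(a[1:5], b, y), "length")
})

test_that("the GLM map agrees with the correlation volume and flags collinearity", {
  shape <- c(6, 6, 6)
  mask <- box_mask(shape, margin = 1L)
  set.seed(44)
  vols <- array(rnorm(prod(shape) * 12), dim = c(shape, 12))
  y <- rnorm(12)
  gm <- glmMap(vols, y, mask)
  cv <- correlationVolume(vols, y, mask)
  expect_equal(volumeData(gm$r), volumeData(cv))
  expect_error(glmMap(vols, y, mask, covariates = data.frame(s = y)),
               "collinear|rank")
  cov2 <- data.frame(age = rnorm(12), dup = 0)  # constant column: deficient
  cov2$dup <- cov2$age
  expect_error(glmMap(vols, y, mask, covariates = cov2), "rank")
})

test_that("GLM maps recover the sign and site of a planted positive effect", {
  cfg <- tiny_cohort_config(seed = 5)
  coh <- preprocessCohort(generateCohort(cfg))
  gt <- groundTruth(coh)
  z <- gt$z
  gm <- glmMap(coh@data$GM, z, coh@mask,
               covariates = data.frame(age = scoreTable(coh)$age))
  core <- gt$labels$GM == 1L
  expect_gt(mean(volumeData(gm$r)[core]), 0.5)
  expect_gt(min(volumeData(gm$t)[core]), 0)
})
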