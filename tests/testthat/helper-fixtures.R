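# Shared fixtures and independent oracles for the test suite.
# The flood-fill connected-components oracle is pure R and deliberately
# independent of the package's compiled watershed machinery.

# 26-connected components of a logical 3-D array; returns integer labels
oracle_flood_fill <- function(vox) {
  shape <- dim(vox)
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  labels <- array(0L, dim = shape)
  nextLab <- 0L
  todo <- which(vox)
  for (start in todo) {
    if (labels[start] != 0L) next
    nextLab <- nextLab + 1L
    frontier <- start
    labels[start] <- nextLab
    while (length(frontier)) {
      co <- arrayInd(frontier, shape)
      cand <- do.call(rbind, lapply(seq_len(nrow(nb)), function(k)
        cbind(co[, 1] + nb[k, 1], co[, 2] + nb[k, 2], co[, 3] + nb[k, 3])))
      ok <- cand[, 1] >= 1 & cand[, 1] <= shape[1] &
        cand[, 2] >= 1 & cand[, 2] <= shape[2] &
        cand[, 3] >= 1 & cand[, 3] <= shape[3]
      cand <- cand[ok, , drop = FALSE]
      idx <- unique(cand[, 1] + shape[1] * (cand[, 2] - 1) +
                      shape[1] * shape[2] * (cand[, 3] - 1))
      idx <- idx[vox[idx] & labels[idx] == 0L]
      labels[idx] <- nextLab
      frontier <- idx
    }
  }
  labels
}

# assert that an atlas is a valid partition of the mask with 26-connected
# clusters of at least minSize voxels, using the oracle above
expect_valid_atlas <- function(atlas, mask, minSize) {
  lab <- atlasLabels(atlas)
  mk <- volumeData(mask)
  expect_true(all((lab > 0L) == mk))          # exact partition of the mask
  tab <- clusterTable(atlas)
  expect_setequal(sort(unique(lab[lab > 0L])), tab$label)
  for (l in tab$label) {
    comp <- oracle_flood_fill(lab == l)
    expect_equal(max(comp), 1L)               # 26-connected
    expect_gte(sum(lab == l), minSize)
  }
}

# small smooth random correlation-like field in [-1, 1]
random_corr_field <- function(shape, seed) {
  set.seed(seed)
  f <- array(stats::rnorm(prod(shape)), dim = shape)
  f <- patreg:::.smoothArray(f, c(1.2, 1.2, 1.2))
  f / max(abs(f))
}

box_mask <- function(shape, margin = 2L, voxelSize = 2) {
  mk <- array(FALSE, dim = shape)
  mk[(1 + margin):(shape[1] - margin),
     (1 + margin):(shape[2] - margin),
     (1 + margin):(shape[3] - margin)] <- TRUE
  BrainMask(mk, VolumeGrid(shape, voxelSize))
}

# deterministic train/validation fixture with one planted signal feature
# (equal to the score up to tiny noise) and pure-noise companions
make_rfe_fixture <- function(seed, nNoise = 4, nTrain = 30, nVal = 10) {
  set.seed(seed)
  n <- nTrain + nVal
  y <- stats::rnorm(n)
  X <- cbind(y + stats::rnorm(n, sd = 0.01),
             matrix(stats::rnorm(n * nNoise), n, nNoise))
  list(trainX = X[1:nTrain, ], trainY = y[1:nTrain],
       valX = X[(nTrain + 1):n, ], valY = y[(nTrain + 1):n])
}

# desk-scale synthetic cohort for fast integration tests
tiny_cohort_config <- function(seed = 1L, ...) {
  syntheticConfig(nSubjects = 20L, shape = c(16L, 16L, 16L),
                  maskFraction = 0.9, radius = 2, seed = seed, ...)
}
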