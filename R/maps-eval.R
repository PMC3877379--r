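# paint per-cluster values onto the voxels of their clusters
.paintClusters <- function(atlas, clusterLabels, values) {
  out <- array(0, dim = dim(atlas@labels))
  for (i in seq_along(clusterLabels)) {
    out[atlas@labels == clusterLabels[i]] <- values[i]
  }
  out
}

#' Per-feature contributions via the discriminative direction
#'
#' For each subject the gradient `g = df/dx` of the fitted regressor is
#' evaluated at the subject's standardized feature vector; the discriminative
#' direction `sign(actual - predicted) * g / ||g||` is the minimal-norm input
#' change that moves the prediction toward the actual score. The per-feature
#' contribution is the mean over subjects of the absolute component of this
#' direction (non-negative). An intercept-only model has zero gradient
#' everywhere and returns all-zero contributions flagged via the
#' `"flagged"` attribute.
#'
#' @param model a fitted [RVRModel-class].
#' @param X feature rows in the model's training space (typically the
#'   training subjects).
#' @param actual the subjects' actual scores.
#' @return Non-negative per-feature contribution vector.
#' @export
discriminativeDirection <- function(model, X, actual) {
  X <- as.matrix(X)
  d <- length(model@center)
  if (ncol(X) != d) stop("feature dimension mismatch")
  if (model@interceptOnly) {
    out <- numeric(d)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  Xs <- sweep(sweep(X, 2, model@center), 2, model@scale, "/")
  pred <- predict(model, X)
  rv <- model@relevance
  kerIdx <- which(rv > 0L)
  G <- matrix(0, nrow(Xs), d)
  if (length(kerIdx)) {
    Xrv <- model@X[rv[kerIdx], , drop = FALSE]
    muK <- model@mu[kerIdx]
    if (model@kernel$kind == "linear") {
      w <- as.vector(crossprod(Xrv, muK))
      G <- matrix(w, nrow(Xs), d, byrow = TRUE)
    } else {
      gam <- model@kernel$gamma
      kcfg <- model@kernel; kcfg$includeBias <- FALSE
      K <- kernelMatrix(Xs, Xrv, kcfg)
      W <- K * matrix(muK, nrow(Xs), length(muK), byrow = TRUE)
      # grad_j = -2 gamma sum_i mu_i K_si (x_sj - x_ij)
      G <- -2 * gam * (rowSums(W) * Xs - W %*% Xrv)
    }
  }
  nrm <- sqrt(rowSums(G^2))
  ok <- nrm > 0
  if (!any(ok)) {
    out <- numeric(d)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  dir <- G[ok, , drop = FALSE] * (sign(actual - pred)[ok] / nrm[ok])
  colMeans(abs(dir))
}

#' Voxelwise contribution map from per-split spatial difference maps
#'
#' Averages the painted per-cluster contribution volumes across leave-k-out
#' splits and min-max normalizes jointly across the modality set to [0, 1],
#' so cross-modality comparison of contributions is meaningful. When every
#' contribution is zero the map stays zero (no division by a zero range).
#'
#' @param x a [CVResult-class] (uses its stored per-split averages), or a
#'   list of per-split named lists modality -> 3-D contribution array.
#' @param mask a [BrainMask-class] (taken from a `CVResult`).
#' @param grid a [VolumeGrid-class] (taken from a `CVResult`).
#' @param overlayThreshold display cutoff stored with the map (default 0.2);
#'   computation never thresholds.
#' @return A [ContributionMap-class].
#' @export
contributionVolume <- function(x, mask = NULL, grid = NULL,
                               overlayThreshold = 0.2) {
  if (methods::is(x, "CVResult")) {
    maps <- x@contribution
    mask <- x@mask
    grid <- x@grid
  } else {
    mods <- names(x[[1]])
    maps <- lapply(stats::setNames(mods, mods), function(m) {
      Reduce(`+`, lapply(x, `[[`, m)) / length(x)
    })
    if (is.null(grid)) grid <- mask@grid
  }
  for (m in names(maps)) {
    if (!identical(dim(maps[[m]]), as.integer(grid@shape)))
      stop("grid mismatch")
  }
  inMask <- mask@data
  vals <- unlist(lapply(maps, function(a) a[inMask]))
  lo <- min(vals)
  hi <- max(vals)
  norm <- lapply(maps, function(a) {
    out <- array(0, dim = dim(a))
    if (hi > lo) out[inMask] <- (a[inMask] - lo) / (hi - lo)
    out
  })
  new("ContributionMap", grid = grid, maps = norm,
      overlayThreshold = overlayThreshold)
}

#' Modality-maximum map
#'
#' Per voxel, the modality with the largest normalized contribution, coded
#' 0 = none, 1 = GM, 2 = WM, 3 = PET; ties resolve by the priority
#' GM > WM > PET, and voxels where every contribution is zero stay 0.
#'
#' @param cm a [ContributionMap-class] with at least two modalities.
#' @return A [BrainVolume-class]-shaped integer array wrapped in a list
#'   `(codes, grid, legend)`.
#' @export
modalityMaxMap <- function(cm) {
  mods <- names(cm@maps)
  if (length(mods) < 2L) stop("need at least 2 modalities")
  ord <- MODALITIES[MODALITIES %in% mods]  # priority order for ties
  shape <- dim(cm@maps[[1]])
  best <- array(0, dim = shape)
  codes <- array(0L, dim = shape)
  for (m in ord) {
    v <- cm@maps[[m]]
    take <- v > best & v > 0
    codes[take] <- match(m, MODALITIES)
    best[take] <- v[take]
  }
  list(codes = codes, grid = cm@grid,
       legend = c(none = 0L, GM = 1L, WM = 2L, PET = 3L))
}

#' Write contribution and modality-maximum maps as NIfTI
#'
#' Contributions as float32 (one file per modality), modality codes as int8.
#'
#' @param cm a [ContributionMap-class].
#' @param dir output directory.
#' @param prefix file name prefix.
#' @export
writeContributionMaps <- function(cm, dir, prefix = "contribution") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(cm@maps)) {
    img <- .niftiFromGrid(cm@maps[[m]], cm@grid, "float")
    RNifti::writeNifti(img, file.path(dir, sprintf("%s_%s.nii.gz", prefix,
                                                   tolower(m))))
  }
  mm <- modalityMaxMap(cm)
  img <- .niftiFromGrid(mm$codes, cm@grid, "int8")
  RNifti::writeNifti(img, file.path(dir, sprintf("%s_modality_max.nii.gz",
                                                 prefix)))
  invisible(dir)
}

#' Model evaluation: MSE summary and prediction-actual correlation
#'
#' Pearson correlation between predicted and actual scores with a two-sided
#' p-value from the t-distribution with n - 2 degrees of freedom, plus the
#' mean, SD and percentile 95 percent confidence interval of the per-split
#' validation MSEs.
#'
#' @param predictions,actual aligned numeric vectors.
#' @param splitMSE per-split validation MSEs.
#' @return List: `r`, `p`, `mse` (`mean`, `sd`, `ci` = 2.5/97.5 percentiles),
#'   `n`.
#' @export
evaluateModel <- function(predictions, actual, splitMSE = NULL) {
  n <- length(actual)
  if (length(predictions) != n) stop("aligned subjects required")
  if (n < 3L) stop("need at least 3 subjects")
  r <- stats::cor(predictions, actual)
  tStat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tStat), df = n - 2)
  mse <- NULL
  if (!is.null(splitMSE)) {
    mse <- list(mean = mean(splitMSE), sd = stats::sd(splitMSE),
                ci = unname(stats::quantile(splitMSE, c(0.025, 0.975))))
  }
  list(r = r, p = p, mse = mse, n = n)
}

#' Permutation comparison of two models' predictions
#'
#' Tests whether model A predicts the actual scores better than model B.
#' The observed statistic is `T = stat(A) - stat(B)` with `stat` either the
#' prediction-actual Pearson correlation (`delta_r`, default) or minus the
#' MSE (`delta_mse`, so larger is better for both statistics). The null
#' exchanges the paired model labels: per subject, A and B predictions are
#' swapped with probability one half, T recomputed, over `nIterations`
#' draws; `p = (#(|T_perm| >= |T_obs|) + 1) / (nIterations + 1)`. An
#' alternative null that permutes the actual scores against both prediction
#' vectors is available via `scheme = "score_permute"`.
#'
#' @param predA,predB,actual aligned numeric vectors.
#' @param nIterations permutation draws (default 10000).
#' @param seed RNG seed.
#' @param statistic `"delta_r"` or `"delta_mse"`.
#' @param scheme `"swap"` (paired label exchange) or `"score_permute"`.
#' @return List: `p`, `observed`, `statistic`, `nIterations`.
#' @export
permutationCompare <- function(predA, predB, actual, nIterations = 10000L,
                               seed = 1L,
                               statistic = c("delta_r", "delta_mse"),
                               scheme = c("swap", "score_permute")) {
  statistic <- match.arg(statistic)
  scheme <- match.arg(scheme)
  n <- length(actual)
  if (length(predA) != n || length(predB) != n) stop("length mismatch")
  stat <- function(A, B, y) {
    if (statistic == "delta_r") {
      rs <- .rowCorrelations(rbind(A, B), y)
      unname(rs[1] - rs[2])
    } else {
      mean((B - y)^2) - mean((A - y)^2)
    }
  }
  rowStat <- function(Am, Bm, y) {
    yc <- y - mean(y)
    sy <- sqrt(sum(yc^2))
    rr <- function(M) {
      Mc <- M - rowMeans(M)
      r <- as.vector(Mc %*% yc) / (sqrt(rowSums(Mc^2)) * sy)
      r[!is.finite(r)] <- 0     # zero-variance predictions carry no signal
      r
    }
    if (statistic == "delta_r") rr(Am) - rr(Bm)
    else rowMeans((Bm - matrix(y, nrow(Bm), n, byrow = TRUE))^2) -
      rowMeans((Am - matrix(y, nrow(Am), n, byrow = TRUE))^2)
  }
  tObs <- stat(predA, predB, actual)
  set.seed(seed)
  if (scheme == "swap") {
    S <- matrix(stats::runif(nIterations * n) < 0.5, nIterations, n)
    Arep <- matrix(predA, nIterations, n, byrow = TRUE)
    Brep <- matrix(predB, nIterations, n, byrow = TRUE)
    Am <- ifelse(S, Brep, Arep)
    Bm <- ifelse(S, Arep, Brep)
    tPerm <- rowStat(Am, Bm, actual)
  } else {
    tPerm <- vapply(seq_len(nIterations), function(i)
      stat(predA, predB, sample(actual)), numeric(1))
  }
  p <- (sum(abs(tPerm) >= abs(tObs)) + 1) / (nIterations + 1)
  list(p = p, observed = tObs, statistic = statistic,
       nIterations = as.integer(nIterations))
}

#' Mass-univariate GLM baseline map
#'
#' Per voxel, the (partial) Pearson correlation of voxel value with the
#' cognitive score, retaining sign, plus the matching t-statistic volume.
#' When covariates are supplied both voxel values and scores are residualized
#' on them (with intercept) first.
#'
#' @param volumes 4-D array `[x, y, z, subject]` or list of
#'   [BrainVolume-class].
#' @param scores numeric scores, one per subject.
#' @param mask a [BrainMask-class].
#' @param covariates optional numeric matrix / data.frame (e.g. age, sex).
#' @param modality tag for the output volumes.
#' @return List of two [BrainVolume-class] objects: `r` and `t`.
#' @export
glmMap <- function(volumes, scores, mask, covariates = NULL,
                   modality = "GM") {
  if (is.list(volumes)) {
    modality <- volumes[[1]]@modality
    volumes <- .stackVolumes(volumes)
  }
  n <- dim(volumes)[4]
  if (n != length(scores)) stop("subject/volume mismatch")
  if (n < 4L) stop("need at least 4 subjects")
  q <- 0L
  y <- scores
  flat <- matrix(volumes, nrow = prod(dim(volumes)[1:3]))
  idx <- which(mask@data)
  X <- t(flat[idx, , drop = FALSE])  # subjects x voxels
  if (!is.null(covariates)) {
    C <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    if (qr(C)$rank < ncol(C)) stop("rank-deficient covariates")
    q <- ncol(C) - 1L
    H <- C %*% solve(crossprod(C), t(C))
    y <- y - as.vector(H %*% y)
    if (stats::var(y) < 1e-12)
      stop("rank-deficient covariates: score is collinear with covariates")
    X <- X - H %*% X
  }
  r <- .rowCorrelations(t(X), y)
  df <- n - 2L - q
  tStat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  rVol <- numeric(prod(mask@grid@shape)); rVol[idx] <- r
  tVol <- numeric(prod(mask@grid@shape)); tVol[idx] <- tStat
  list(r = BrainVolume(array(rVol, dim = mask@grid@shape), grid = mask@grid,
                       modality = modality),
       t = BrainVolume(array(tVol, dim = mask@grid@shape), grid = mask@grid,
                       modality = modality))
}
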