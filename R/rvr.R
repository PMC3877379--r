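#' Kernel configuration for relevance vector regression
#'
#' @param kind `"rbf"` (Gaussian, `K_ij = exp(-gamma ||x_i - y_j||^2)`) or
#'   `"linear"` (inner product).
#' @param gamma RBF width in standardized-feature units; `NULL` defers to the
#'   median heuristic at fit time (`gamma = 1 / (d * median^2)` with `median`
#'   the median pairwise distance of the standardized training features).
#' @param includeBias append a constant bias basis function.
#' @return Kernel config list.
#' @export
rvrKernel <- function(kind = c("rbf", "linear"), gamma = NULL,
                      includeBias = TRUE) {
  kind <- match.arg(kind)
  if (!is.null(gamma) && gamma <= 0) stop("gamma must be positive")
  list(kind = kind, gamma = gamma, includeBias = includeBias)
}

#' Kernel matrix between two standardized feature sets
#'
#' @param X,Y numeric matrices with matching column counts (rows are
#'   points). Features are assumed already standardized.
#' @param cfg a [rvrKernel()] config (with `gamma` resolved for rbf).
#' @return The `nrow(X) x nrow(Y)` kernel matrix, with a trailing column of
#'   ones appended when `cfg$includeBias` is `TRUE`.
#' @export
kernelMatrix <- function(X, Y, cfg = rvrKernel()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("dimension mismatch")
  K <- if (cfg$kind == "linear") {
    tcrossprod(X, Y)
  } else {
    if (is.null(cfg$gamma)) stop("gamma must be set for the rbf kernel")
    d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
    exp(-cfg$gamma * pmax(d2, 0))
  }
  if (isTRUE(cfg$includeBias)) K <- cbind(K, 1)
  K
}

.medianHeuristicGamma <- function(Xs) {
  d <- ncol(Xs)
  n <- nrow(Xs)
  if (n < 2L) return(1 / max(d, 1))
  d2 <- outer(rowSums(Xs^2), rowSums(Xs^2), "+") - 2 * tcrossprod(Xs)
  med <- stats::median(sqrt(pmax(d2[lower.tri(d2)], 0)))
  if (!is.finite(med) || med <= 0) return(1 / max(d, 1))
  1 / (d * med^2)
}

#' Sparse Bayesian evidence maximization on a fixed design matrix
#'
#' The core update scheme behind [fitRVR()], exposed so that it can be run on
#' an arbitrary design. Iterates the posterior/hyperparameter updates
#' `Sigma = (diag(alpha) + Phi'Phi/sigma2)^-1`,
#' `mu = Sigma Phi' y / sigma2`, `g_i = 1 - alpha_i Sigma_ii`,
#' `alpha_i <- g_i / mu_i^2`,
#' `sigma2 <- ||y - Phi mu||^2 / (n - sum g)`, pruning basis functions whose
#' precision exceeds `alphaPrune` and stopping when
#' `max |delta log alpha| < tol` or `maxIter` is reached. With
#' `updateAlpha = updateSigma2 = FALSE` a single posterior computation at the
#' supplied hyperparameters is returned (whose mean is the ridge solution
#' `(Phi'Phi + alpha sigma2 I)^-1 Phi' y` for a common alpha).
#'
#' @param Phi n x M design matrix.
#' @param y length-n targets.
#' @param alphaInit initial weight precisions (scalar recycled; default
#'   `1/n^2`).
#' @param sigma2Init initial noise variance (default `0.1 var(y)`).
#' @param tol convergence tolerance on `log alpha`.
#' @param maxIter iteration cap.
#' @param alphaPrune precision above which a basis function is pruned.
#' @param updateAlpha,updateSigma2 freeze flags for the hyperparameters.
#' @return List with `active` (1-based surviving column indices), `mu`,
#'   `alpha`, `Sigma` (for the surviving set), `sigma2`, `iterations`,
#'   `converged` and the per-iteration `logEvidence`.
#' @export
rvrEM <- function(Phi, y, alphaInit = NULL, sigma2Init = NULL, tol = 1e-3,
                  maxIter = 500L, alphaPrune = 1e9,
                  updateAlpha = TRUE, updateSigma2 = TRUE) {
  Phi <- as.matrix(Phi)
  n <- nrow(Phi)
  if (length(y) != n) stop("length(y) must match nrow(Phi)")
  if (any(!is.finite(Phi)) || any(!is.finite(y))) stop("inputs must be finite")
  if (is.null(alphaInit)) alphaInit <- 1 / n^2
  alpha <- rep_len(alphaInit, ncol(Phi))
  if (is.null(sigma2Init)) sigma2Init <- max(0.1 * stats::var(y), 1e-6)
  fit <- .rvr_em_cpp(Phi, y, alpha, sigma2Init, tol, as.integer(maxIter),
                     alphaPrune, updateAlpha, updateSigma2)
  fit$active <- fit$active + 1L
  fit
}

#' Fit a relevance vector regression model
#'
#' Kernel regression with independent zero-mean Gaussian priors on the basis
#' weights whose precisions are optimized by evidence maximization. Most
#' precisions diverge, pruning their basis functions; training points whose
#' kernel column survives are the relevance vectors. Features are
#' standardized to zero mean and unit SD using training statistics only; for
#' the rbf kernel an unset width defaults to the median heuristic.
#'
#' @param X n x d numeric feature matrix (training subjects by features).
#' @param y length-n continuous targets.
#' @param kernel a [rvrKernel()] config.
#' @param tol,maxIter,alphaPrune see [rvrEM()].
#' @return A fitted [RVRModel-class]. If every basis function is pruned
#'   (no-signal data) the model falls back to predicting the training mean
#'   and is flagged `interceptOnly`.
#' @examples
#' set.seed(1)
#' X <- matrix(runif(60, -2, 2), 30, 2)
#' y <- sin(X[, 1]) + 0.05 * rnorm(30)
#' m <- fitRVR(X, y)
#' cor(predict(m, X), y)
#' @export
fitRVR <- function(X, y, kernel = rvrKernel(), tol = 1e-3, maxIter = 500L,
                   alphaPrune = 1e9) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 training points")
  if (any(!is.finite(X)) || any(!is.finite(y))) stop("inputs must be finite")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  if (kernel$kind == "rbf" && is.null(kernel$gamma))
    kernel$gamma <- .medianHeuristicGamma(Xs)
  Phi <- kernelMatrix(Xs, Xs, kernel)
  fit <- rvrEM(Phi, y, tol = tol, maxIter = maxIter, alphaPrune = alphaPrune)

  nBasis <- ncol(Phi)
  # map design columns to training rows; bias column (last) is 0
  colMap <- seq_len(nrow(Xs))
  if (isTRUE(kernel$includeBias)) colMap <- c(colMap, 0L)

  if (length(fit$active) == 0L) {
    return(new("RVRModel", X = Xs, center = ctr, scale = scl, kernel = kernel,
               relevance = integer(0), mu = numeric(0), alpha = numeric(0),
               Sigma = matrix(0, 0, 0), sigma2 = max(fit$sigma2, 1e-12),
               converged = fit$converged, iterations = as.integer(fit$iterations),
               logEvidence = as.numeric(fit$logEvidence),
               interceptOnly = TRUE, yMean = mean(y)))
  }
  new("RVRModel", X = Xs, center = ctr, scale = scl, kernel = kernel,
      relevance = as.integer(colMap[fit$active]), mu = as.numeric(fit$mu),
      alpha = as.numeric(fit$alpha), Sigma = as.matrix(fit$Sigma),
      sigma2 = fit$sigma2, converged = fit$converged,
      iterations = as.integer(fit$iterations),
      logEvidence = as.numeric(fit$logEvidence),
      interceptOnly = FALSE, yMean = mean(y))
}

# design rows for new standardized points against the surviving basis set
.rvrDesign <- function(model, Xs) {
  rv <- model@relevance
  k <- model@kernel
  cols <- matrix(0, nrow(Xs), length(rv))
  kerIdx <- which(rv > 0L)
  if (length(kerIdx)) {
    kcfg <- k; kcfg$includeBias <- FALSE
    cols[, kerIdx] <- kernelMatrix(Xs, model@X[rv[kerIdx], , drop = FALSE],
                                   kcfg)
  }
  cols[, rv == 0L] <- 1
  cols
}

#' Predict from a fitted RVR model
#'
#' `f(x) = sum_i mu_i k(x, x_i) (+ bias)` over the relevance vectors, with
#' the training standardization applied to `newdata`.
#'
#' @param object a fitted [RVRModel-class].
#' @param newdata matrix of new feature rows (training-space columns).
#' @param variance also return the predictive variance
#'   `sigma2 + phi' Sigma phi`.
#' @param ... ignored.
#' @return Numeric predictions, or a list `(mean, variance)` when
#'   `variance = TRUE`.
#' @export
setMethod("predict", "RVRModel",
  function(object, newdata, variance = FALSE, ...) {
    Xn <- as.matrix(newdata)
    if (ncol(Xn) != length(object@center))
      stop("feature dimension mismatch")
    if (object@interceptOnly) {
      mu <- rep(object@yMean, nrow(Xn))
      if (variance) return(list(mean = mu,
                                variance = rep(object@sigma2, nrow(Xn))))
      return(mu)
    }
    Xs <- sweep(sweep(Xn, 2, object@center), 2, object@scale, "/")
    Phi <- .rvrDesign(object, Xs)
    mu <- as.vector(Phi %*% object@mu)
    if (!variance) return(mu)
    v <- object@sigma2 + rowSums((Phi %*% object@Sigma) * Phi)
    list(mean = mu, variance = v)
  })

#' Serialize / restore an RVR model
#'
#' Writes the complete model state (standardization, kernel, relevance set,
#' posterior) as versioned JSON so that map evaluation can reuse a fit.
#'
#' @param model a [RVRModel-class].
#' @param path JSON path.
#' @return `path` invisibly; `readRVRModel()` returns the restored model.
#' @export
writeRVRModel <- function(model, path) {
  obj <- list(schema = "patreg-rvr-1",
              X = model@X, center = model@center, scale = model@scale,
              kernel = model@kernel, relevance = model@relevance,
              mu = model@mu, alpha = model@alpha, Sigma = model@Sigma,
              sigma2 = model@sigma2, converged = model@converged,
              iterations = model@iterations,
              logEvidence = model@logEvidence,
              interceptOnly = model@interceptOnly, yMean = model@yMean)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeRVRModel
#' @export
readRVRModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "patreg-rvr-1")) stop("unknown model schema")
  kernel <- obj$kernel
  kernel$gamma <- if (is.null(kernel$gamma)) NULL else as.numeric(kernel$gamma)
  new("RVRModel", X = as.matrix(obj$X), center = as.numeric(obj$center),
      scale = as.numeric(obj$scale), kernel = kernel,
      relevance = as.integer(obj$relevance), mu = as.numeric(obj$mu),
      alpha = as.numeric(obj$alpha),
      Sigma = matrix(as.numeric(obj$Sigma), nrow = length(obj$mu)),
      sigma2 = as.numeric(obj$sigma2), converged = as.logical(obj$converged),
      iterations = as.integer(obj$iterations),
      logEvidence = as.numeric(obj$logEvidence),
      interceptOnly = as.logical(obj$interceptOnly),
      yMean = as.numeric(obj$yMean))
}
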