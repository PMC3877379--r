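# fit an RVR on a column subset and return validation MSE
.rfeFitMSE <- function(trainX, trainY, valX, valY, cols, kernel, rvrControl,
                       counter) {
  m <- fitRVR(trainX[, cols, drop = FALSE], trainY, kernel = kernel,
              tol = rvrControl$tol, maxIter = rvrControl$maxIter,
              alphaPrune = rvrControl$alphaPrune)
  counter$nFits <- counter$nFits + 1L
  mean((predict(m, valX[, cols, drop = FALSE]) - valY)^2)
}

#' RVR fit controls used inside feature elimination
#'
#' @param tol,maxIter,alphaPrune see [rvrEM()]. `maxIter` defaults lower than
#'   a standalone fit because elimination refits the model many times per
#'   split and the selection signal saturates quickly.
#' @return Control list.
#' @export
rfeControl <- function(tol = 1e-3, maxIter = 100L, alphaPrune = 1e9) {
  list(tol = tol, maxIter = as.integer(maxIter), alphaPrune = alphaPrune)
}

#' Backward feature elimination driven by validation MSE
#'
#' Starting from the ranked feature pool, each iteration fits an RVR for
#' every single-feature-removed candidate set and evaluates its MSE on the
#' left-out validation subjects; if the smallest candidate MSE is below the
#' current MSE, that feature is removed (MSE ties to 1e-12 are broken by
#' removing the lower-ranked feature). Elimination stops when no removal
#' reduces the MSE or one feature remains. The rbf kernel width is resolved
#' once on the full candidate pool and reused for every candidate subset so
#' that MSE comparisons are stable.
#'
#' @param features integer feature (column) indices in rank order, best
#'   first.
#' @param trainX,trainY training feature matrix and scores.
#' @param valX,valY left-out validation feature matrix and scores (disjoint
#'   subjects).
#' @param kernel a [rvrKernel()]; an unset rbf width is resolved on the full
#'   pool.
#' @param control an [rfeControl()] list.
#' @return RFE state list: `selected` (rank order), `eliminated` (order of
#'   removal), `history` data.frame (`action`, `feature`, `mse`), `bestMSE`,
#'   `nFits`, `kernel` (resolved).
#' @export
backwardEliminate <- function(features, trainX, trainY, valX, valY,
                              kernel = rvrKernel(), control = rfeControl()) {
  features <- as.integer(features)
  if (!length(features)) stop("empty feature list")
  trainX <- as.matrix(trainX); valX <- as.matrix(valX)
  if (kernel$kind == "rbf" && is.null(kernel$gamma)) {
    full <- trainX[, features, drop = FALSE]
    scl <- apply(full, 2, stats::sd); scl[scl == 0 | !is.finite(scl)] <- 1
    Xs <- sweep(sweep(full, 2, colMeans(full)), 2, scl, "/")
    kernel$gamma <- .medianHeuristicGamma(Xs)
  }
  counter <- new.env()
  counter$nFits <- 0L
  cur <- features
  curMSE <- .rfeFitMSE(trainX, trainY, valX, valY, cur, kernel, control,
                       counter)
  history <- data.frame(action = "full", feature = NA_integer_, mse = curMSE)
  rank <- stats::setNames(seq_along(features), features)

  while (length(cur) > 1L) {
    mses <- vapply(seq_along(cur), function(j)
      .rfeFitMSE(trainX, trainY, valX, valY, cur[-j], kernel, control,
                 counter), numeric(1))
    best <- min(mses)
    if (best >= curMSE - 1e-15) break
    cand <- which(mses <= best + 1e-12)
    # tie: remove the lower-ranked (largest rank number) feature
    j <- cand[which.max(rank[as.character(cur[cand])])]
    removed <- cur[j]
    cur <- cur[-j]
    curMSE <- mses[j]
    history <- rbind(history, data.frame(action = "remove", feature = removed,
                                         mse = curMSE))
  }
  list(selected = cur, eliminated = rev(history$feature[history$action == "remove"]),
       history = history, bestMSE = curMSE, nFits = counter$nFits,
       kernel = kernel)
}

#' Forward re-addition of eliminated features
#'
#' To avoid losing features whose marginal rank was low but which perform
#' well jointly with the kept set, each eliminated feature is trialled for
#' re-addition under the same validation-MSE criterion; the best addition is
#' accepted while it lowers the MSE (ties to 1e-12 prefer the higher-ranked
#' feature). The kernel resolved during backward elimination is reused.
#'
#' @param state the list returned by [backwardEliminate()].
#' @param eliminated features eligible for re-addition (defaults to the
#'   state's eliminated set).
#' @param rankOrder the original ranked pool (for tie-breaking; defaults to
#'   selected followed by eliminated).
#' @inheritParams backwardEliminate
#' @return Updated state list (same shape as [backwardEliminate()]).
#' @export
forwardAdd <- function(state, trainX, trainY, valX, valY,
                       eliminated = state$eliminated,
                       rankOrder = NULL, control = rfeControl()) {
  if (!length(eliminated)) return(state)
  trainX <- as.matrix(trainX); valX <- as.matrix(valX)
  kernel <- state$kernel
  counter <- new.env()
  counter$nFits <- state$nFits
  cur <- state$selected
  curMSE <- state$bestMSE
  pool <- as.integer(eliminated)
  if (is.null(rankOrder)) rankOrder <- c(cur, pool)
  rank <- stats::setNames(seq_along(rankOrder), rankOrder)
  history <- state$history

  while (length(pool)) {
    mses <- vapply(pool, function(f)
      .rfeFitMSE(trainX, trainY, valX, valY, c(cur, f), kernel, control,
                 counter), numeric(1))
    best <- min(mses)
    if (best >= curMSE - 1e-15) break
    cand <- which(mses <= best + 1e-12)
    j <- cand[which.min(rank[as.character(pool[cand])])]
    added <- pool[j]
    cur <- c(cur, added)
    pool <- pool[-j]
    curMSE <- mses[j]
    history <- rbind(history, data.frame(action = "add", feature = added,
                                         mse = curMSE))
  }
  list(selected = cur, eliminated = pool, history = history, bestMSE = curMSE,
       nFits = counter$nFits, kernel = kernel)
}

#' Backward-then-forward feature selection
#'
#' Runs [backwardEliminate()] then [forwardAdd()]; the accepted-step MSE
#' sequence is non-increasing by construction, so the final validation MSE is
#' never above that of the full initial pool.
#'
#' @inheritParams backwardEliminate
#' @return Final RFE state list.
#' @export
rfeSelect <- function(features, trainX, trainY, valX, valY,
                      kernel = rvrKernel(), control = rfeControl()) {
  st <- backwardEliminate(features, trainX, trainY, valX, valY, kernel,
                          control)
  forwardAdd(st, trainX, trainY, valX, valY, rankOrder = features,
             control = control)
}

#' Write an RFE audit trace
#'
#' @param state an RFE state list.
#' @param path CSV path; columns iteration, action, feature, mse.
#' @export
writeRFETrace <- function(state, path) {
  h <- state$history
  h$iteration <- seq_len(nrow(h)) - 1L
  utils::write.csv(h[, c("iteration", "action", "feature", "mse")], path,
                   row.names = FALSE)
  invisible(path)
}
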