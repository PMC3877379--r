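#' Cross-validation configuration
#'
#' Leave-k-out design and the feature-generation/selection knobs used by
#' [runDomain()]. `k_c = round(kFraction * N_c)` subjects are left out per
#' split ("10 percent of full sample size"); exhausting all leave-k-out
#' permutations is combinatorially infeasible (C(80, 8) is of order 1e10),
#' so `nSplits` balanced random splits are drawn instead, the scheduler
#' guaranteeing every subject is left out at least `floor(R k_c / N_c)`
#' times.
#'
#' @param kFraction left-out fraction of the domain sample.
#' @param nSplits number of leave-k-out repetitions R.
#' @param seed integer seed for the split scheduler.
#' @param multiplier ranked-pool multiplier (cap `multiplier * (N_c - k_c)`).
#' @param fMax hard cap on the ranked pool fed to RFE (desk-scale knob).
#' @param minClusterVoxels watershed spatial-consistency minimum.
#' @param preSmoothFwhm pre-smoothing of `|r|` before watershed, mm.
#' @param kernel [rvrKernel()] used by all RVR fits.
#' @param control [rfeControl()] for the elimination fits.
#' @param rfeValidation `"inner"` (default) carves the RFE validation set out
#'   of the split's training subjects, so feature selection never sees the
#'   left-out subjects and their averaged predictions are unbiased;
#'   `"leftout"` drives RFE by the MSE on the split's left-out subjects
#'   themselves. The left-out variant selects features using the very
#'   subjects it is later evaluated on and inflates the
#'   prediction-score correlation on signal-free data (see the vignette),
#'   so it is provided for protocol comparison only.
#' @return Config list.
#' @export
cvConfig <- function(kFraction = 0.1, nSplits = 100L, seed = 1L,
                     multiplier = 3, fMax = 60L, minClusterVoxels = 10L,
                     preSmoothFwhm = 4, kernel = rvrKernel(),
                     control = rfeControl(),
                     rfeValidation = c("inner", "leftout")) {
  if (nSplits < 1L) stop("nSplits must be >= 1")
  list(kFraction = kFraction, nSplits = as.integer(nSplits),
       seed = as.integer(seed), multiplier = multiplier,
       fMax = as.integer(fMax), minClusterVoxels = as.integer(minClusterVoxels),
       preSmoothFwhm = preSmoothFwhm, kernel = kernel, control = control,
       rfeValidation = match.arg(rfeValidation))
}

#' Balanced leave-k-out splits
#'
#' Draws `cfg$nSplits` validation sets of size `k_c` without replacement
#' within a split. A deficit-greedy scheduler (always leave out the subjects
#' with the fewest appearances, random ties) keeps per-subject leave-out
#' counts within one of each other, so every subject is left out at least
#' `floor(R k_c / N_c)` times. Deterministic under `cfg$seed`.
#'
#' @param nC domain sample size.
#' @param cfg a [cvConfig()].
#' @return List of `list(train =, val =)` index pairs.
#' @export
makeSplits <- function(nC, cfg = cvConfig()) {
  kC <- leaveOutSize(nC, cfg$kFraction)
  if (kC >= nC) stop("k_c must be smaller than the sample")
  set.seed(cfg$seed)
  counts <- integer(nC)
  lapply(seq_len(cfg$nSplits), function(s) {
    pri <- order(counts, stats::runif(nC))
    val <- sort(pri[seq_len(kC)])
    counts[val] <<- counts[val] + 1L
    list(train = setdiff(seq_len(nC), val), val = val)
  })
}

# feature generation for one split: per-modality clustering on training
# subjects only, features extracted for all subjects from the train-derived
# atlases, pooled across modalities
.splitFeatures <- function(data, mask, subjects, y, trainIdx, modalities,
                           cfg) {
  fms <- vector("list", length(modalities))
  atlases <- vector("list", length(modalities))
  names(fms) <- names(atlases) <- modalities
  for (m in modalities) {
    arr <- data[[m]]
    cv <- correlationVolume(arr[, , , trainIdx, drop = FALSE], y[trainIdx],
                            mask, modality = m)
    atlases[[m]] <- watershedCluster(cv, mask, cfg$minClusterVoxels,
                                     cfg$preSmoothFwhm)
    fms[[m]] <- extractFeatures(atlases[[m]], arr, subjects)
  }
  list(fm = combineFeatures(fms), atlases = atlases)
}

#' Run the pattern-regression pipeline for one cognitive domain
#'
#' For each leave-k-out split: watershed clustering of the training-subject
#' correlation maps (per modality), regional feature extraction, pooled
#' ranking by correlation power, RVR-RFE feature selection, a final RVR
#' refit on the full training set with the selected features, left-out
#' prediction, and the split's spatial difference map from the
#' discriminative direction of the fitted regressor. By default RFE is
#' validated on an inner split of the training subjects (see
#' [cvConfig()]`$rfeValidation`), so every quantity that touches the
#' left-out subjects is computed after selection is frozen. Left-out
#' predictions are averaged per subject across splits; spatial difference
#' maps are averaged voxelwise.
#'
#' @param cohort a preprocessed [CohortSample-class] (see
#'   [preprocessCohort()]).
#' @param domain domain name present in the cohort's batteries.
#' @param modalities modality subset to model.
#' @param cfg a [cvConfig()].
#' @param verbose print per-split progress.
#' @return A [CVResult-class].
#' @export
runDomain <- function(cohort, domain, modalities = c("GM", "WM", "PET"),
                      cfg = cvConfig(), verbose = FALSE) {
  modalities <- match.arg(modalities, MODALITIES, several.ok = TRUE)
  comp <- .cohortComposite(cohort, domain)
  keep <- match(comp$subject_id, cohort@subjects)
  stopifnot(!anyNA(keep))
  data <- lapply(cohort@data[modalities], function(a)
    a[, , , keep, drop = FALSE])
  subjects <- comp$subject_id
  y <- comp$composite
  nC <- length(y)
  kC <- leaveOutSize(nC, cfg$kFraction)
  splits <- makeSplits(nC, cfg)

  predSum <- numeric(nC)
  predCount <- integer(nC)
  contribSum <- lapply(stats::setNames(modalities, modalities), function(m)
    array(0, dim = cohort@grid@shape))
  valMSE <- numeric(length(splits))
  splitRecs <- vector("list", length(splits))

  for (s in seq_along(splits)) {
    tr <- splits[[s]]$train
    va <- splits[[s]]$val
    gen <- tryCatch(
      .splitFeatures(data, cohort@mask, subjects, y, tr, modalities, cfg),
      error = function(e) stop("split ", s, " [feature_generation]: ",
                               conditionMessage(e)))
    fm <- gen$fm
    Xall <- fm@values
    ranked <- rankAndSelect(
      new("FeatureMatrix", values = Xall[tr, , drop = FALSE],
          features = fm@features, subjects = subjects[tr]),
      y[tr], nC = nC, kC = kC, multiplier = cfg$multiplier, fMax = cfg$fMax)
    if (identical(cfg$rfeValidation, "leftout")) {
      rfeTr <- tr
      rfeVa <- va
    } else {
      # nested design: selection validated on an inner split of the training
      # subjects so the left-out subjects stay untouched until prediction
      nInner <- max(1L, as.integer(round(cfg$kFraction * length(tr))))
      set.seed((cfg$seed %% 10000L) * 1000L + s)
      rfeVa <- sort(sample(tr, nInner))
      rfeTr <- setdiff(tr, rfeVa)
    }
    st <- tryCatch(
      rfeSelect(ranked, Xall[rfeTr, , drop = FALSE], y[rfeTr],
                Xall[rfeVa, , drop = FALSE], y[rfeVa], kernel = cfg$kernel,
                control = cfg$control),
      error = function(e) stop("split ", s, " [rfe]: ", conditionMessage(e)))
    sel <- st$selected
    model <- fitRVR(Xall[tr, sel, drop = FALSE], y[tr], kernel = st$kernel,
                    tol = cfg$control$tol, maxIter = cfg$control$maxIter,
                    alphaPrune = cfg$control$alphaPrune)
    pv <- predict(model, Xall[va, sel, drop = FALSE])
    predSum[va] <- predSum[va] + pv
    predCount[va] <- predCount[va] + 1L
    valMSE[s] <- mean((pv - y[va])^2)

    contrib <- discriminativeDirection(model, Xall[tr, sel, drop = FALSE],
                                       y[tr])
    selInfo <- fm@features[sel, , drop = FALSE]
    selInfo$contribution <- contrib
    for (m in modalities) {
      rows <- which(selInfo$modality == m)
      if (length(rows)) {
        painted <- .paintClusters(gen$atlases[[m]], selInfo$cluster[rows],
                                  contrib[rows])
        contribSum[[m]] <- contribSum[[m]] + painted
      }
    }
    splitRecs[[s]] <- list(train = tr, val = va, selected = selInfo,
                           valMSE = valMSE[s], nFits = st$nFits,
                           history = st$history)
    if (verbose)
      message(sprintf("split %d/%d: %d -> %d features, val MSE %.3f",
                      s, length(splits), length(ranked), length(sel),
                      valMSE[s]))
  }
  if (any(predCount == 0L))
    stop("scheduler bug: subject never left out")
  new("CVResult", domain = domain, modalities = modalities,
      grid = cohort@grid, mask = cohort@mask,
      predictions = data.frame(subject_id = subjects, actual = y,
                               predicted = predSum / predCount,
                               coverage = predCount,
                               stringsAsFactors = FALSE),
      valMSE = valMSE, splits = splitRecs,
      contribution = lapply(contribSum, function(a) a / length(splits)))
}

#' Averaged left-out predictions
#'
#' Arithmetic mean of each subject's left-out predictions across the splits
#' that left them out, with coverage counts.
#'
#' @param result a [CVResult-class].
#' @return data.frame `subject_id`, `actual`, `predicted`, `coverage`.
#' @export
averagePredictions <- function(result) {
  if (any(result@predictions$coverage == 0L))
    stop("uncovered subject: split scheduler failed")
  result@predictions
}
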