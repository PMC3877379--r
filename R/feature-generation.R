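# column-wise Pearson correlation of a voxels-x-subjects matrix with y;
# zero-variance voxels get r = 0
.rowCorrelations <- function(X, y) {
  n <- length(y)
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  Xc <- X - rowMeans(X)
  sx <- sqrt(rowSums(Xc^2))
  r <- as.vector(Xc %*% yc) / (sx * sy)
  r[!is.finite(r)] <- 0
  r
}

#' Voxelwise correlation with a cognitive score
#'
#' Pearson correlation between each mask voxel's values across subjects and
#' the composite score; voxels with zero variance across subjects get r = 0,
#' and voxels outside the mask are 0.
#'
#' @param volumes 4-D array `[x, y, z, subject]` or list of
#'   [BrainVolume-class] objects (one per subject, shared grid).
#' @param scores numeric composite scores, one per subject.
#' @param mask a [BrainMask-class].
#' @return A [BrainVolume-class] of correlations (the modality tag of the
#'   input is retained for arrays via the `modality` argument).
#' @param modality modality tag for the output.
#' @export
correlationVolume <- function(volumes, scores, mask, modality = "GM") {
  if (is.list(volumes)) {
    modality <- volumes[[1]]@modality
    volumes <- .stackVolumes(volumes)
  }
  d <- dim(volumes)
  n <- d[4]
  if (n != length(scores)) stop("subject/volume mismatch")
  if (n < 3L) stop("need at least 3 subjects")
  if (stats::var(scores) == 0) stop("scores have zero variance")
  idx <- which(mask@data)
  flat <- matrix(volumes, nrow = prod(d[1:3]))
  r <- numeric(prod(d[1:3]))
  r[idx] <- .rowCorrelations(flat[idx, , drop = FALSE], scores)
  BrainVolume(array(r, dim = d[1:3]), grid = mask@grid, modality = modality)
}

.stackVolumes <- function(vols) {
  shape <- vols[[1]]@grid@shape
  arr <- array(0, dim = c(shape, length(vols)))
  for (s in seq_along(vols)) arr[, , , s] <- vols[[s]]@data
  arr
}

# cluster adjacency over 26-connectivity: unique label pairs that touch
.clusterAdjacency <- function(labels) {
  shape <- dim(labels)
  pairs <- NULL
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dx < 0 || (dx == 0 && (dy < 0 || (dy == 0 && dz < 0)))) next  # half
    xs <- seq_len(shape[1] - abs(dx))
    ys <- seq_len(shape[2] - abs(dy))
    zs <- seq_len(shape[3] - abs(dz))
    a <- labels[xs + max(dx, 0), ys + max(dy, 0), zs + max(dz, 0)]
    b <- labels[xs + max(-dx, 0), ys + max(-dy, 0), zs + max(-dz, 0)]
    keep <- a > 0L & b > 0L & a != b
    if (any(keep))
      pairs <- rbind(pairs, unique(cbind(pmin(a[keep], b[keep]),
                                         pmax(a[keep], b[keep]))))
  }
  unique(pairs)
}

# merge clusters below minSize into the 26-adjacent cluster with the closest
# mean |r|; deterministic (smallest cluster first, ties by label)
.mergeSmallClusters <- function(labels, absR, minSize) {
  labs <- sort(unique(labels[labels > 0L]))
  size <- vapply(labs, function(l) sum(labels == l), integer(1))
  names(size) <- labs
  sumR <- vapply(labs, function(l) sum(absR[labels == l]), numeric(1))
  names(sumR) <- labs
  adj <- .clusterAdjacency(labels)
  nbr <- lapply(stats::setNames(labs, labs), function(l) {
    c(adj[adj[, 1] == l, 2], adj[adj[, 2] == l, 1])
  })
  alive <- stats::setNames(rep(TRUE, length(labs)), labs)
  parent <- stats::setNames(labs, labs)  # final label of each original label

  repeat {
    cur <- names(alive)[alive]
    small <- cur[size[cur] < minSize]
    small <- small[vapply(small, function(l) length(nbr[[l]]) > 0L, logical(1))]
    if (!length(small)) break
    l <- small[order(size[small], as.integer(small))][1]
    nb <- unique(nbr[[l]])
    meanL <- sumR[l] / size[l]
    meanNb <- sumR[as.character(nb)] / size[as.character(nb)]
    pick <- nb[order(abs(meanNb - meanL), as.integer(nb))][1]
    pc <- as.character(pick)
    # merge l into pick
    size[pc] <- size[pc] + size[l]
    sumR[pc] <- sumR[pc] + sumR[l]
    alive[l] <- FALSE
    parent[parent == as.integer(l)] <- pick
    merged <- union(setdiff(nbr[[l]], pick), setdiff(nbr[[pc]], as.integer(l)))
    nbr[[pc]] <- merged
    for (m in as.character(merged)) {
      nbr[[m]] <- union(setdiff(nbr[[m]], c(as.integer(l), pick)), pick)
    }
    nbr[[l]] <- integer(0)
  }
  map <- integer(max(labs))
  map[as.integer(names(parent))] <- parent
  out <- labels
  out[out > 0L] <- map[out[out > 0L]]
  out
}

#' Watershed clustering of a correlation volume
#'
#' Segments the mask into regional voxel clusters of similar correlation with
#' the cognitive variable. The relief is `-|r|` after Gaussian pre-smoothing
#' of `|r|`, so peaks of absolute correlation are basin cores; markers are
#' the 26-neighbourhood local maxima of the smoothed `|r|` (equal-valued
#' plateau maxima collapse to one marker at the lowest linear index). As a
#' spatial-consistency constraint, clusters smaller than `minClusterVoxels`
#' are merged into the 26-adjacent cluster with the closest mean `|r|` until
#' every cluster meets the minimum. The result labels every mask voxel with
#' 1..K (0 outside), each cluster 26-connected. Final labels are ordered by
#' decreasing cluster mean `|r|`.
#'
#' @param cv a correlation [BrainVolume-class] (as from
#'   [correlationVolume()]).
#' @param mask a [BrainMask-class].
#' @param minClusterVoxels minimum cluster size in voxels.
#' @param preSmoothFwhm FWHM (mm) of the pre-smoothing of `|r|`; 0 disables.
#' @return A [ClusterAtlas-class].
#' @export
watershedCluster <- function(cv, mask, minClusterVoxels = 10L,
                             preSmoothFwhm = 4) {
  if (!any(mask@data)) stop("empty mask")
  if (!sameGrid(cv@grid, mask@grid)) stop("grid mismatch")
  absR <- abs(cv@data)
  absR[!mask@data] <- 0
  relief <- if (preSmoothFwhm > 0) {
    .smoothArray(absR, preSmoothFwhm / (cv@grid@voxelSize * sqrt(8 * log(2))))
  } else absR
  relief[!mask@data] <- -Inf
  dim3 <- as.integer(dim(relief))
  markers <- .find_markers_cpp(as.numeric(relief), as.logical(mask@data), dim3)
  labels <- .watershed_flood_cpp(as.numeric(relief), as.logical(mask@data),
                                 dim3, markers)
  labels <- .mergeSmallClusters(labels, absR, as.integer(minClusterVoxels))
  # relabel 1..K by decreasing mean |r| (ties: lowest first voxel index)
  labs <- sort(unique(labels[labels > 0L]))
  meanR <- vapply(labs, function(l) mean(absR[labels == l]), numeric(1))
  firstIdx <- vapply(labs, function(l) which(labels == l)[1], numeric(1))
  ord <- labs[order(-meanR, firstIdx)]
  map <- integer(max(labs))
  map[ord] <- seq_along(ord)
  out <- labels
  out[out > 0L] <- map[out[out > 0L]]
  k <- length(ord)
  tab <- data.frame(label = seq_len(k),
                    modality = cv@modality,
                    nVoxels = vapply(ord, function(l) sum(labels == l),
                                     integer(1)),
                    meanAbsR = meanR[match(ord, labs)],
                    stringsAsFactors = FALSE)
  new("ClusterAtlas", grid = cv@grid, labels = out, clusters = tab)
}

#' Extract regional features from an atlas
#'
#' The feature value of (subject, cluster) is the mean voxel value of the
#' cluster in that subject's volume.
#'
#' @param atlas a [ClusterAtlas-class].
#' @param volumes 4-D array `[x, y, z, subject]` or list of
#'   [BrainVolume-class].
#' @param subjects subject ids (default `S1..Sn`).
#' @return A [FeatureMatrix-class] with one column per cluster.
#' @export
extractFeatures <- function(atlas, volumes, subjects = NULL) {
  if (is.list(volumes)) {
    if (!sameGrid(atlas@grid, volumes[[1]]@grid)) stop("grid mismatch")
    volumes <- .stackVolumes(volumes)
  }
  d <- dim(volumes)
  if (!identical(d[1:3], as.integer(atlas@grid@shape)))
    stop("grid mismatch between atlas and volumes")
  n <- d[4]
  if (is.null(subjects)) subjects <- sprintf("S%d", seq_len(n))
  labs <- atlas@clusters$label
  idx <- which(atlas@labels > 0L)
  lab <- atlas@labels[idx]
  flat <- matrix(volumes, nrow = prod(d[1:3]))[idx, , drop = FALSE]
  sums <- rowsum(flat, lab)
  counts <- as.vector(table(factor(lab, levels = rownames(sums))))
  vals <- t(sums / counts)
  got <- as.integer(rownames(sums))
  if (!all(labs %in% got)) stop("label absent from atlas volume")
  vals <- vals[, match(labs, got), drop = FALSE]
  colnames(vals) <- NULL
  new("FeatureMatrix", values = vals,
      features = data.frame(modality = atlas@clusters$modality,
                            cluster = labs, stringsAsFactors = FALSE),
      subjects = as.character(subjects))
}

#' Combine feature matrices across modalities
#'
#' Pools per-modality regional feature sets (same subjects, same order) into
#' one matrix, keeping provenance.
#'
#' @param ... [FeatureMatrix-class] objects.
#' @return A [FeatureMatrix-class].
#' @export
combineFeatures <- function(...) {
  fms <- list(...)
  if (length(fms) == 1L && is.list(fms[[1]]) && !methods::is(fms[[1]], "FeatureMatrix"))
    fms <- fms[[1]]
  subj <- fms[[1]]@subjects
  for (f in fms) {
    if (!identical(f@subjects, subj)) stop("subject sets differ")
  }
  new("FeatureMatrix",
      values = do.call(cbind, lapply(fms, function(f) f@values)),
      features = do.call(rbind, lapply(fms, function(f) f@features)),
      subjects = subj)
}

#' Cap on the ranked feature pool
#'
#' The initial pool fed to feature selection keeps the top
#' `multiplier * (N_c - k_c)` features by correlation power.
#'
#' @param nC analyzed sample size for the domain.
#' @param kC number of left-out validation subjects.
#' @param multiplier pool multiplier (default 3).
#' @return Integer cap.
#' @examples
#' featureCap(80, 8)  # 216
#' @export
featureCap <- function(nC, kC, multiplier = 3) {
  if (multiplier < 1) stop("multiplier must be >= 1")
  as.integer(round(multiplier * (nC - kC)))
}

#' Validation-set size for leave-k-out
#'
#' `k_c = round(fraction * N_c)`, the "10 percent of full sample size" rule.
#'
#' @param nC analyzed sample size.
#' @param fraction left-out fraction (default 0.1).
#' @return Integer k (at least 1).
#' @examples
#' leaveOutSize(80)  # 8
#' @export
leaveOutSize <- function(nC, fraction = 0.1) {
  max(1L, as.integer(round(fraction * nC)))
}

#' Rank features by correlation power and keep the top of the pool
#'
#' Features are sorted by decreasing `|Pearson r(feature, score)|` over the
#' training subjects; the top `min(cap, total)` are kept, where
#' `cap = multiplier * (N_c - k_c)`. Ties are broken by modality order
#' GM < WM < PET, then cluster label, for determinism.
#'
#' @param fm a [FeatureMatrix-class] (training subjects only).
#' @param scores numeric training scores aligned with `fm` rows.
#' @param nC,kC sample bookkeeping for the cap (defaults: `nrow + kC` is the
#'   domain sample; pass explicitly in pipeline use).
#' @param multiplier pool multiplier.
#' @param fMax optional hard cap on the pool size (desk-scale runs).
#' @return Integer vector of selected column indices of `fm`, in rank order,
#'   with the per-feature `|r|` attached as attribute `absR`.
#' @export
rankAndSelect <- function(fm, scores, nC, kC, multiplier = 3, fMax = Inf) {
  if (stats::var(scores) == 0) stop("scores have zero variance")
  X <- fm@values
  if (nrow(X) != length(scores)) stop("subject mismatch")
  r <- abs(.rowCorrelations(t(X), scores))
  modOrd <- match(fm@features$modality, MODALITIES)
  ord <- order(-r, modOrd, fm@features$cluster)
  cap <- min(featureCap(nC, kC, multiplier), ncol(X), fMax)
  sel <- ord[seq_len(cap)]
  attr(sel, "absR") <- r[sel]
  sel
}
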