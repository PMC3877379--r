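#' Accessors for patreg objects
#'
#' Small accessor generics so user code never reaches into slots.
#'
#' @param x a patreg object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volumeGrid", function(x) standardGeneric("volumeGrid"))

#' @rdname accessors
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))

#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname accessors
#' @export
setGeneric("atlasLabels", function(x) standardGeneric("atlasLabels"))

#' @rdname accessors
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setGeneric("featureInfo", function(x) standardGeneric("featureInfo"))

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("relevanceVectors", function(x) standardGeneric("relevanceVectors"))

#' @rdname accessors
#' @export
setGeneric("contributionMaps", function(x) standardGeneric("contributionMaps"))

#' @rdname accessors
#' @export
setGeneric("cvPredictions", function(x) standardGeneric("cvPredictions"))

#' @rdname accessors
#' @export
setMethod("volumeGrid", "BrainVolume", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("volumeGrid", "BrainMask", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("volumeGrid", "ClusterAtlas", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("volumeGrid", "CohortSample", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("volumeGrid", "ContributionMap", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("volumeData", "BrainVolume", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("volumeData", "BrainMask", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("modality", "BrainVolume", function(x) x@modality)

#' @rdname accessors
#' @export
setMethod("atlasLabels", "ClusterAtlas", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("clusterTable", "ClusterAtlas", function(x) x@clusters)

#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("featureInfo", "FeatureMatrix", function(x) x@features)
#' @rdname accessors
#' @export
setMethod("subjectIds", "FeatureMatrix", function(x) x@subjects)

#' @rdname accessors
#' @export
setMethod("subjectIds", "CohortSample", function(x) x@subjects)
#' @rdname accessors
#' @export
setMethod("scoreTable", "CohortSample", function(x) x@scores)
#' @rdname accessors
#' @export
setMethod("groundTruth", "CohortSample", function(x) x@groundTruth)

#' @rdname accessors
#' @export
setMethod("relevanceVectors", "RVRModel", function(x) {
  x@relevance[x@relevance > 0L]
})

#' @rdname accessors
#' @export
setMethod("contributionMaps", "ContributionMap", function(x) x@maps)

#' @rdname accessors
#' @export
setMethod("cvPredictions", "CVResult", function(x) x@predictions)
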