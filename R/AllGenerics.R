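# Accessor generics and show methods for the data containers.

#' @describeIn SliceRecord-class patient identifier.
#' @param object,x object.
#' @export
setGeneric("patientId", function(object) standardGeneric("patientId"))
#' @export
setMethod("patientId", "SliceRecord", function(object) object@patientId)

#' @describeIn SliceRecord-class slice index within the patient.
#' @export
setGeneric("sliceIndex", function(object) standardGeneric("sliceIndex"))
#' @export
setMethod("sliceIndex", "SliceRecord", function(object) object@sliceIndex)

#' @describeIn SliceRecord-class intensity matrix.
#' @export
setGeneric("sliceImage", function(object) standardGeneric("sliceImage"))
#' @export
setMethod("sliceImage", "SliceRecord", function(object) object@image)

#' @describeIn SliceRecord-class binary lesion mask matrix.
#' @export
setGeneric("sliceMask", function(object) standardGeneric("sliceMask"))
#' @export
setMethod("sliceMask", "SliceRecord", function(object) object@mask)

setMethod("show", "SliceRecord", function(object) {
  d <- dim(object@image)
  cat(sprintf("SliceRecord  patient %s  slice %d  %dx%d  lesion %d px\n",
              object@patientId, object@sliceIndex, d[1], d[2],
              sum(object@mask)))
})

#' @describeIn SliceSet-class number of slices.
#' @export
setMethod("length", "SliceSet", function(x) length(x@records))

#' @describeIn SliceSet-class extract one SliceRecord.
#' @param i index.
#' @export
setMethod("[[", "SliceSet", function(x, i) x@records[[i]])

#' @describeIn SliceSet-class subset to a new SliceSet.
#' @export
setMethod("[", "SliceSet", function(x, i) {
  SliceSet(x@records[i], x@metadata)
})

#' @describeIn SliceSet-class patient id of every slice.
#' @export
setGeneric("patientIds", function(object) standardGeneric("patientIds"))
#' @export
setMethod("patientIds", "SliceSet", function(object) {
  vapply(object@records, patientId, character(1))
})

#' @describeIn SliceSet-class cohort metadata list.
#' @export
setGeneric("sliceMetadata", function(object) standardGeneric("sliceMetadata"))
#' @export
setMethod("sliceMetadata", "SliceSet", function(object) object@metadata)

setMethod("show", "SliceSet", function(object) {
  ids <- unique(patientIds(object))
  d <- if (length(object)) dim(object[[1]]@image) else c(0, 0)
  cat(sprintf("SliceSet  %d slices  %d patients  %dx%d\n",
              length(object), length(ids), d[1], d[2]))
})

setMethod("show", "DatasetStats", function(object) {
  cat(sprintf("DatasetStats  mean %.4f  sd %.4f%s\n", object@mean, object@sd,
              if (!object@valid) "  [invalid: constant pixel population]" else ""))
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan  train %d  validation %d  test %d\n",
              length(object@train), length(object@validation),
              length(object@test)))
})

#' @describeIn FoldAssignment-class fold index of each patient.
#' @param object object.
#' @export
setGeneric("foldOf", function(object) standardGeneric("foldOf"))
#' @export
setMethod("foldOf", "FoldAssignment", function(object) object@folds)

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment  %d patients in %d folds (sizes: %s)\n",
              length(object@folds), object@k,
              paste(tabulate(object@folds, object@k), collapse = ", ")))
})

setMethod("show", "NetworkConfig", function(object) {
  mech <- c(if (object@useAttention) "attention",
            if (object@useRecurrent) sprintf("recurrent(t=%d)", object@tSteps),
            if (object@useResidual) "residual",
            if (object@useNormalization) "normalization")
  if (!length(mech)) mech <- "skeleton"
  cat(sprintf("NetworkConfig  depth 5, base %d channels  [%s]\n",
              object@baseChannels, paste(mech, collapse = " + ")))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport (per-slice mean ± sd)\n")
  for (m in names(object@means)) {
    cat(sprintf("  %-12s %s\n", m, fmtPM(object@means[m], object@sds[m])))
  }
  cat(sprintf("  %-12s %.4f\n", "pr-auc", object@auc))
})

setMethod("show", "TrainHistory", function(object) {
  n <- nrow(object@epochs)
  cat(sprintf("TrainHistory  %d epochs, best epoch %d (val DSC %.4f)\n",
              n, object@bestEpoch, object@epochs$valDsc[object@bestEpoch]))
})

#' @describeIn MetricsReport-class named vector of per-slice metric means.
#' @param object object.
#' @export
setGeneric("metricMeans", function(object) standardGeneric("metricMeans"))
#' @export
setMethod("metricMeans", "MetricsReport", function(object) object@means)

#' @describeIn MetricsReport-class named vector of per-slice metric sds.
#' @export
setGeneric("metricSds", function(object) standardGeneric("metricSds"))
#' @export
setMethod("metricSds", "MetricsReport", function(object) object@sds)

#' @describeIn MetricsReport-class pooled precision-recall AUC.
#' @export
setGeneric("prAuc", function(object) standardGeneric("prAuc"))
#' @export
setMethod("prAuc", "MetricsReport", function(object) object@auc)
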