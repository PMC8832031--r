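#' SliceRecord: one annotated 2-D slice
#'
#' The atomic dataset unit: a grayscale image, its binary lesion mask, and the
#' identity of the patient the slice came from. Image and mask always share
#' the same shape; the mask is strictly 0/1 (1 = lesion).
#'
#' @slot patientId character scalar, opaque patient identifier.
#' @slot sliceIndex integer scalar, non-negative index within the patient.
#' @slot image numeric matrix of intensities.
#' @slot mask numeric matrix of 0/1 lesion labels, same shape as `image`.
#' @export
setClass("SliceRecord", representation(
  patientId = "character",
  sliceIndex = "integer",
  image = "matrix",
  mask = "matrix"
))

setValidity("SliceRecord", function(object) {
  msg <- character()
  if (length(object@patientId) != 1L) msg <- c(msg, "patientId must be a single string")
  if (length(object@sliceIndex) != 1L || object@sliceIndex < 0L)
    msg <- c(msg, "sliceIndex must be a single non-negative integer")
  if (!identical(dim(object@image), dim(object@mask)))
    msg <- c(msg, "image and mask must have identical shapes")
  if (!isBinary(object@mask)) msg <- c(msg, "mask values must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Construct a SliceRecord
#'
#' @param patientId patient identifier string.
#' @param sliceIndex non-negative slice index.
#' @param image numeric intensity matrix.
#' @param mask 0/1 matrix, same shape as `image`.
#' @return a [SliceRecord-class] object.
#' @export
SliceRecord <- function(patientId, sliceIndex, image, mask) {
  new("SliceRecord", patientId = as.character(patientId),
      sliceIndex = as.integer(sliceIndex), image = image, mask = mask)
}

#' SliceSet: an ordered collection of slices
#'
#' A list-like container of [SliceRecord-class] objects with cohort-level
#' metadata (e.g. the scanner profile assigned to each patient by the phantom
#' generator).
#'
#' @slot records list of SliceRecord objects.
#' @slot metadata named list of cohort-level annotations.
#' @export
setClass("SliceSet", representation(records = "list", metadata = "list"))

setValidity("SliceSet", function(object) {
  ok <- vapply(object@records, function(r) is(r, "SliceRecord"), logical(1))
  if (all(ok)) TRUE else "all records must be SliceRecord objects"
})

#' Construct a SliceSet
#' @param records list of [SliceRecord-class] objects.
#' @param metadata optional named list of cohort metadata.
#' @return a [SliceSet-class] object.
#' @export
SliceSet <- function(records, metadata = list()) {
  new("SliceSet", records = records, metadata = metadata)
}

#' DatasetStats: pixel-population statistics for Z-score normalization
#'
#' @slot mean numeric scalar, pooled pixel mean.
#' @slot sd numeric scalar, pooled pixel standard deviation (population form).
#' @slot valid logical; `FALSE` flags a degenerate (constant) pixel population
#'   whose statistics cannot be used for normalization.
#' @export
setClass("DatasetStats",
         representation(mean = "numeric", sd = "numeric", valid = "logical"))

setValidity("DatasetStats", function(object) {
  if (object@sd < 0) "sd must be non-negative" else TRUE
})

#' SplitPlan: disjoint train/validation/test index sets
#'
#' @slot train,validation,test integer index vectors; pairwise disjoint and
#'   jointly exhaustive over `seq_len(n)`.
#' @export
setClass("SplitPlan", representation(
  train = "integer", validation = "integer", test = "integer"
))

setValidity("SplitPlan", function(object) {
  all_idx <- c(object@train, object@validation, object@test)
  if (anyDuplicated(all_idx)) return("split index sets must be disjoint")
  if (!setequal(all_idx, seq_along(all_idx))) {
    return("split index sets must partition 1..n")
  }
  TRUE
})

#' FoldAssignment: patient-wise cross-validation fold map
#'
#' Maps each distinct patient to a fold in `1..k` so that all slices of a
#' patient share a fold (patient-disjoint partitions).
#'
#' @slot folds named integer vector, patient id -> fold index in 1..k.
#' @slot k integer number of folds.
#' @export
setClass("FoldAssignment", representation(folds = "integer", k = "integer"))

setValidity("FoldAssignment", function(object) {
  msg <- character()
  if (is.null(names(object@folds))) msg <- c(msg, "folds must be named by patient id")
  if (any(object@folds < 1L | object@folds > object@k))
    msg <- c(msg, "fold indices must lie in 1..k")
  sz <- tabulate(object@folds, object@k)
  if (diff(range(sz)) > 1L) msg <- c(msg, "fold sizes must differ by at most 1")
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: parameters of the synthetic head-slice generator
#'
#' Encodes the statistical structure the generator emulates: a single
#' connected lesion of highly variable size/shape/laterality, distractor
#' structures at lesion-like intensity, and strong per-scanner
#' brightness/contrast variation.
#'
#' @slot imageSide image side length in pixels.
#' @slot lesionAreaFraction length-2 range of the lesion area as a fraction of
#'   all pixels (sampled log-uniformly per slice).
#' @slot lesionIrregularity non-negative radial perturbation amplitude; 0
#'   yields an exact ellipse.
#' @slot lateralityBias probability that the lesion sits in the left
#'   hemisphere.
#' @slot nDistractors number of distractor blobs at lesion-like intensity.
#' @slot scannerProfiles list of numeric triples `(brightness offset,
#'   contrast gain, noise sd)` on the 8-bit intensity scale.
#' @slot quantize8bit logical; round output intensities to 0..255 so slices
#'   round-trip through PNG exactly.
#' @slot seed integer root seed.
#' @export
setClass("PhantomSpec", representation(
  imageSide = "integer", lesionAreaFraction = "numeric",
  lesionIrregularity = "numeric", lateralityBias = "numeric",
  nDistractors = "integer", scannerProfiles = "list",
  quantize8bit = "logical", seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  f <- object@lesionAreaFraction
  if (length(f) != 2L || any(f <= 0) || any(f >= 1) || f[1] > f[2])
    msg <- c(msg, "lesionAreaFraction must be an increasing range inside (0,1)")
  if (object@imageSide < 16L) msg <- c(msg, "imageSide must be at least 16")
  if (object@lesionIrregularity < 0) msg <- c(msg, "lesionIrregularity must be >= 0")
  if (object@lateralityBias < 0 || object@lateralityBias > 1)
    msg <- c(msg, "lateralityBias must lie in [0,1]")
  if (length(object@scannerProfiles) < 1L)
    msg <- c(msg, "at least one scanner profile is required")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults describe the full-resolution study conditions: 256x256 slices,
#' lesion area between 0.2% and 6% of pixels, moderately irregular star-convex
#' lesions with no laterality preference, four peripheral distractors, and
#' three scanner profiles spanning a strong brightness/contrast range.
#'
#' @param imageSide image side in pixels (default 256).
#' @param lesionAreaFraction length-2 area-fraction range (default
#'   `c(0.002, 0.06)`).
#' @param lesionIrregularity radial perturbation amplitude (default 0.25).
#' @param lateralityBias probability of a left-hemisphere lesion (default 0.5).
#' @param nDistractors distractor blob count (default 4).
#' @param scannerProfiles list of `(offset, gain, noise sd)` triples.
#' @param quantize8bit round to 8-bit intensities (default TRUE).
#' @param seed integer root seed (default 1).
#' @return a [PhantomSpec-class] object.
#' @export
phantomSpec <- function(imageSide = 256L,
                        lesionAreaFraction = c(0.002, 0.06),
                        lesionIrregularity = 0.25,
                        lateralityBias = 0.5,
                        nDistractors = 4L,
                        scannerProfiles = list(c(-30, 0.8, 4),
                                               c(0, 1.0, 6),
                                               c(40, 1.3, 8)),
                        quantize8bit = TRUE,
                        seed = 1L) {
  new("PhantomSpec", imageSide = as.integer(imageSide),
      lesionAreaFraction = lesionAreaFraction,
      lesionIrregularity = lesionIrregularity,
      lateralityBias = lateralityBias, nDistractors = as.integer(nDistractors),
      scannerProfiles = scannerProfiles, quantize8bit = quantize8bit,
      seed = as.integer(seed))
}

#' CohortSpec: parameters of a multi-patient phantom cohort
#'
#' @slot nPatients number of patients.
#' @slot slicesPerPatient length-2 inclusive range of slices per patient
#'   (sampled uniformly), emulating the wide per-patient slice-count variation
#'   of clinical cohorts.
#' @slot phantom a [PhantomSpec-class].
#' @slot profilePerSlice logical; if `TRUE` a scanner profile is drawn per
#'   slice instead of per patient.
#' @export
setClass("CohortSpec", representation(
  nPatients = "integer", slicesPerPatient = "integer",
  phantom = "PhantomSpec", profilePerSlice = "logical"
))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nPatients < 1L) msg <- c(msg, "nPatients must be >= 1")
  s <- object@slicesPerPatient
  if (length(s) != 2L || s[1] < 1L || s[1] > s[2])
    msg <- c(msg, "slicesPerPatient must be a non-empty increasing range")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortSpec
#' @param nPatients number of patients (default 24).
#' @param slicesPerPatient length-2 range of slices per patient (default
#'   `c(4, 12)`).
#' @param phantom a [PhantomSpec-class] (default [phantomSpec()]).
#' @param profilePerSlice draw scanner profiles per slice rather than per
#'   patient (default FALSE).
#' @return a [CohortSpec-class] object.
#' @export
cohortSpec <- function(nPatients = 24L, slicesPerPatient = c(4L, 12L),
                       phantom = phantomSpec(), profilePerSlice = FALSE) {
  new("CohortSpec", nPatients = as.integer(nPatients),
      slicesPerPatient = as.integer(slicesPerPatient), phantom = phantom,
      profilePerSlice = profilePerSlice)
}

#' NetworkConfig: architecture definition of a network variant
#'
#' A five-level encoder-decoder whose blocks are residual recurrent
#' convolution blocks, degrading gracefully as mechanism flags are switched
#' off (the ablation axis). Channel width doubles per encoder level.
#'
#' @slot depth number of encoder levels (fixed at 5).
#' @slot baseChannels channel width of the first level.
#' @slot tSteps recurrence steps t (total conv passes per recurrent layer).
#' @slot useAttention gate the skip connections with soft spatial attention.
#' @slot useRecurrent recurrent convolution in the blocks.
#' @slot useResidual residual (shortcut) connection in the blocks.
#' @slot useNormalization Z-score-normalize inputs during preprocessing
#'   (a pipeline flag carried with the architecture for the ablation table).
#' @slot dropoutRate dropout rate at the two deepest encoder blocks.
#' @slot modulatingScalar scalar weighting of the residual shortcut.
#' @slot bnEpsilon batch-norm variance floor.
#' @slot bnMomentum running-statistics momentum.
#' @slot bnPerStep keep separate batch-norm state per recurrence step.
#' @export
setClass("NetworkConfig", representation(
  depth = "integer", baseChannels = "integer", tSteps = "integer",
  useAttention = "logical", useRecurrent = "logical", useResidual = "logical",
  useNormalization = "logical", dropoutRate = "numeric",
  modulatingScalar = "numeric", bnEpsilon = "numeric", bnMomentum = "numeric",
  bnPerStep = "logical"
))

setValidity("NetworkConfig", function(object) {
  msg <- character()
  if (object@depth != 5L) msg <- c(msg, "depth is fixed at 5 encoder levels")
  if (object@baseChannels < 1L) msg <- c(msg, "baseChannels must be >= 1")
  if (object@tSteps < 1L) msg <- c(msg, "tSteps must be >= 1")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must lie in [0,1)")
  if (object@bnEpsilon <= 0) msg <- c(msg, "bnEpsilon must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a NetworkConfig
#'
#' @param baseChannels first-level channel width (default 64; reduce to 2-8
#'   for CPU-scale experiments).
#' @param tSteps recurrence steps (default 3).
#' @param useAttention,useRecurrent,useResidual mechanism flags (default all
#'   TRUE).
#' @param useNormalization Z-score preprocessing flag (default TRUE).
#' @param dropoutRate dropout at the two deepest encoder blocks (default 0.5).
#' @param modulatingScalar residual shortcut weight (default 1).
#' @param bnEpsilon batch-norm epsilon (default 1e-5).
#' @param bnMomentum batch-norm running-stat momentum (default 0.1).
#' @param bnPerStep separate batch-norm state per recurrence step (default
#'   FALSE; weights are tied across steps either way).
#' @return a [NetworkConfig-class] object.
#' @export
networkConfig <- function(baseChannels = 64L, tSteps = 3L,
                          useAttention = TRUE, useRecurrent = TRUE,
                          useResidual = TRUE, useNormalization = TRUE,
                          dropoutRate = 0.5, modulatingScalar = 1,
                          bnEpsilon = 1e-5, bnMomentum = 0.1,
                          bnPerStep = FALSE) {
  new("NetworkConfig", depth = 5L, baseChannels = as.integer(baseChannels),
      tSteps = as.integer(tSteps), useAttention = useAttention,
      useRecurrent = useRecurrent, useResidual = useResidual,
      useNormalization = useNormalization, dropoutRate = dropoutRate,
      modulatingScalar = modulatingScalar, bnEpsilon = bnEpsilon,
      bnMomentum = bnMomentum, bnPerStep = bnPerStep)
}

#' TrainConfig: optimizer and training-loop settings
#'
#' @slot beta1,beta2 Adam moment decay rates (0.9 and 0.999).
#' @slot initialLr initial learning rate.
#' @slot lrDecayFactor multiplicative decay applied when validation Dice
#'   plateaus.
#' @slot lrPatience epochs without validation improvement before decay.
#' @slot weightDecay L2 regularization coefficient.
#' @slot epochs training epochs.
#' @slot batchSize mini-batch size.
#' @slot seed integer seed governing shuffling, dropout and initialization.
#' @slot threshold probability threshold for binarizing predictions.
#' @export
setClass("TrainConfig", representation(
  beta1 = "numeric", beta2 = "numeric", initialLr = "numeric",
  lrDecayFactor = "numeric", lrPatience = "integer", weightDecay = "numeric",
  epochs = "integer", batchSize = "integer", seed = "integer",
  threshold = "numeric"
))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@beta1 <= 0 || object@beta1 >= 1) msg <- c(msg, "beta1 must lie in (0,1)")
  if (object@beta2 <= 0 || object@beta2 >= 1) msg <- c(msg, "beta2 must lie in (0,1)")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "threshold must lie in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Construct a TrainConfig
#' @param initialLr initial Adam learning rate (default 1e-3).
#' @param epochs number of epochs (default 25).
#' @param batchSize mini-batch size (default 8).
#' @param seed integer seed (default 1).
#' @param beta1,beta2 Adam moments (defaults 0.9, 0.999).
#' @param lrDecayFactor plateau decay factor (default 0.5).
#' @param lrPatience plateau patience in epochs (default 5).
#' @param weightDecay L2 coefficient (default 1e-5).
#' @param threshold binarization threshold (default 0.5).
#' @return a [TrainConfig-class] object.
#' @export
trainConfig <- function(initialLr = 1e-3, epochs = 25L, batchSize = 8L,
                        seed = 1L, beta1 = 0.9, beta2 = 0.999,
                        lrDecayFactor = 0.5, lrPatience = 5L,
                        weightDecay = 1e-5, threshold = 0.5) {
  new("TrainConfig", beta1 = beta1, beta2 = beta2, initialLr = initialLr,
      lrDecayFactor = lrDecayFactor, lrPatience = as.integer(lrPatience),
      weightDecay = weightDecay, epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), seed = as.integer(seed),
      threshold = threshold)
}

#' MetricsReport: slice-averaged segmentation evaluation
#'
#' @slot means,sds named numeric vectors (dsc, jaccard, precision,
#'   specificity, sensitivity) of per-slice means and standard deviations.
#' @slot auc area under the pooled precision-recall curve.
#' @slot perSlice data.frame of per-slice metric values.
#' @slot prCurve data.frame of (recall, precision) points.
#' @export
setClass("MetricsReport", representation(
  means = "numeric", sds = "numeric", auc = "numeric",
  perSlice = "data.frame", prCurve = "data.frame"
))

#' TrainHistory: per-epoch training record
#'
#' @slot epochs data.frame with columns epoch, lr, trainLoss, valDsc.
#' @slot bestEpoch index (1-based) of the epoch with the highest validation
#'   Dice; the returned model is the checkpoint from this epoch.
#' @export
setClass("TrainHistory",
         representation(epochs = "data.frame", bestEpoch = "integer"))
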