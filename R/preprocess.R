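# Intensity normalization, ROI cropping, resizing, augmentation, and dataset
# partitioning.

#' Pixel-population statistics for Z-score normalization
#'
#' With `scope = "dataset"`, pools every pixel of every slice and returns the
#' population mean and standard deviation (the statistics are typically
#' computed on the training split only and then applied to all splits, which
#' avoids test-set leakage). With `scope = "per_image"`, returns one
#' [DatasetStats-class] per slice.
#'
#' @param records a [SliceSet-class] or list of [SliceRecord-class] objects.
#' @param scope `"dataset"` (default) or `"per_image"`.
#' @return a [DatasetStats-class], or a list of them for `"per_image"`.
#' @export
computeDatasetStats <- function(records, scope = c("dataset", "per_image")) {
  scope <- match.arg(scope)
  recs <- if (is(records, "SliceSet")) records@records else records
  if (length(recs) == 0L) {
    stop("computeDatasetStats: no slices supplied", call. = FALSE)
  }
  if (any(vapply(recs, function(r) length(r@image) == 0L, logical(1)))) {
    stop("computeDatasetStats: empty image encountered", call. = FALSE)
  }
  statsOf <- function(v) {
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))
    new("DatasetStats", mean = m, sd = s, valid = s > 0)
  }
  if (scope == "dataset") {
    statsOf(unlist(lapply(recs, function(r) as.numeric(r@image))))
  } else {
    lapply(recs, function(r) statsOf(as.numeric(r@image)))
  }
}

#' Z-score normalize an image
#'
#' `(image - mean) / sd`, producing a pixel population with mean 0 and unit
#' variance when normalized by its own statistics.
#'
#' @param image numeric matrix.
#' @param stats a valid [DatasetStats-class].
#' @return normalized matrix of the same shape.
#' @export
zscoreNormalize <- function(image, stats) {
  if (!stats@valid || stats@sd <= 0) {
    stop("zscoreNormalize: degenerate pixel population (zero standard ",
         "deviation); Z-score normalization is undefined", call. = FALSE)
  }
  (image - stats@mean) / stats@sd
}

#' Z-score normalize a whole slice set
#'
#' @param set a [SliceSet-class].
#' @param stats a [DatasetStats-class] (dataset scope), or `NULL` to use each
#'   slice's own statistics (per-image scope).
#' @return a new [SliceSet-class] with normalized images (masks untouched).
#' @export
normalizeSliceSet <- function(set, stats = NULL) {
  recs <- lapply(set@records, function(r) {
    s <- stats %||% computeDatasetStats(list(r))
    r@image <- zscoreNormalize(r@image, s)
    r
  })
  SliceSet(recs, set@metadata)
}

#' Crop a slice to the lesion region of interest
#'
#' The crop window is the mask bounding box expanded by `margin` pixels on
#' every side and clipped to the image bounds; image and mask are cropped
#' identically. Slices without any lesion pixel are rejected (the dataset
#' convention keeps only lesion-containing slices).
#'
#' @param record a [SliceRecord-class] with a non-empty mask.
#' @param margin non-negative margin in pixels (default 0).
#' @return the cropped [SliceRecord-class].
#' @export
cropToRoi <- function(record, margin = 0L) {
  m <- record@mask
  if (sum(m) == 0) {
    stop("cropToRoi: empty mask; only lesion-containing slices are kept",
         call. = FALSE)
  }
  rows <- range(which(rowSums(m) > 0))
  cols <- range(which(colSums(m) > 0))
  r0 <- max(1L, rows[1] - margin)
  r1 <- min(nrow(m), rows[2] + margin)
  c0 <- max(1L, cols[1] - margin)
  c1 <- min(ncol(m), cols[2] + margin)
  SliceRecord(record@patientId, record@sliceIndex,
              record@image[r0:r1, c0:c1, drop = FALSE],
              record@mask[r0:r1, c0:c1, drop = FALSE])
}

#' Resize a slice to a square side
#'
#' The image is resampled with bilinear interpolation; the mask with
#' nearest-neighbor and re-binarized at 0.5, so it stays strictly 0/1.
#'
#' @param record a [SliceRecord-class].
#' @param side target side length (>= 8).
#' @return the resized [SliceRecord-class].
#' @export
resizeTo <- function(record, side) {
  side <- as.integer(side)
  if (is.na(side) || side < 8L) {
    stop("resizeTo: side must be an integer >= 8", call. = FALSE)
  }
  if (identical(dim(record@image), c(side, side))) return(record)
  img <- EBImage::resize(record@image, w = side, h = side,
                         filter = "bilinear")
  msk <- EBImage::resize(record@mask, w = side, h = side, filter = "none")
  SliceRecord(record@patientId, record@sliceIndex, as.matrix(img),
              (as.matrix(msk) > 0.5) * 1)
}

# geometric transforms applied identically to image and mask; the mask path
# uses nearest-neighbor sampling and re-binarization.
applyTransform <- function(record, tr) {
  d <- dim(record@image)
  warp <- function(x, filter) {
    out <- switch(tr$type,
      mirror = x[, ncol(x):1, drop = FALSE],
      rotate = if (tr$angle %% 360 == 0) x else {
        as.matrix(EBImage::rotate(x, tr$angle, filter = filter,
                                  output.dim = d, bg.col = 0))
      },
      affine = {
        # center the transform: out(p) = in(A (p - c) + c + shift)
        A <- matrix(c(tr$sx %||% 1, tr$shear %||% 0,
                      0, tr$sy %||% 1), 2, 2)
        cen <- (d + 1) / 2
        off <- cen - A %*% cen
        m <- rbind(t(A), as.numeric(off))
        as.matrix(EBImage::affine(x, m, filter = filter, output.dim = d,
                                  bg.col = 0))
      },
      stop("augment: unknown transform '", tr$type, "'", call. = FALSE)
    )
    out
  }
  img <- warp(record@image, "bilinear")
  msk <- (warp(record@mask, "none") > 0.5) * 1
  SliceRecord(record@patientId, record@sliceIndex, img, msk)
}

#' Default geometric augmentation transforms
#'
#' Horizontal mirror, rotations of +-5 and +-10 degrees, mild isotropic
#' scaling (0.9 and 1.1) and a 5% shear: magnitudes chosen to preserve
#' anatomical plausibility of head slices.
#' @return list of transform descriptors for [augment()].
#' @export
defaultAugmentation <- function() {
  list(list(type = "mirror"),
       list(type = "rotate", angle = 5), list(type = "rotate", angle = -5),
       list(type = "rotate", angle = 10), list(type = "rotate", angle = -10),
       list(type = "affine", sx = 1.1, sy = 1.1),
       list(type = "affine", sx = 0.9, sy = 0.9),
       list(type = "affine", shear = 0.05))
}

#' Augment a slice with geometric transforms
#'
#' Returns the original slice followed by one transformed copy per entry of
#' `spec`; every transform is applied identically to image and mask, and the
#' result is deterministic under `seed` (relevant for transforms with random
#' parameters, none of which are in the default spec).
#'
#' @param record a [SliceRecord-class].
#' @param spec list of transform descriptors, each a list with `type` in
#'   `"mirror"`, `"rotate"` (field `angle`, degrees), `"affine"` (fields
#'   `sx`, `sy` scale, `shear`); default [defaultAugmentation()]: horizontal
#'   mirror, rotations of +-5 and +-10 degrees, mild scale (0.9/1.1) and
#'   shear.
#' @param seed integer seed.
#' @return list of [SliceRecord-class]: the original plus the transforms.
#' @export
augment <- function(record, spec = defaultAugmentation(), seed = 1L) {
  withSeed(seed, {
    c(list(record), lapply(spec, function(tr) applyTransform(record, tr)))
  })
}

#' Expand a slice set to a target size by sampled augmentation
#'
#' Samples (slice, transform) pairs uniformly until `targetCount` slices
#' exist (originals included), mirroring the way a fixed augmentation recipe
#' expands an annotated dataset to a round training-set size.
#'
#' @param set a [SliceSet-class].
#' @param targetCount desired total slice count (>= `length(set)`).
#' @param spec transform list as in [augment()].
#' @param seed integer seed.
#' @return augmented [SliceSet-class] of exactly `targetCount` slices.
#' @export
augmentDataset <- function(set, targetCount,
                           spec = defaultAugmentation(), seed = 1L) {
  n <- length(set)
  if (targetCount < n) {
    stop("augmentDataset: targetCount below current size", call. = FALSE)
  }
  withSeed(seed, {
    extra <- targetCount - n
    recs <- set@records
    if (extra > 0L) {
      si <- sample.int(n, extra, replace = TRUE)
      ti <- sample.int(length(spec), extra, replace = TRUE)
      for (j in seq_len(extra)) {
        recs[[n + j]] <- applyTransform(set@records[[si[j]]], spec[[ti[j]]])
      }
    }
    SliceSet(recs, set@metadata)
  })
}

#' Split a dataset into train/validation/test index sets
#'
#' After a seeded shuffle, the training set receives `floor(f1 * n)` indices
#' and the validation set `floor(f2 * n)`; the test set takes the remainder
#' (the rounding convention under which 4775 slices split 80/10/10 yield a
#' 478-image test set).
#'
#' @param n number of items (>= 3).
#' @param fractions length-3 vector summing to 1 (default `c(0.8, 0.1, 0.1)`
#'   for train/validation/test).
#' @param seed integer seed.
#' @return a [SplitPlan-class].
#' @export
splitDataset <- function(n, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L) {
    stop("splitDataset: need at least 3 items", call. = FALSE)
  }
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9) {
    stop("splitDataset: fractions must be length 3 and sum to 1",
         call. = FALSE)
  }
  withSeed(seed, {
    ord <- sample.int(n)
    nTrain <- floor(fractions[1] * n)
    nVal <- floor(fractions[2] * n)
    rest <- if (nTrain + nVal < n) ord[(nTrain + nVal + 1L):n] else integer(0)
    new("SplitPlan",
        train = sort(ord[seq_len(nTrain)]),
        validation = sort(ord[nTrain + seq_len(nVal)]),
        test = sort(rest))
  })
}

#' Assign patients to cross-validation folds
#'
#' Shuffles the distinct patient identifiers under the seed and deals them
#' round-robin into `k` folds, so fold sizes differ by at most one patient
#' and every slice of a patient inherits the patient's fold (patient-disjoint
#' partitions).
#'
#' @param patient_ids character vector of patient ids (with repeats allowed;
#'   only distinct ids are assigned).
#' @param k number of folds.
#' @param seed integer seed.
#' @return a [FoldAssignment-class].
#' @export
assignPatientFolds <- function(patient_ids, k = 5L, seed = 1L) {
  ids <- unique(as.character(patient_ids))
  k <- as.integer(k)
  if (length(ids) < k) {
    stop("assignPatientFolds: fewer distinct patients (", length(ids),
         ") than folds (", k, ")", call. = FALSE)
  }
  withSeed(seed, {
    ord <- sample(ids)
    folds <- stats::setNames(rep(seq_len(k), length.out = length(ord)), ord)
    new("FoldAssignment", folds = folds[ids], k = k)
  })
}
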