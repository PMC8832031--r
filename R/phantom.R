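# Synthetic head-slice phantom generator.
#
# The phantoms are not anatomically realistic; they reproduce the statistical
# structure that makes lesion segmentation hard: a single connected lesion of
# highly variable size, shape and laterality near the image center,
# surrounding distractor structures at lesion-like intensity in the
# peripheral "tissue" band, and strong per-scanner brightness/contrast/noise
# variation applied as an affine intensity transform.

# smooth isotropic random field via Gaussian blur of white noise
smoothField <- function(side, sigma, amplitude) {
  f <- matrix(rnorm(side * side), side, side)
  f <- as.matrix(EBImage::gblur(f, sigma = sigma))
  f / max(sd(f), 1e-8) * amplitude
}

# star-convex radial function: ellipse base modulated by a random Fourier
# perturbation of relative amplitude `irregularity`
radialProfile <- function(theta, a, b, phi, irregularity) {
  ct <- cos(theta - phi); st <- sin(theta - phi)
  r <- a * b / sqrt((b * ct)^2 + (a * st)^2)
  if (irregularity > 0) {
    nh <- 4L
    amp <- runif(nh, 0, irregularity / nh)
    ph <- runif(nh, 0, 2 * pi)
    pert <- rowSums(vapply(seq_len(nh), function(k) {
      amp[k] * cos((k + 1) * theta + ph[k])
    }, numeric(length(theta))))
    r <- r * pmax(1 + pert, 0.2)
  }
  r
}

# rasterize a star-convex blob; returns a binary matrix
rasterBlob <- function(side, cx, cy, a, b, phi, irregularity) {
  xs <- matrix(rep(seq_len(side), each = side), side, side)  # column index
  ys <- matrix(rep(seq_len(side), times = side), side, side) # row index
  dx <- (xs - cx); dy <- (ys - cy)
  theta <- atan2(dy, dx)
  rr <- sqrt(dx^2 + dy^2)
  (rr <= radialProfile(as.numeric(theta), a, b, phi, irregularity)) * 1
}

#' Generate one synthetic head-slice phantom
#'
#' Deterministic in `(spec@seed, patient_seed, slice_index)`: the same triple
#' always yields a byte-identical record. The background is a smoothed random
#' field with concentric ring "anatomy" inside an elliptical head; the lesion
#' is a star-convex blob (an exact ellipse at zero irregularity) placed in
#' the central region with its hemisphere drawn from the laterality bias; the
#' distractors are blobs of lesion-like intensity in the peripheral band and
#' are excluded from the mask; the scanner profile is applied as
#' `gain * I + offset + noise`.
#'
#' @param spec a [PhantomSpec-class].
#' @param patient_seed integer per-patient stream label.
#' @param slice_index integer slice label.
#' @param profile index into `spec@scannerProfiles` (default drawn from the
#'   slice's stream).
#' @return a [SliceRecord-class]; the applied profile index is attached as
#'   attribute `profile`.
#' @export
generatePhantom <- function(spec, patient_seed = 1L, slice_index = 0L,
                            profile = NULL) {
  validObject(spec)
  side <- spec@imageSide
  withSeed(deriveSeed(spec@seed, patient_seed, slice_index), {
    cen <- (side + 1) / 2
    # head ellipse with mild jitter
    headA <- side / 2 * runif(1, 0.82, 0.9)
    headB <- side / 2 * runif(1, 0.88, 0.96)
    xs <- matrix(rep(seq_len(side), each = side), side, side)
    ys <- matrix(rep(seq_len(side), times = side), side, side)
    rx <- (xs - cen) / headA
    ry <- (ys - cen) / headB
    inHead <- (rx^2 + ry^2) <= 1
    rnorm2 <- sqrt(rx^2 + ry^2)

    img <- matrix(8, side, side) + smoothField(side, side / 32, 2)
    tissue <- 90 + smoothField(side, side / 16, 18) +
      20 * sin(rnorm2 * 3 * 2 * pi + runif(1, 0, 2 * pi)) * (rnorm2 > 0.35)
    img[inHead] <- tissue[inHead]

    # lesion: sampled area fraction (log-uniform), center in the central
    # region with laterality from the bias, star-convex support
    lo <- spec@lesionAreaFraction[1]; hi <- spec@lesionAreaFraction[2]
    mask <- NULL
    for (attempt in seq_len(100L)) {
      frac <- exp(runif(1, log(lo), log(hi)))
      area <- frac * side^2
      ecc <- runif(1, 0.6, 1)         # axis ratio b/a
      a <- sqrt(area / (pi * ecc))
      b <- a * ecc
      phi <- runif(1, 0, pi)
      sgn <- if (runif(1) < spec@lateralityBias) -1 else 1
      cx <- cen + sgn * runif(1, 0.03, 0.22) * side
      cy <- cen + runif(1, -0.18, 0.18) * side
      if (max(a, b) * 1.4 > 0.33 * side) next  # keep inside the central zone
      cand <- rasterBlob(side, cx, cy, a, b, phi, spec@lesionIrregularity)
      af <- sum(cand) / side^2
      if (af >= lo && af <= hi && all(inHead[cand == 1])) {
        mask <- cand
        break
      }
    }
    if (is.null(mask)) {
      stop("generatePhantom: could not place a lesion within bounds after ",
           "100 attempts", call. = FALSE)
    }

    lesionIntensity <- 170 + rnorm(1, 0, 8)
    img[mask == 1] <- lesionIntensity + smoothField(side, side / 24, 5)[mask == 1]

    # distractors: lesion-like intensity, peripheral band, never overlapping
    # the lesion; excluded from the mask
    placed <- 0L
    guard <- 0L
    while (placed < spec@nDistractors && guard < 200L) {
      guard <- guard + 1L
      ang <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0.45, 0.8)
      dcx <- cen + cos(ang) * rad * headA
      dcy <- cen + sin(ang) * rad * headB
      da <- side * runif(1, 0.03, 0.07)
      db <- da * runif(1, 0.6, 1)
      blob <- rasterBlob(side, dcx, dcy, da, db, runif(1, 0, pi), 0.3)
      blob[!inHead] <- 0
      if (sum(blob) < 4 || any(blob == 1 & mask == 1)) next
      img[blob == 1] <- lesionIntensity + rnorm(1, 0, 6)
      placed <- placed + 1L
    }

    # scanner profile: affine intensity transform + additive noise
    pidx <- profile %||% sample.int(length(spec@scannerProfiles), 1L)
    pr <- spec@scannerProfiles[[pidx]]
    img <- pr[2] * img + pr[1] + matrix(rnorm(side^2, 0, pr[3]), side, side)
    img <- pmin(pmax(img, 0), 255)
    if (spec@quantize8bit) img <- round(img)

    rec <- SliceRecord(paste0("P", patient_seed), slice_index, img, mask)
    attr(rec, "profile") <- pidx
    rec
  })
}

#' Generate a multi-patient phantom cohort
#'
#' Draws a per-patient slice count from the spec range and one scanner
#' profile per patient (so intensity statistics cluster by patient, emulating
#' equipment- and operator-dependent image variation), then generates every
#' slice deterministically from the root seed.
#'
#' @param spec a [CohortSpec-class].
#' @return a [SliceSet-class]; `sliceMetadata()` carries the patient
#'   manifest (`patient`, `nSlices`, `profile`).
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  ph <- spec@phantom
  nProf <- length(ph@scannerProfiles)
  plan <- withSeed(deriveSeed(ph@seed, 9001), {
    counts <- seq(spec@slicesPerPatient[1], spec@slicesPerPatient[2])
    data.frame(
      patient = paste0("P", seq_len(spec@nPatients)),
      nSlices = counts[sample.int(length(counts), spec@nPatients,
                                  replace = TRUE)],
      profile = sample.int(nProf, spec@nPatients, replace = TRUE)
    )
  })
  recs <- list()
  for (p in seq_len(spec@nPatients)) {
    for (s in seq_len(plan$nSlices[p])) {
      prof <- if (spec@profilePerSlice) NULL else plan$profile[p]
      recs[[length(recs) + 1L]] <-
        generatePhantom(ph, patient_seed = p, slice_index = s - 1L,
                        profile = prof)
    }
  }
  SliceSet(recs, metadata = list(manifest = plan, phantom = ph))
}
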