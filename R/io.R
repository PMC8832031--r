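# Dataset disk layout: paired grayscale images
# `<patient>_<slice>_img.png` / `<patient>_<slice>_mask.png` plus a manifest
# CSV (patient_id, slice_index, image_path, mask_path). 16-bit PNG and TIFF
# inputs are accepted on read.

#' Write a slice set to a dataset directory
#'
#' Images are written as 8-bit grayscale PNGs on the 0-255 scale (16-bit when
#' intensities are not integral), masks as binary PNGs, plus `manifest.csv`.
#'
#' @param set a [SliceSet-class].
#' @param dir output directory (created if missing).
#' @return the manifest data.frame, invisibly.
#' @export
writeSliceSet <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(length(set)), function(i) {
    r <- set[[i]]
    base <- sprintf("%s_%03d", r@patientId, r@sliceIndex)
    ip <- file.path(dir, paste0(base, "_img.png"))
    mp <- file.path(dir, paste0(base, "_mask.png"))
    img <- r@image
    if (all(img == round(img)) && max(img) <= 255 && min(img) >= 0) {
      png::writePNG(img / 255, ip)
    } else {
      rng <- range(img)
      png::writePNG((img - rng[1]) / max(rng[2] - rng[1], 1e-12), ip)
    }
    png::writePNG(r@mask, mp)
    data.frame(patient_id = r@patientId, slice_index = r@sliceIndex,
               image_path = basename(ip), mask_path = basename(mp))
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

readGray <- function(path) {
  x <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x
}

#' Read a dataset directory written by [writeSliceSet()]
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @param rescale255 multiply intensities back to the 0-255 scale (default
#'   TRUE; PNG decodes to 0-1).
#' @return a [SliceSet-class].
#' @export
readSliceSet <- function(dir, rescale255 = TRUE) {
  mf <- read.csv(file.path(dir, "manifest.csv"),
                 colClasses = c(patient_id = "character"))
  recs <- lapply(seq_len(nrow(mf)), function(i) {
    img <- readGray(file.path(dir, mf$image_path[i]))
    msk <- readGray(file.path(dir, mf$mask_path[i]))
    if (rescale255) img <- img * 255
    SliceRecord(mf$patient_id[i], mf$slice_index[i], img, (msk > 0.5) * 1)
  })
  SliceSet(recs)
}

#' DICOM series ingestion hook
#'
#' Converts a directory of DICOM files into [SliceRecord-class]s through a
#' caller-supplied reader, keeping the package free of a hard DICOM
#' dependency. The reader receives one file path and must return a list with
#' `pixels` (numeric matrix) and `patient_id` (string); slices are indexed in
#' file order. Masks are initialized empty and must be supplied by the
#' annotation workflow.
#'
#' @param dir directory containing a DICOM series.
#' @param reader function `(path) -> list(pixels, patient_id)`.
#' @param pattern filename pattern (default `"\\.dcm$"`).
#' @return a [SliceSet-class] with all-zero masks.
#' @export
readDicomSeries <- function(dir, reader, pattern = "\\.dcm$") {
  if (!is.function(reader)) {
    stop("readDicomSeries: a reader function must be supplied", call. = FALSE)
  }
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE,
                           ignore.case = TRUE))
  if (!length(files)) stop("readDicomSeries: no DICOM files found",
                           call. = FALSE)
  recs <- lapply(seq_along(files), function(i) {
    r <- reader(files[i])
    SliceRecord(r$patient_id, i - 1L, r$pixels, r$pixels * 0)
  })
  SliceSet(recs)
}
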