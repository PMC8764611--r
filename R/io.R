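#' CT slice in Hounsfield units
#'
#' @param pixels Square numeric matrix of HU values.
#' @param pixel_spacing_mm Length-1 or length-2 (row, col) spacing in mm.
#' @param slice_thickness_mm Slice thickness in mm.
#' @param subject_id,slice_index Identifiers.
#' @return Object of class `hu_slice`.
#' @export
hu_slice <- function(pixels, pixel_spacing_mm, slice_thickness_mm,
                     subject_id = NA_character_, slice_index = NA_integer_) {
  if (!is.matrix(pixels) || nrow(pixels) != ncol(pixels))
    stop_user("slice pixel grid must be a square matrix")
  if (length(pixel_spacing_mm) == 1)
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2)
  if (any(pixel_spacing_mm <= 0) || slice_thickness_mm <= 0)
    stop_user("pixel spacing and slice thickness must be positive")
  structure(list(pixels = pixels, pixel_spacing_mm = pixel_spacing_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 subject_id = subject_id, slice_index = as.integer(slice_index)),
            class = "hu_slice")
}

#' @export
print.hu_slice <- function(x, ...) {
  cat(sprintf("CT slice %s/%s: %d x %d px, %.2f x %.2f mm spacing, %.1f mm thick, HU range [%.0f, %.0f]\n",
              x$subject_id, x$slice_index, nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              x$slice_thickness_mm, min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Stored-value convention for the 16-bit container (HU = stored*slope + intercept)
CT_RESCALE_SLOPE <- 1
CT_RESCALE_INTERCEPT <- -1024

#' Write / read a CT slice as 16-bit TIFF plus JSON sidecar
#'
#' The pixel container is a 16-bit grayscale TIFF of stored values; the
#' JSON sidecar carries the rescale tags (`RescaleSlope`,
#' `RescaleIntercept`), `PixelSpacing` and `SliceThickness`, mirroring the
#' corresponding DICOM attributes. `read_ct_slice()` applies
#' HU = stored x slope + intercept and errors, naming the tag, when a
#' required tag is absent.
#'
#' @param slice An `hu_slice`.
#' @param path TIFF path (`.tif`); the sidecar is written next to it.
#' @return `write_ct_slice()` the path, invisibly; `read_ct_slice()` an
#'   `hu_slice` (round-trips exactly for integer HU in \[-1024, 64511\]).
#' @export
write_ct_slice <- function(slice, path) {
  stopifnot(inherits(slice, "hu_slice"))
  stored <- round((slice$pixels - CT_RESCALE_INTERCEPT) / CT_RESCALE_SLOPE)
  stored <- pmin(pmax(stored, 0), 65535)
  tiff::writeTIFF(stored / 65535, path, bits.per.sample = 16,
                  compression = "none")
  meta <- list(RescaleSlope = CT_RESCALE_SLOPE,
               RescaleIntercept = CT_RESCALE_INTERCEPT,
               PixelSpacing = slice$pixel_spacing_mm,
               SliceThickness = slice$slice_thickness_mm,
               SubjectID = slice$subject_id,
               SliceIndex = slice$slice_index)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' @rdname write_ct_slice
#' @export
read_ct_slice <- function(path) {
  if (!file.exists(path)) stop_user("no such slice file: ", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop_user("missing metadata sidecar: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (tag in c("RescaleSlope", "RescaleIntercept", "PixelSpacing",
                "SliceThickness"))
    if (is.null(meta[[tag]]))
      stop_user("required tag `", tag, "` missing from ", sc)
  stored <- round(tiff::readTIFF(path) * 65535)
  if (nrow(stored) != ncol(stored))
    stop_user("slice pixel grid is not square: ", nrow(stored), " x ", ncol(stored))
  hu_slice(stored * meta$RescaleSlope + meta$RescaleIntercept,
           meta$PixelSpacing, meta$SliceThickness,
           meta$SubjectID %||% NA_character_,
           meta$SliceIndex %||% NA_integer_)
}

#' Write / read a binary mask as 8-bit PNG
#'
#' Positive pixels are stored as 255, background as 0.
#'
#' @param mask 0/1 matrix.
#' @param path PNG path.
#' @return The path / a 0/1 integer matrix.
#' @export
write_mask <- function(mask, path) {
  check_binary(mask)
  png::writePNG(mask + 0, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  out <- (m >= 0.5) + 0L
  dim(out) <- dim(m)
  out
}

#' Write a phantom dataset to disk
#'
#' Layout: `slices/<subject>_<index>.tif` (+ `.json` sidecar),
#' `masks/<subject>_<index>.png`, and `manifest.csv` with relative paths
#' and per-slice `has_ascites` flags.
#'
#' @param dataset A `phantom_dataset`.
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  dir.create(file.path(dir, "slices"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  m <- dataset$manifest
  m$slice_path <- sprintf("slices/%s_%03d.tif", m$subject_id, m$slice_index)
  m$mask_path <- sprintf("masks/%s_%03d.png", m$subject_id, m$slice_index)
  for (i in seq_len(nrow(m))) {
    write_ct_slice(dataset$slices[[i]], file.path(dir, m$slice_path[i]))
    write_mask(dataset$masks[[i]], file.path(dir, m$mask_path[i]))
  }
  write.csv(m, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(m)
}

#' Load a phantom dataset written by [write_dataset()]
#'
#' @param dir Dataset directory containing `manifest.csv`.
#' @return A `phantom_dataset`.
#' @export
load_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop_user("no manifest.csv in ", dir,
                                  " - not a dataset directory?")
  m <- read.csv(mf, stringsAsFactors = FALSE)
  slices <- lapply(file.path(dir, m$slice_path), read_ct_slice)
  masks <- lapply(file.path(dir, m$mask_path), read_mask)
  structure(list(manifest = m[, c("subject_id", "slice_index", "group",
                                  "has_ascites")],
                 slices = slices, masks = masks,
                 class_counts = table(m$has_ascites),
                 spec_template = NULL),
            class = "phantom_dataset")
}
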