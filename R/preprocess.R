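#' Abdomen display window
#'
#' @param width Window width in HU (> 0), default 400.
#' @param level Window level (center) in HU, default 60. The defaults clip
#'   HU to \[-140, 260\] before normalising to \[0, 1\].
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(width = 400, level = 60) {
  if (width <= 0) stop_user("window `width` must be positive")
  structure(list(width = width, level = level), class = "window_spec")
}

#' Window-normalise HU values to \[0, 1\]
#'
#' out = clip((HU - (level - width/2)) / width, 0, 1). Monotone
#' non-decreasing in HU; with the abdomen defaults, -140 HU maps to 0,
#' the level (60 HU) to 0.5 and 260 HU to 1.
#'
#' @param slice An `hu_slice` or a numeric matrix of HU values.
#' @param window A [window_spec()].
#' @return Numeric matrix in \[0, 1\].
#' @export
apply_window <- function(slice, window = window_spec()) {
  stopifnot(inherits(window, "window_spec"))
  hu <- if (inherits(slice, "hu_slice")) slice$pixels else slice
  pmin(pmax((hu - (window$level - window$width / 2)) / window$width, 0), 1)
}

#' Down-sample an image grid by bilinear interpolation
#'
#' Center-aligned bilinear resampling; output values stay within the input
#' range. Up-sizing is rejected (the pipeline only ever reduces the
#' acquisition grid to the model grid).
#'
#' @param grid Numeric matrix.
#' @param target Target side length in pixels.
#' @return `target` x `target` matrix.
#' @export
resize_image <- function(grid, target) {
  n <- nrow(grid)
  if (target > n) stop_user("up-sizing (", n, " -> ", target, ") is not supported")
  if (target == n) return(grid)
  EBImage::imageData(EBImage::resize(EBImage::Image(grid), w = target,
                                     h = target, filter = "bilinear",
                                     antialias = FALSE))
}

#' Down-sample a binary mask by nearest-neighbour
#'
#' Nearest-neighbour keeps the mask strictly binary.
#'
#' @param mask 0/1 matrix.
#' @param target Target side length in pixels.
#' @return 0/1 integer matrix of size `target` x `target`.
#' @export
resize_mask <- function(mask, target) {
  check_binary(mask)
  n <- nrow(mask)
  if (target > n) stop_user("up-sizing (", n, " -> ", target, ") is not supported")
  if (target == n) return(mask + 0L)
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(mask + 0),
                                            w = target, h = target,
                                            filter = "none"))
  o <- (out >= 0.5) + 0L
  dim(o) <- dim(out)
  o
}

#' Replicate a windowed grid into the 3-channel model input
#'
#' The network consumes H x W x 3 tensors; single CT slices are fed as
#' three identical grayscale channels.
#'
#' @param windowed Matrix in \[0, 1\].
#' @return H x W x 3 array, channels identical.
#' @export
to_model_input <- function(windowed) {
  if (any(windowed < 0 | windowed > 1))
    stop_user("model inputs must lie in [0, 1]; window the slice first")
  array(windowed, dim = c(dim(windowed), 3))
}

#' Augmentation settings
#'
#' @param rotation_range_deg Length-2 rotation range in degrees, symmetric
#'   about 0; default c(-10, 10).
#' @param allow_horizontal_flip,allow_vertical_flip Enable flips (each
#'   applied independently with probability 0.5).
#' @param seed Seed used by [balance_and_augment()] for its draw stream.
#' @return Object of class `augment_spec`.
#' @export
augment_spec <- function(rotation_range_deg = c(-10, 10),
                         allow_horizontal_flip = TRUE,
                         allow_vertical_flip = TRUE, seed = 1L) {
  if (length(rotation_range_deg) != 2 ||
      !isTRUE(all.equal(rotation_range_deg[1], -rotation_range_deg[2])))
    stop_user("rotation range must be symmetric about 0")
  structure(list(rotation_range_deg = rotation_range_deg,
                 allow_horizontal_flip = allow_horizontal_flip,
                 allow_vertical_flip = allow_vertical_flip,
                 seed = as.integer(seed)),
            class = "augment_spec")
}

#' Randomly transform a paired image and mask
#'
#' Draws one transform — rotation angle uniform over the configured range,
#' then horizontal/vertical flips each with probability 0.5 where allowed —
#' and applies the identical transform to image and mask. Images are
#' rotated with bilinear interpolation, masks are re-binarised at 0.5 after
#' rotation; out-of-frame pixels are filled with 0 (the windowed value of
#' air). Draws come from the session RNG; seed externally for
#' reproducibility.
#'
#' @param image H x W x 3 array (or H x W matrix) in \[0, 1\].
#' @param mask H x W binary mask of the same spatial size.
#' @param spec An [augment_spec()].
#' @return List with transformed `image`, `mask`, and the realised draw
#'   (`angle`, `hflip`, `vflip`).
#' @export
augment_pair <- function(image, mask, spec = augment_spec()) {
  sp_img <- dim(image)[1:2]
  if (!identical(as.integer(sp_img), as.integer(dim(mask)[1:2])))
    stop_user("image and mask spatial sizes differ")
  angle <- runif(1, spec$rotation_range_deg[1], spec$rotation_range_deg[2])
  hflip <- spec$allow_horizontal_flip && runif(1) < 0.5
  vflip <- spec$allow_vertical_flip && runif(1) < 0.5

  rot <- function(m, filter) {
    if (angle == 0) return(m)
    EBImage::imageData(EBImage::rotate(EBImage::Image(m), angle,
                                       filter = filter,
                                       output.dim = rev(sp_img), bg.col = 0))
  }
  tx_mat <- function(m, filter) {
    m <- rot(m, filter)
    if (hflip) m <- m[, rev(seq_len(ncol(m)))]
    if (vflip) m <- m[rev(seq_len(nrow(m))), ]
    m
  }
  img_out <- if (length(dim(image)) == 3) {
    out <- image
    for (c in seq_len(dim(image)[3])) out[, , c] <- tx_mat(image[, , c], "bilinear")
    out
  } else tx_mat(image, "bilinear")
  mk <- tx_mat(mask + 0, "bilinear")
  mk <- (mk >= 0.5) + 0L
  dim(mk) <- sp_img
  list(image = img_out, mask = mk, angle = angle, hflip = hflip, vflip = vflip)
}

#' Preprocess a phantom dataset into model tensors
#'
#' Applies the abdomen window, resizes images (bilinear) and masks
#' (nearest-neighbour) to the model grid, and stacks them into the
#' activation layout used by the network.
#'
#' @param dataset A `phantom_dataset`.
#' @param window A [window_spec()].
#' @param target_size Model grid side (must not exceed the acquisition
#'   grid).
#' @return Object of class `seg_data`: `x` (S x S x N x 3), `y`
#'   (S x S x N x 1), `manifest`, plus spacing/thickness metadata and
#'   `source_grid` for volume scaling.
#' @export
preprocess_dataset <- function(dataset, window = window_spec(),
                               target_size = 256) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  n <- nrow(dataset$manifest)
  if (n == 0) stop_user("dataset is empty")
  src <- nrow(dataset$slices[[1]]$pixels)
  x <- array(0, dim = c(target_size, target_size, n, 3))
  y <- array(0, dim = c(target_size, target_size, n, 1))
  for (i in seq_len(n)) {
    w <- resize_image(apply_window(dataset$slices[[i]], window), target_size)
    x[, , i, ] <- to_model_input(w)
    y[, , i, 1] <- resize_mask(dataset$masks[[i]], target_size)
  }
  structure(list(x = x, y = y, manifest = dataset$manifest,
                 pixel_spacing_mm = dataset$slices[[1]]$pixel_spacing_mm,
                 slice_thickness_mm = dataset$slices[[1]]$slice_thickness_mm,
                 source_grid = src),
            class = "seg_data")
}

#' Save / load preprocessed tensors
#'
#' Writes the model-ready tensor stack (`tensors.rds`, a compressed archive
#' of the `x`/`y` arrays with their metadata) together with a plain-text
#' `manifest.csv` for inspection.
#'
#' @param data A `seg_data` set.
#' @param dir Directory to write into (created if needed).
#' @return The directory / a `seg_data` set.
#' @export
save_seg_data <- function(data, dir) {
  stopifnot(inherits(data, "seg_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(unclass(data), file.path(dir, "tensors.rds"))
  write.csv(data$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_seg_data
#' @export
load_seg_data <- function(dir) {
  path <- file.path(dir, "tensors.rds")
  if (!file.exists(path))
    stop_user("no tensors.rds in ", dir, " - not a preprocessed-data directory?")
  structure(readRDS(path), class = "seg_data")
}

#' @export
print.seg_data <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("Preprocessed set: %d slices at %d x %d x %d; %d with ascites\n",
              d[3], d[1], d[2], d[4], sum(x$manifest$has_ascites)))
  invisible(x)
}

subset_seg_data <- function(data, idx) {
  structure(list(x = data$x[, , idx, , drop = FALSE],
                 y = data$y[, , idx, , drop = FALSE],
                 manifest = data$manifest[idx, , drop = FALSE],
                 pixel_spacing_mm = data$pixel_spacing_mm,
                 slice_thickness_mm = data$slice_thickness_mm,
                 source_grid = data$source_grid),
            class = "seg_data")
}

#' Balance the two classes by augmented over-sampling
#'
#' Keeps every original slice and appends augmented copies (drawn with
#' replacement from the originals of the class, transformed by
#' [augment_pair()]) until each class — ascites and fluid-free — holds
#' exactly `target_per_class` entries. Deterministic given `spec$seed`.
#'
#' @param data A `seg_data` set.
#' @param target_per_class Entries per class after balancing; must be at
#'   least each original class size (originals are never discarded).
#' @param spec An [augment_spec()].
#' @return A `seg_data` set with 2 x `target_per_class` entries; appended
#'   rows are flagged in `manifest$augmented`.
#' @export
balance_and_augment <- function(data, target_per_class, spec = augment_spec()) {
  stopifnot(inherits(data, "seg_data"))
  cls <- data$manifest$has_ascites
  n_pos <- sum(cls); n_neg <- sum(!cls)
  if (n_pos == 0 || n_neg == 0)
    stop_user("both classes must be non-empty to balance")
  if (target_per_class < max(n_pos, n_neg))
    stop_user("`target_per_class` (", target_per_class,
              ") is below an original class size (", max(n_pos, n_neg),
              "); originals are never discarded")
  S <- dim(data$x)[1]
  n_extra <- 2 * target_per_class - n_pos - n_neg
  x <- array(0, dim = c(S, S, 2 * target_per_class, 3))
  y <- array(0, dim = c(S, S, 2 * target_per_class, 1))
  n0 <- n_pos + n_neg
  x[, , seq_len(n0), ] <- data$x
  y[, , seq_len(n0), ] <- data$y
  manifest <- data$manifest
  manifest$augmented <- FALSE
  if (n_extra > 0) {
    src <- withr::with_seed(spec$seed, {
      c(sample(which(cls), target_per_class - n_pos, replace = TRUE),
        sample(which(!cls), target_per_class - n_neg, replace = TRUE))
    })
    withr::with_seed(spec$seed + 1L, {
      for (j in seq_along(src)) {
        aug <- augment_pair(data$x[, , src[j], ], data$y[, , src[j], 1], spec)
        x[, , n0 + j, ] <- aug$image
        y[, , n0 + j, 1] <- aug$mask
      }
    })
    extra <- data$manifest[src, , drop = FALSE]
    extra$augmented <- TRUE
    manifest <- rbind(manifest, extra)
    rownames(manifest) <- NULL
  }
  structure(list(x = x, y = y, manifest = manifest,
                 pixel_spacing_mm = data$pixel_spacing_mm,
                 slice_thickness_mm = data$slice_thickness_mm,
                 source_grid = data$source_grid),
            class = "seg_data")
}

#' Split a phantom dataset into training and testing partitions
#'
#' The split is by subject — no subject contributes slices to both sides —
#' and stratified on subject class (a subject is an ascites subject when
#' any of its slices carries fluid). Deterministic given `seed`.
#'
#' @param dataset A `phantom_dataset`.
#' @param ratio Fraction of subjects per class assigned to training,
#'   in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @return List with `train` and `test` phantom datasets.
#' @export
split_train_test <- function(dataset, ratio = 0.8, seed = 1L) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  if (ratio <= 0 || ratio >= 1) stop_user("`ratio` must be in (0, 1)")
  m <- dataset$manifest
  sub_cls <- tapply(m$has_ascites, m$subject_id, any)
  subjects <- names(sub_cls)
  train_sub <- withr::with_seed(seed, {
    unlist(lapply(c(TRUE, FALSE), function(cl) {
      s <- subjects[sub_cls == cl]
      if (length(s) < 2)
        stop_user("need at least 2 subjects per class to split (",
                  if (cl) "ascites" else "control", " has ", length(s), ")")
      k <- min(max(round(ratio * length(s)), 1), length(s) - 1)
      sample(s, k)
    }))
  })
  subset_phantom <- function(idx) {
    structure(list(manifest = m[idx, , drop = FALSE],
                   slices = dataset$slices[idx],
                   masks = dataset$masks[idx],
                   class_counts = table(m$has_ascites[idx]),
                   spec_template = dataset$spec_template),
              class = "phantom_dataset")
  }
  in_train <- m$subject_id %in% train_sub
  list(train = subset_phantom(which(in_train)),
       test = subset_phantom(which(!in_train)))
}
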