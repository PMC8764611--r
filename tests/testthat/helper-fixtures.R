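# Small in-code fixtures shared across test files.

# A fast low-resolution phantom spec (noiseless unless asked otherwise)
tiny_spec <- function(grid = 64, noise = 0, seed = 1L, ...) {
  phantom_spec(grid_size = grid, noise_sd_hu = noise, seed = seed, ...)
}

# Random binary mask helper
rand_mask <- function(n = 8, p = 0.4) {
  matrix(rbinom(n * n, 1, p), n, n)
}

# Exhaustive set-based IoU oracle (independent of the package routine):
# enumerate pixel index sets and use length(intersect)/length(union).
iou_oracle <- function(pred, truth) {
  ps <- which(pred != 0); ts <- which(truth != 0)
  if (length(ts) == 0) return(if (length(ps) == 0) 1 else 0)
  length(intersect(ps, ts)) / length(union(ps, ts))
}

# Pair-concordance AUROC oracle with half-credit for ties.
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# A tiny learnable segmentation problem: bright square blobs on dark
# background; masks mark the blobs. Returned as a seg_data object.
toy_seg_data <- function(n = 12, size = 16, seed = 1) {
  withr::with_seed(seed, {
    x <- array(0, c(size, size, n, 3))
    y <- array(0, c(size, size, n, 1))
    has <- rep(c(TRUE, FALSE), length.out = n)
    for (i in seq_len(n)) {
      img <- matrix(runif(size * size, 0, 0.2), size, size)
      if (has[i]) {
        r0 <- sample(2:(size - 6), 1); c0 <- sample(2:(size - 6), 1)
        img[r0:(r0 + 4), c0:(c0 + 4)] <- runif(25, 0.8, 1)
        y[r0:(r0 + 4), c0:(c0 + 4), i, 1] <- 1
      }
      x[, , i, ] <- array(img, c(size, size, 3))
    }
    structure(list(x = x, y = y,
                   manifest = data.frame(
                     subject_id = sprintf("T%02d", seq_len(n)),
                     slice_index = 1L, group = ifelse(has, "ascites", "control"),
                     has_ascites = has),
                   pixel_spacing_mm = c(1, 1), slice_thickness_mm = 5,
                   source_grid = size),
              class = "seg_data")
  })
}
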