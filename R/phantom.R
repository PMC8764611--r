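#' Specification of a synthetic abdominal CT phantom slice
#'
#' The phantom emulates a contrast-enhanced axial abdominopelvic CT slice:
#' an elliptical body on an air background, HU-calibrated tissue analogues
#' (subcutaneous fat, muscle wall, liver, bowel, bone), near-water ascites
#' pockets collecting in dependent recesses (flanks, pelvis), and optional
#' fluid-filled confounders — a distended urinary bladder and an ovarian
#' cyst larger than 3 cm — whose HU range overlaps the ascites range, so
#' that intensity alone cannot separate them and shape must carry the
#' signal.
#'
#' @param grid_size Pixels per side (square grid), default 512.
#' @param pixel_spacing_mm mm per pixel; default scales 0.74 mm at 512
#'   (a 38 cm field of view) to the requested grid.
#' @param slice_thickness_mm Slice thickness in mm, default 5.
#' @param body_axes_px Semi-axes of the body ellipse in pixels.
#' @param organ_templates List of regions with `hu_mean`/`hu_sd`; default
#'   [default_organs()].
#' @param ascites_pockets List of pocket regions, each with an `hu_range`
#'   within \[-10, 30\] (near water). See [pocket_ellipse()],
#'   [pocket_crescent()], [pocket_rect()].
#' @param confounders List with optional elements `bladder` and `cyst`
#'   (regions with `hu_range`); see [confounder_bladder()],
#'   [confounder_cyst()].
#' @param noise_sd_hu Additive Gaussian noise scale in HU, default 12
#'   (typical abdominal CT noise); set 0 for a noiseless phantom.
#' @param seed Integer seed; a given spec generates a bit-identical slice.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = 512,
                         pixel_spacing_mm = 0.74 * 512 / grid_size,
                         slice_thickness_mm = 5,
                         body_axes_px = c(0.44, 0.36) * grid_size,
                         organ_templates = default_organs(grid_size),
                         ascites_pockets = list(),
                         confounders = list(),
                         noise_sd_hu = 12,
                         seed = 1L) {
  spec <- structure(list(grid_size = as.integer(grid_size),
                         pixel_spacing_mm = pixel_spacing_mm,
                         slice_thickness_mm = slice_thickness_mm,
                         body_axes_px = body_axes_px,
                         organ_templates = organ_templates,
                         ascites_pockets = ascites_pockets,
                         confounders = confounders,
                         noise_sd_hu = noise_sd_hu,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

ASCITES_HU_BOUNDS <- c(-10, 30)

validate_phantom_spec <- function(spec) {
  if (spec$grid_size <= 0) stop_user("`grid_size` must be positive")
  if (spec$pixel_spacing_mm <= 0 || spec$slice_thickness_mm <= 0)
    stop_user("pixel spacing and slice thickness must be positive")
  hu_means <- vapply(spec$organ_templates, `[[`, numeric(1), "hu_mean")
  if (any(hu_means < -1000 | hu_means > 2000))
    stop_user("organ HU means must lie in [-1000, 2000]")
  for (p in spec$ascites_pockets) {
    if (is.null(p$hu_range) || p$hu_range[1] < ASCITES_HU_BOUNDS[1] ||
        p$hu_range[2] > ASCITES_HU_BOUNDS[2])
      stop_user("ascites pocket HU range must lie within [-10, 30]")
  }
  for (cf in spec$confounders) {
    if (cf$hu_range[1] > ASCITES_HU_BOUNDS[2] ||
        cf$hu_range[2] < ASCITES_HU_BOUNDS[1])
      stop_user("confounder fluid HU range must overlap the ascites range")
  }
  invisible(spec)
}

# Regions are analytic; rasterization tests pixel-center membership, with no
# boundary anti-aliasing, so pixel counts and areas are exact and testable.

#' Analytic region primitives
#'
#' Regions describe phantom anatomy in continuous pixel coordinates
#' (x = column, y = row, both 1-based at pixel centers). `region_raster()`
#' rasterises a region onto a square grid by pixel-center membership with
#' no anti-aliasing, so counts are exact.
#'
#' @param cx,cy Center; `a,b` ellipse semi-axes; `r`, `r1`, `r2` radii;
#'   `theta1,theta2` angular range (radians, y-down convention);
#'   `x0,x1,y0,y1` inclusive rectangle bounds.
#' @param region A region object.
#' @param grid_size Raster side length in pixels.
#' @return A region object; for `region_raster()` a logical matrix.
#' @name regions
NULL

#' @rdname regions
#' @export
region_ellipse <- function(cx, cy, a, b) {
  list(type = "ellipse", cx = cx, cy = cy, a = a, b = b)
}

#' @rdname regions
#' @export
region_circle <- function(cx, cy, r) region_ellipse(cx, cy, r, r)

#' @rdname regions
#' @export
region_annulus_sector <- function(cx, cy, r1, r2, theta1, theta2) {
  list(type = "annulus_sector", cx = cx, cy = cy, r1 = r1, r2 = r2,
       theta1 = theta1, theta2 = theta2)
}

#' @rdname regions
#' @export
region_rect <- function(x0, x1, y0, y1) {
  list(type = "rect", x0 = x0, x1 = x1, y0 = y0, y1 = y1)
}

#' @rdname regions
#' @export
region_raster <- function(region, grid_size) {
  x <- matrix(seq_len(grid_size), grid_size, grid_size, byrow = TRUE)
  y <- matrix(seq_len(grid_size), grid_size, grid_size)
  switch(region$type,
    ellipse = ((x - region$cx) / region$a)^2 +
              ((y - region$cy) / region$b)^2 <= 1,
    annulus_sector = {
      dx <- x - region$cx; dy <- y - region$cy
      r <- sqrt(dx^2 + dy^2)
      th <- atan2(dy, dx)
      # rotate so theta1 maps to 0, widths < 2*pi handled modulo 2*pi
      w <- (th - region$theta1) %% (2 * pi)
      r >= region$r1 & r <= region$r2 &
        w <= ((region$theta2 - region$theta1) %% (2 * pi))
    },
    rect = x >= region$x0 & x <= region$x1 & y >= region$y0 & y <= region$y1,
    stop_user("unknown region type: ", region$type))
}

#' Analytic area of a phantom region, in pixels^2
#'
#' Exact continuous area of the region (ellipse: pi a b; annulus sector:
#' (r2^2 - r1^2) dtheta / 2; rectangle: width x height of the pixel-center
#' raster). Used to check volume recovery against construction.
#'
#' @param region A region as stored in a pocket/confounder.
#' @return Area in squared pixels.
#' @export
region_area_px <- function(region) {
  switch(region$type,
    ellipse = pi * region$a * region$b,
    annulus_sector = 0.5 * (region$r2^2 - region$r1^2) *
      ((region$theta2 - region$theta1) %% (2 * pi)),
    rect = (region$x1 - region$x0 + 1) * (region$y1 - region$y0 + 1),
    stop_user("unknown region type: ", region$type))
}

#' Default tissue analogues for the phantom body
#'
#' Mean HU values follow typical contrast-enhanced abdominal CT: fat about
#' -100, muscle about 45, enhancing liver about 90, bowel about 20 with
#' gas pockets near -650, vertebral bone about 500. `hu_sd` is a per-slice
#' jitter of the organ mean, not pixel noise.
#'
#' @param grid_size Phantom grid size in pixels.
#' @return List of organ template regions.
#' @export
default_organs <- function(grid_size) {
  g <- grid_size; c0 <- (g + 1) / 2
  list(
    list(region = region_ellipse(c0 - 0.16 * g, c0 - 0.12 * g, 0.20 * g, 0.16 * g),
         hu_mean = 90, hu_sd = 8, name = "liver"),
    list(region = region_ellipse(c0 + 0.14 * g, c0 - 0.05 * g, 0.13 * g, 0.15 * g),
         hu_mean = 20, hu_sd = 10, name = "bowel"),
    list(region = region_circle(c0 + 0.12 * g, c0 - 0.02 * g, 0.035 * g),
         hu_mean = -650, hu_sd = 30, name = "bowel_gas"),
    list(region = region_circle(c0, c0 + 0.24 * g, 0.055 * g),
         hu_mean = 500, hu_sd = 40, name = "spine"))
}

#' Ascites pocket constructors
#'
#' `pocket_crescent()` builds an annular-sector pocket hugging the body
#' wall (where free fluid layers in dependent recesses), `pocket_ellipse()`
#' a blob pocket, `pocket_rect()` an axis-aligned pocket with an exact
#' pixel count (useful for arithmetic checks).
#'
#' @param cx,cy Center in pixels.
#' @param r1,r2 Inner/outer radius (crescent).
#' @param theta1,theta2 Angular range in radians, measured clockwise from
#'   the +x axis in image coordinates (y grows downwards).
#' @param a,b Ellipse semi-axes.
#' @param x0,x1,y0,y1 Rectangle bounds (inclusive, pixel indices).
#' @param hu_range Length-2 HU range of the fluid, within \[-10, 30\].
#' @return A pocket object.
#' @name pockets
NULL

#' @rdname pockets
#' @export
pocket_crescent <- function(cx, cy, r1, r2, theta1, theta2,
                            hu_range = c(0, 25)) {
  list(region = region_annulus_sector(cx, cy, r1, r2, theta1, theta2),
       hu_range = hu_range)
}

#' @rdname pockets
#' @export
pocket_ellipse <- function(cx, cy, a, b, hu_range = c(0, 25)) {
  list(region = region_ellipse(cx, cy, a, b), hu_range = hu_range)
}

#' @rdname pockets
#' @export
pocket_rect <- function(x0, x1, y0, y1, hu_range = c(0, 25)) {
  list(region = region_rect(x0, x1, y0, y1), hu_range = hu_range)
}

#' Confounder constructors
#'
#' A fully distended urinary bladder (large midline fluid ellipse in the
#' pelvis) and an ovarian cyst with diameter above 3 cm: fluid-filled
#' structures whose attenuation is indistinguishable from ascites. They are
#' painted into the slice but never into the ground-truth mask.
#'
#' @param grid_size Phantom grid size.
#' @param pixel_spacing_mm mm per pixel (the cyst diameter must exceed
#'   3 cm in mm, not pixels).
#' @param cx,cy Optional center override, pixels.
#' @param hu_range Fluid HU range; must overlap \[-10, 30\].
#' @return A confounder region object.
#' @name confounders
NULL

#' @rdname confounders
#' @export
confounder_bladder <- function(grid_size, cx = NULL, cy = NULL,
                               hu_range = c(2, 18)) {
  g <- grid_size; c0 <- (g + 1) / 2
  list(region = region_ellipse(cx %||% c0, cy %||% (c0 + 0.17 * g),
                               0.13 * g, 0.10 * g),
       hu_range = hu_range, name = "bladder")
}

#' @rdname confounders
#' @export
confounder_cyst <- function(grid_size, pixel_spacing_mm, cx = NULL, cy = NULL,
                            hu_range = c(4, 20)) {
  g <- grid_size; c0 <- (g + 1) / 2
  r_px <- max(17 / pixel_spacing_mm, 0.033 * g)  # radius > 1.5 cm
  list(region = region_circle(cx %||% (c0 - 0.20 * g), cy %||% (c0 + 0.14 * g),
                              r_px),
       hu_range = hu_range, name = "cyst")
}

# --- slice generation ------------------------------------------------------

#' Generate one phantom slice and its ground-truth ascites mask
#'
#' Paints, in order: air background (-1000 HU), body fat, muscle wall,
#' organ analogues, confounder fluid, then ascites pockets; adds Gaussian
#' HU noise last. The mask marks exactly the ascites pockets — confounder
#' fluid is deliberately unmasked. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @param subject_id,slice_index Identifiers stamped on the slice.
#' @return List with `slice` (an `hu_slice`) and `mask` (0/1 matrix).
#' @export
generate_slice <- function(spec, subject_id = "S1", slice_index = 1L) {
  validate_phantom_spec(spec)
  g <- spec$grid_size
  withr::with_seed(spec$seed, {
    hu <- matrix(-1000, g, g)
    c0 <- (g + 1) / 2
    body <- region_raster(region_ellipse(c0, c0, spec$body_axes_px[1],
                                         spec$body_axes_px[2]), g)
    inner <- region_raster(region_ellipse(c0, c0, 0.93 * spec$body_axes_px[1],
                                          0.93 * spec$body_axes_px[2]), g)
    hu[body] <- 45 + rnorm(1, 0, 5)     # muscle wall
    hu[inner] <- -100 + rnorm(1, 0, 5)  # visceral/subcutaneous fat
    for (org in spec$organ_templates) {
      r <- region_raster(org$region, g)
      hu[r] <- org$hu_mean + rnorm(1, 0, org$hu_sd)
    }
    for (cf in spec$confounders) {
      r <- region_raster(cf$region, g)
      hu[r] <- runif(sum(r), cf$hu_range[1], cf$hu_range[2])
    }
    mask <- matrix(0L, g, g)
    for (p in spec$ascites_pockets) {
      r <- region_raster(p$region, g)
      if (any(r & !body))
        stop_user("ascites pocket extends outside the body ellipse")
      hu[r] <- runif(sum(r), p$hu_range[1], p$hu_range[2])
      mask[r] <- 1L
    }
    if (spec$noise_sd_hu > 0)
      hu <- hu + matrix(rnorm(g * g, 0, spec$noise_sd_hu), g, g)
    list(slice = hu_slice(hu, spec$pixel_spacing_mm, spec$slice_thickness_mm,
                          subject_id, slice_index),
         mask = mask)
  })
}

#' Generate a phantom dataset of subjects and slices
#'
#' Ascites subjects receive randomized crescent/blob pockets (at least one
#' slice with a pocket is guaranteed); control subjects receive none.
#' Confounders (bladder, ovarian cyst) appear in both groups with fixed
#' prevalence, so controls contain fluid-intensity pixels that must not be
#' segmented. Deterministic given `seed`.
#'
#' @param n_subjects_ascites,n_subjects_control Subject counts.
#' @param slices_per_subject Slices per subject.
#' @param spec_template A [phantom_spec()] providing grid, organs, noise.
#' @param seed Integer seed for all randomized geometry.
#' @param p_bladder,p_cyst Per-subject confounder prevalence (defaults 0.4
#'   and 0.25, both groups).
#' @param p_pocket_slice Probability that a given slice of an ascites
#'   subject carries fluid (first slice always does), default 0.85.
#' @return Object of class `phantom_dataset`: `manifest` data frame
#'   (subject_id, slice_index, group, has_ascites), `slices`, `masks`,
#'   `class_counts`, `spec_template`.
#' @export
generate_dataset <- function(n_subjects_ascites, n_subjects_control,
                             slices_per_subject, spec_template, seed = 1L,
                             p_bladder = 0.4, p_cyst = 0.25,
                             p_pocket_slice = 0.85) {
  if (n_subjects_ascites < 0 || n_subjects_control < 0 ||
      n_subjects_ascites + n_subjects_control <= 0)
    stop_user("subject counts must be positive")
  if (slices_per_subject <= 0) stop_user("`slices_per_subject` must be positive")
  g <- spec_template$grid_size
  n_sub <- n_subjects_ascites + n_subjects_control
  n_total <- n_sub * slices_per_subject

  plan <- withr::with_seed(seed, {
    lapply(seq_len(n_sub), function(s) {
      ascites <- s <= n_subjects_ascites
      cfs <- list()
      if (runif(1) < p_bladder)
        cfs$bladder <- confounder_bladder(
          g, cx = (g + 1) / 2 + runif(1, -0.03, 0.03) * g,
          cy = (g + 1) / 2 + (0.17 + runif(1, -0.03, 0.03)) * g)
      if (runif(1) < p_cyst)
        cfs$cyst <- confounder_cyst(
          g, spec_template$pixel_spacing_mm,
          cx = (g + 1) / 2 + runif(1, -0.26, -0.14) * g,
          cy = (g + 1) / 2 + runif(1, 0.08, 0.20) * g)
      pockets <- lapply(seq_len(slices_per_subject), function(k) {
        if (!ascites) return(list())
        if (k > 1 && runif(1) > p_pocket_slice) return(list())
        random_pockets(g)
      })
      list(ascites = ascites, confounders = cfs, pockets = pockets,
           slice_seeds = sample.int(2147483646L, slices_per_subject))
    })
  })

  slices <- vector("list", n_total); masks <- vector("list", n_total)
  manifest <- data.frame(subject_id = character(n_total),
                         slice_index = integer(n_total),
                         group = character(n_total),
                         has_ascites = logical(n_total))
  i <- 0
  for (s in seq_len(n_sub)) {
    sid <- sprintf("S%03d", s)
    for (k in seq_len(slices_per_subject)) {
      i <- i + 1
      spec <- spec_template
      spec$seed <- plan[[s]]$slice_seeds[k]
      spec$confounders <- plan[[s]]$confounders
      spec$ascites_pockets <- plan[[s]]$pockets[[k]]
      out <- generate_slice(spec, subject_id = sid, slice_index = k)
      slices[[i]] <- out$slice; masks[[i]] <- out$mask
      manifest$subject_id[i] <- sid
      manifest$slice_index[i] <- k
      manifest$group[i] <- if (plan[[s]]$ascites) "ascites" else "control"
      manifest$has_ascites[i] <- any(out$mask != 0)
    }
  }
  structure(list(manifest = manifest, slices = slices, masks = masks,
                 class_counts = table(manifest$has_ascites),
                 spec_template = spec_template),
            class = "phantom_dataset")
}

# 1-3 pockets per slice: flank crescents plus occasional pelvic blob,
# sized so small/moderate/large amounts all occur (the strata are arbitrary)
random_pockets <- function(g) {
  c0 <- (g + 1) / 2
  n <- sample(1:3, 1)
  base_r <- 0.36 * g * 0.93  # just inside the muscle wall at the minor axis
  centers_th <- c(0.35 * pi, 0.65 * pi, 0.08 * pi, 0.92 * pi)  # pelvis + flanks
  th0 <- sample(centers_th, n)
  lapply(seq_len(n), function(j) {
    width <- runif(1, 0.25, 0.7)                 # radians
    r2 <- base_r * runif(1, 0.9, 0.99)
    r1 <- r2 - runif(1, 0.04, 0.12) * g
    pocket_crescent(c0, c0, r1, r2, th0[j] - width / 2, th0[j] + width / 2,
                    hu_range = c(0, 25))
  })
}

#' @export
print.phantom_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Phantom CT dataset: %d slices / %d subjects (%d x %d px)\n",
              nrow(m), length(unique(m$subject_id)),
              x$spec_template$grid_size, x$spec_template$grid_size))
  cat(sprintf("  slices with ascites: %d; fluid-free: %d\n",
              sum(m$has_ascites), sum(!m$has_ascites)))
  invisible(x)
}
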