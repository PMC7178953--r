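# Synthetic transverse finger-ultrasound phantoms: an elliptical
# hyperechoic tendon above a bright volar-plate band, surrounded by a
# hypoechoic synovial-sheath ring, on a textured background with
# multiplicative Rayleigh speckle. A controllable intensity step across
# the tendon's bottom boundary drives the clear/fuzzy appearance, so the
# clear/fuzzy window classifier can be exercised without clinical data.

#' Specification of one synthetic phantom
#'
#' Geometry is given in pixels on an `image_size = (H, W)` grid; the
#' defaults draw nothing random -- randomization happens in
#' [generate_dataset()]. Intensities are 8-bit (0..255).
#'
#' @param image_size `(height, width)` in pixels.
#' @param tendon_center `(row, col)` of the tendon ellipse center.
#' @param tendon_axes `(semi_row, semi_col)` ellipse semi-axes in px.
#' @param sheath_thickness thickness of the sheath ring around the
#'   tendon, px.
#' @param plate_gap gap between the sheath outer boundary and the volar
#'   plate band, px.
#' @param plate_thickness thickness of the volar plate band, px.
#' @param plate_intensity intensity of the volar plate.
#' @param tendon_intensity,sheath_intensity,background_intensity base
#'   intensities of the tissue classes.
#' @param bottom_contrast intensity step across the tendon's bottom
#'   boundary (>= 0); large values give a clear boundary, values near
#'   zero a fuzzy one.
#' @param strip_height height of the sub-tendon strip carrying the
#'   bottom contrast, px.
#' @param speckle multiplicative speckle strength in `[0, 1]` (0 = none).
#' @param texture_amplitude amplitude of the smooth background texture.
#' @param seed integer seed making the phantom fully reproducible.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(192L, 384L),
                         tendon_center = round(c(0.42, 0.50) * image_size),
                         tendon_axes = round(c(0.16, 0.14) * image_size),
                         sheath_thickness = max(2L, round(0.03 * image_size[1])),
                         plate_gap = max(2L, round(0.10 * image_size[1])),
                         plate_thickness = max(2L, round(0.025 * image_size[1])),
                         plate_intensity = 225,
                         tendon_intensity = 150,
                         sheath_intensity = 55,
                         background_intensity = 90,
                         bottom_contrast = 60,
                         strip_height = max(4L, round(0.09 * image_size[1])),
                         speckle = 0.25,
                         texture_amplitude = 12,
                         seed = 1L) {
  spec <- list(image_size = as.integer(image_size),
               tendon_center = as.numeric(tendon_center),
               tendon_axes = as.numeric(tendon_axes),
               sheath_thickness = as.numeric(sheath_thickness),
               plate_gap = as.numeric(plate_gap),
               plate_thickness = as.numeric(plate_thickness),
               plate_intensity = plate_intensity,
               tendon_intensity = tendon_intensity,
               sheath_intensity = sheath_intensity,
               background_intensity = background_intensity,
               bottom_contrast = bottom_contrast,
               strip_height = as.numeric(strip_height),
               speckle = speckle,
               texture_amplitude = texture_amplitude,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  cy <- spec$tendon_center[1]; cx <- spec$tendon_center[2]
  ay <- spec$tendon_axes[1]; ax <- spec$tendon_axes[2]
  th <- spec$sheath_thickness
  if (spec$bottom_contrast < 0) stop("bottom_contrast must be >= 0")
  if (cy - ay < 1 || cy + ay > H || cx - ax < 1 || cx + ax > W)
    stop("tendon ellipse must lie entirely inside the image")
  if (cy - ay - th < 1 || cy + ay + th > H || cx - ax - th < 1 || cx + ax + th > W)
    stop("sheath ring must surround the tendon without leaving the image")
  invisible(spec)
}

ellipse_mask <- function(H, W, cy, cx, ay, ax) {
  r <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  m <- ((r - cy) / ay)^2 + ((cc - cx) / ax)^2 <= 1
  matrix(as.integer(m), H, W)
}

#' Generate one synthetic phantom
#'
#' @param spec a [phantom_spec()].
#' @param sheath_mode `"filled"` returns the sheath mask as the filled
#'   outer region (tendon included, matching the convention that the
#'   sheath contour encloses the tendon); `"ring"` returns the ring only.
#' @return `list(image, tendon, sheath)`: an `[H, W]` intensity matrix
#'   with values in 0..255 and two binary masks; `tendon` is a subset of
#'   `sheath` in `"filled"` mode.
#' @export
generate_phantom <- function(spec, sheath_mode = c("filled", "ring")) {
  stopifnot(inherits(spec, "phantom_spec"))
  sheath_mode <- match.arg(sheath_mode)
  validate_phantom_spec(spec)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  H <- spec$image_size[1]; W <- spec$image_size[2]
  cy <- spec$tendon_center[1]; cx <- spec$tendon_center[2]
  ay <- spec$tendon_axes[1]; ax <- spec$tendon_axes[2]
  th <- spec$sheath_thickness

  tendon <- ellipse_mask(H, W, cy, cx, ay, ax)
  outer <- ellipse_mask(H, W, cy, cx, ay + th, ax + th)
  ring <- outer & !tendon

  # smooth background texture: a few random-phase sinusoids
  rgrid <- matrix(seq_len(H), H, W); cgrid <- matrix(seq_len(W), H, W, byrow = TRUE)
  tex <- matrix(0, H, W)
  for (k in 1:3) {
    fr <- stats::runif(1, 1, 3) * 2 * pi / H
    fc <- stats::runif(1, 1, 3) * 2 * pi / W
    tex <- tex + sin(fr * rgrid + stats::runif(1, 0, 2 * pi)) *
      sin(fc * cgrid + stats::runif(1, 0, 2 * pi))
  }
  img <- spec$background_intensity + spec$texture_amplitude * tex / 3

  # volar plate: a shallow parabolic bright band below the sheath
  plate_top <- cy + ay + th + spec$plate_gap
  span <- 1.6 * ax
  curve <- plate_top + 0.06 * spec$image_size[1] * ((cgrid - cx) / span)^2
  plate <- abs(cgrid - cx) <= span & rgrid >= curve &
    rgrid <= curve + spec$plate_thickness
  img[plate] <- spec$plate_intensity

  img[ring == 1L] <- spec$sheath_intensity

  # sub-tendon strip carrying the bottom-boundary contrast
  cols <- which(colSums(tendon) > 0)
  for (cidx in cols) {
    bot <- max(which(tendon[, cidx] == 1L))
    lo <- min(H, bot + 1L); hi <- min(H, bot + spec$strip_height)
    prows <- which(plate[lo:hi, cidx])
    if (length(prows) > 0L) hi <- lo + min(prows) - 2L   # stop above the plate
    if (lo <= hi)
      img[lo:hi, cidx] <- spec$tendon_intensity - spec$bottom_contrast
  }
  img[tendon == 1L] <- spec$tendon_intensity

  if (spec$speckle > 0) {
    ray <- sqrt(-2 * log(stats::runif(H * W)))   # Rayleigh, scale 1
    m <- matrix(ray / sqrt(pi / 2), H, W)        # normalized to mean 1
    img <- img * ((1 - spec$speckle) + spec$speckle * m)
  }
  img <- round(pmin(pmax(img, 0), 255))
  sheath <- if (sheath_mode == "filled") matrix(as.integer(outer), H, W)
            else matrix(as.integer(ring), H, W)
  list(image = img, tendon = tendon, sheath = sheath)
}

#' Classify an image as clear or fuzzy at the tendon's bottom boundary
#'
#' Compares the mean intensities of two square windows placed above and
#' below the tendon's bottom boundary, on the vertical through the
#' tendon centroid column: the image is `"clear"` if the upper window
#' mean exceeds the lower by strictly more than `threshold`, otherwise
#' `"fuzzy"`.
#'
#' @param img `[H, W]` intensity matrix (8-bit scale, 0..255).
#' @param tendon nonempty binary tendon mask of the same shape.
#' @param window window side length in px.
#' @param offset distance from the boundary to each window center, px.
#' @param threshold intensity-difference threshold.
#' @return `"clear"` or `"fuzzy"`.
#' @export
classify_clear_fuzzy <- function(img, tendon, window = 15L, offset = 8L,
                                 threshold = 30) {
  tendon <- as_mask(tendon)
  if (sum(tendon) == 0L) stop("tendon mask is empty")
  if (!all(dim(img) == dim(tendon))) stop("image and mask shapes differ")
  half <- (window - 1L) %/% 2L
  ccol <- round(mean(which(tendon == 1L, arr.ind = TRUE)[, "col"]))
  if (colSums(tendon)[ccol] == 0L) stop("no tendon pixels in the centroid column")
  bot <- max(which(tendon[, ccol] == 1L))
  win_mean <- function(center_row) {
    rows <- (center_row - half):(center_row + half)
    cls <- (ccol - half):(ccol + half)
    if (min(rows) < 1L || max(rows) > nrow(img) || min(cls) < 1L || max(cls) > ncol(img))
      stop("classification window out of image bounds")
    mean(img[rows, cls])
  }
  above <- win_mean(bot - offset)
  below <- win_mean(bot + offset)
  if (above - below > threshold) "clear" else "fuzzy"
}

#' Generate a seeded dataset of synthetic phantoms
#'
#' Draws `n` phantoms with randomized geometry; the bottom-boundary
#' contrast is sampled from a high range (45..90) for images intended to
#' be clear and a low range (0..15) for fuzzy ones, with the number of
#' clear images set by `clear_fraction`. When the image is large enough
#' for the 15x15 windows, the realized label from
#' [classify_clear_fuzzy()] is recorded alongside the intended one. In
#' series mode the phantoms form one smoothly varying sweep (consecutive
#' slices drift by at most ~1 px), emulating a continuous acquisition
#' group.
#'
#' @param n number of phantoms (>= 1).
#' @param clear_fraction fraction of images intended to be clear.
#' @param seed integer seed; the whole dataset is a deterministic
#'   function of `(n, clear_fraction, seed, image_size, series)`.
#' @param image_size `(height, width)` of every phantom.
#' @param series logical; generate one continuous series instead of
#'   independent draws.
#' @return list of `n` elements, each
#'   `list(image, tendon, sheath, label, realized_label, spec)`.
#' @export
generate_dataset <- function(n, clear_fraction = 0.5, seed = 1L,
                             image_size = c(192L, 384L), series = FALSE) {
  if (n < 1) stop("n must be >= 1")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  H <- image_size[1]; W <- image_size[2]
  n_clear <- round(n * clear_fraction)
  labels <- sample(c(rep("clear", n_clear), rep("fuzzy", n - n_clear)))
  can_classify <- H >= 96L && W >= 96L

  base_cy <- stats::runif(1, 0.40, 0.44); base_cx <- stats::runif(1, 0.47, 0.53)
  base_ay <- stats::runif(1, 0.15, 0.17); base_ax <- stats::runif(1, 0.13, 0.15)
  drift_phase <- stats::runif(2, 0, 2 * pi)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (series) {
      t <- i / n
      cy <- base_cy + 0.015 * sin(2 * pi * t + drift_phase[1])
      cx <- base_cx + 0.015 * sin(2 * pi * t + drift_phase[2])
      ay <- base_ay * (1 + 0.05 * sin(4 * pi * t))
      ax <- base_ax * (1 + 0.05 * cos(4 * pi * t))
    } else {
      cy <- stats::runif(1, 0.40, 0.44); cx <- stats::runif(1, 0.45, 0.55)
      ay <- stats::runif(1, 0.14, 0.18); ax <- stats::runif(1, 0.12, 0.16)
    }
    contrast <- if (labels[i] == "clear") stats::runif(1, 45, 90)
                else stats::runif(1, 0, 15)
    spec <- phantom_spec(image_size = image_size,
                         tendon_center = c(cy * H, cx * W),
                         tendon_axes = c(ay * H, ax * W),
                         bottom_contrast = contrast,
                         seed = sample.int(.Machine$integer.max, 1L))
    ph <- generate_phantom(spec)
    realized <- if (can_classify)
      tryCatch(classify_clear_fuzzy(ph$image, ph$tendon),
               error = function(e) NA_character_)
    else NA_character_
    out[[i]] <- list(image = ph$image, tendon = ph$tendon, sheath = ph$sheath,
                     label = labels[i], realized_label = realized, spec = spec)
  }
  out
}
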