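# Data augmentation: the offline 10x expansion (flip + random
# translations + random scalings) and the per-epoch online augmentation
# (rotation, shrinking, translation, noise, gamma). Geometric transforms
# are applied identically to image and mask (bilinear vs nearest-neighbor
# resampling, zero fill); intensity transforms touch the image alone, so
# masks stay strictly binary.

#' Augmentation parameter specification
#'
#' Offline parameters follow the reference protocol: translations drawn
#' independently per axis from `[-translation, translation]` pixels, and
#' scalings realized as enlarging or cropping the field of view by a
#' margin drawn from `scaling` pixels per side before resampling back to
#' the original grid. The flip mirrors about the vertical axis. Online
#' operations are each applied with probability `online_prob`; their
#' ranges default to modest values suitable for 384x192 images and scale
#' down with the image for desk-scale runs.
#'
#' @param translation max offline translation per axis (px).
#' @param scaling two-element range of the offline scaling margin (px).
#' @param online_prob per-op application probability for online ops.
#' @param rotation max online rotation (degrees, either direction).
#' @param shrink max online shrink fraction (scale factor `1 - U(0, shrink)`).
#' @param online_translation max online translation per axis (px).
#' @param noise_sd max additive Gaussian noise s.d., in 8-bit intensity
#'   levels (applied to images scaled to `[0, 1]` as `noise_sd / 255`).
#' @param gamma two-element range of the gamma exponent.
#' @return object of class `augment_spec`.
#' @export
augment_spec <- function(translation = 32L, scaling = c(10L, 50L),
                         online_prob = 0.5, rotation = 10, shrink = 0.1,
                         online_translation = 16L, noise_sd = 5,
                         gamma = c(0.7, 1.3)) {
  spec <- list(translation = as.integer(translation),
               scaling = as.integer(scaling), online_prob = online_prob,
               rotation = rotation, shrink = shrink,
               online_translation = as.integer(online_translation),
               noise_sd = noise_sd, gamma = gamma)
  class(spec) <- "augment_spec"
  spec
}

affine_tf <- function(angle = 0, scale = c(1, 1), translate = c(0, 0)) {
  list(kind = "affine", angle = angle, scale = scale, translate = translate)
}

#' Apply a logged geometric transform to an image or mask
#'
#' Re-applies a transform recorded by [offline_augment()] or
#' [online_augment()], so augmented masks can be reproduced exactly from
#' the originals for reproducibility audits.
#'
#' @param img `[H, W]` numeric matrix.
#' @param tf a transform record (`kind` one of `identity`, `flip`,
#'   `affine`).
#' @param interp `"bilinear"` for images, `"nearest"` for masks.
#' @return transformed matrix of the same shape.
#' @export
apply_transform <- function(img, tf, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  switch(tf$kind,
         identity = img,
         flip = img[, ncol(img):1, drop = FALSE],
         affine = warp_affine(img, tf, interp),
         stop("unknown transform kind: ", tf$kind))
}

# Inverse-mapped affine warp about the image center: output pixel ->
# (undo translation) -> (inverse rotation) -> (inverse scale) -> sample.
warp_affine <- function(img, tf, interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  H <- nrow(img); W <- ncol(img)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  th <- tf$angle * pi / 180
  rr <- rep(seq_len(H), times = W) - cy - tf$translate[1]
  cc <- rep(seq_len(W), each = H) - cx - tf$translate[2]
  yi <- (cos(th) * rr + sin(th) * cc) / tf$scale[1] + cy
  xi <- (-sin(th) * rr + cos(th) * cc) / tf$scale[2] + cx
  gather <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    v <- rep(fill, length(ri))
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v
  }
  out <- if (interp == "nearest") {
    gather(round(yi), round(xi))
  } else {
    r0 <- floor(yi); c0 <- floor(xi)
    wr <- yi - r0; wc <- xi - c0
    gather(r0, c0) * (1 - wr) * (1 - wc) + gather(r0 + 1, c0) * wr * (1 - wc) +
      gather(r0, c0 + 1) * (1 - wr) * wc + gather(r0 + 1, c0 + 1) * wr * wc
  }
  matrix(out, H, W)
}

draw_scaling_tf <- function(H, W, spec) {
  mh <- sample(seq(spec$scaling[1], spec$scaling[2]), 1L)
  mv <- sample(seq(spec$scaling[1], spec$scaling[2]), 1L)
  s <- sample(c(-1L, 1L), 1L)             # +1 widens the field of view
  mh <- min(mh, (W - 2L) %/% 2L); mv <- min(mv, (H - 2L) %/% 2L)
  affine_tf(scale = c(H / (H + 2 * s * mv), W / (W + 2 * s * mh)))
}

#' Offline 10x augmentation of one image/mask pair
#'
#' Returns exactly ten pairs: the original, a flip about the vertical
#' axis, four random translations (independent horizontal and vertical
#' offsets) and four random scalings, each with its transform record
#' attached. Deterministic given `seed`.
#'
#' @param img `[H, W]` numeric image.
#' @param mask paired binary mask of the same shape.
#' @param seed integer seed.
#' @param spec an [augment_spec()].
#' @return list of 10 elements, each `list(image, mask, transform)`.
#' @export
offline_augment <- function(img, mask, seed = 1L, spec = augment_spec()) {
  if (!all(dim(img) == dim(mask)))
    stop("image and mask shapes differ")
  mask <- as_mask(mask)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  H <- nrow(img); W <- ncol(img)
  tfs <- c(list(list(kind = "identity"), list(kind = "flip")),
           replicate(4, affine_tf(translate = c(
             sample(seq(-spec$translation, spec$translation), 1L),
             sample(seq(-spec$translation, spec$translation), 1L))),
             simplify = FALSE),
           replicate(4, draw_scaling_tf(H, W, spec), simplify = FALSE))
  lapply(tfs, function(tf) {
    list(image = apply_transform(img, tf, "bilinear"),
         mask = as_mask(matrix(as.integer(apply_transform(mask, tf, "nearest")), H, W)),
         transform = tf)
  })
}

#' Online augmentation of one image/mask pair
#'
#' Each operation -- rotation, shrinking, translation, additive Gaussian
#' noise, gamma transformation -- is applied independently with
#' probability `spec$online_prob`, drawing from the current RNG stream
#' (so a seeded training loop is reproducible). Geometric ops act on
#' image and mask alike; noise and gamma only on the image, which is
#' assumed to be scaled to `[0, 1]`.
#'
#' @inheritParams offline_augment
#' @return `list(image, mask, transform, noise_sd, gamma)`.
#' @export
online_augment <- function(img, mask, spec = augment_spec()) {
  if (!all(dim(img) == dim(mask))) stop("image and mask shapes differ")
  mask <- as_mask(mask)
  p <- spec$online_prob
  angle <- if (stats::runif(1) < p) stats::runif(1, -spec$rotation, spec$rotation) else 0
  shrink <- if (stats::runif(1) < p) 1 - stats::runif(1, 0, spec$shrink) else 1
  tr <- if (stats::runif(1) < p) {
    c(sample(seq(-spec$online_translation, spec$online_translation), 1L),
      sample(seq(-spec$online_translation, spec$online_translation), 1L))
  } else c(0, 0)
  nsd <- if (stats::runif(1) < p) stats::runif(1, 0, spec$noise_sd) else 0
  gam <- if (stats::runif(1) < p) stats::runif(1, spec$gamma[1], spec$gamma[2]) else 1
  geometric <- angle != 0 || shrink != 1 || any(tr != 0)
  tf <- if (geometric) affine_tf(angle, c(shrink, shrink), tr) else list(kind = "identity")
  out_img <- apply_transform(img, tf, "bilinear")
  out_mask <- apply_transform(mask, tf, "nearest")
  if (nsd > 0)
    out_img <- out_img + stats::rnorm(length(out_img), sd = nsd / 255)
  out_img <- pmin(pmax(out_img, 0), 1)
  if (gam != 1) out_img <- out_img^gam
  list(image = out_img,
       mask = as_mask(matrix(as.integer(out_mask), nrow(mask), ncol(mask))),
       transform = tf, noise_sd = nsd, gamma = gam)
}
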