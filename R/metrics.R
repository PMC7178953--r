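# Region and contour evaluation: Dice similarity coefficient, mean
# absolute contour distance (MAD), Hausdorff distance (HD), the Yasnoff
# measure, and a convex-hull Hausdorff distance (CHD) for contour
# smoothness, plus the contour extraction and artifact filtering they
# rely on.
#
# Conventions: masks are [H, W] matrices with values {0, 1}; contours are
# integer (row, col) matrices of pixel centers, 0-based distances in
# pixel units, Euclidean between centers.

as_mask <- function(m) {
  if (!is.matrix(m)) stop("a mask must be a matrix")
  v <- unique(c(m))
  if (!all(v %in% c(0, 1))) stop("mask values must be 0/1")
  storage.mode(m) <- "integer"
  m
}

#' Dice similarity coefficient of two binary masks
#'
#' `DSC(X, Y) = 2|X intersect Y| / (|X| + |Y|)`, the standard region
#' overlap measure. An empty prediction against a nonempty truth scores
#' 0; two empty masks are undefined (0/0) and raise an error.
#'
#' @param pred,truth binary `[H, W]` matrices of identical shape.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(pred, truth) {
  pred <- as_mask(pred); truth <- as_mask(truth)
  if (!all(dim(pred) == dim(truth)))
    stop("mask shapes differ: ", paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(truth), collapse = "x"))
  np <- sum(pred); nt <- sum(truth)
  if (np + nt == 0L) stop("DSC undefined: both masks empty")
  2 * sum(pred & truth) / (np + nt)
}

#' Extract the contour of a binary region
#'
#' The contour is the set of foreground pixels with at least one
#' background 4-neighbor (inner-boundary convention); pixels on the
#' image border count as touching background. Points are returned in
#' raster order.
#'
#' @param mask binary `[H, W]` matrix with at least one foreground pixel.
#' @return integer matrix with columns `row`, `col` (1-based indices).
#' @export
extract_contour <- function(mask) {
  mask <- as_mask(mask)
  if (sum(mask) == 0L) stop("cannot extract a contour from an empty mask")
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  inner <- pad[2:(H + 1L), 2:(W + 1L)]
  nb <- pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  border <- inner == 1L & !nb
  idx <- which(border)
  cbind(row = ((idx - 1L) %% H) + 1L, col = ((idx - 1L) %/% H) + 1L)
}

# All nearest-neighbour distances from points a to set b, via the
# squared-distance matrix (BLAS path; the tests check it against an
# exhaustive per-point scan).
contour_nn_dist <- function(a, b) {
  a <- contour_points(a); b <- contour_points(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(apply(d2, 1, min))
}

contour_points <- function(x) {
  if (is.matrix(x) && ncol(x) == 2L) {
    if (nrow(x) == 0L) stop("contour is empty")
    return(matrix(as.numeric(x), ncol = 2L))
  }
  stop("a contour must be a two-column (row, col) matrix")
}

#' Mean absolute distance between two contours
#'
#' Symmetric average of the two directed mean nearest-point Euclidean
#' distances:
#' `MAD(A,B) = 1/2 * (mean_a inf_b d(a,b) + mean_b inf_a d(a,b))`.
#'
#' @param a,b contours as (row, col) matrices (see [extract_contour()]).
#' @return distance in pixels.
#' @export
mad_contour <- function(a, b) {
  (mean(contour_nn_dist(a, b)) + mean(contour_nn_dist(b, a))) / 2
}

#' Hausdorff distance between two contours
#'
#' `HD(A,B) = max(sup_a inf_b d(a,b), sup_b inf_a d(a,b))`; always at
#' least as large as the MAD of the same pair.
#'
#' @inheritParams mad_contour
#' @return distance in pixels.
#' @export
hausdorff <- function(a, b) {
  max(max(contour_nn_dist(a, b)), max(contour_nn_dist(b, a)))
}

#' Yasnoff measure between two contours
#'
#' `(100 / W) * sqrt(sum_a min_b d(a,b)^2)` where `W` is the number of
#' pixels in the image. Asymmetric: `a` is the predicted contour, `b`
#' the ground-truth contour.
#'
#' @inheritParams mad_contour
#' @param image_pixel_count total pixel count `W` of the image (> 0).
#' @return dimensionless value.
#' @export
yasnoff <- function(a, b, image_pixel_count) {
  if (image_pixel_count <= 0) stop("image_pixel_count must be positive")
  100 / image_pixel_count * sqrt(sum(contour_nn_dist(a, b)^2))
}

#' Keep only the largest connected component of a mask
#'
#' Artifact filter applied before HD and CHD: retains the largest
#' 8-connected foreground component. Components are labelled in raster
#' order, and ties in size keep the lowest label, so the result is
#' deterministic.
#'
#' @param mask nonempty binary `[H, W]` matrix.
#' @return binary matrix with a single connected component.
#' @export
filter_artifacts <- function(mask) {
  mask <- as_mask(mask)
  if (sum(mask) == 0L) stop("cannot filter an empty mask")
  lab <- label_components_cpp(c(mask), nrow(mask), ncol(mask))
  n <- attr(lab, "n")
  if (n <= 1L) return(mask)
  sizes <- tabulate(lab, nbins = n)
  keep <- which.max(sizes)                 # first maximum = lowest label
  out <- matrix(as.integer(lab == keep), nrow(mask), ncol(mask))
  out
}

# Rasterize the filled convex hull of a region's contour points: hull
# vertices from chull(), then a scanline fill of the convex polygon over
# pixel centers. Every foreground pixel of the source region lies inside
# the hull of its boundary pixels, so region <= hull fill.
convex_hull_mask <- function(mask) {
  mask <- as_mask(mask)
  pts <- extract_contour(mask)
  hull <- grDevices::chull(pts[, "col"], pts[, "row"])
  poly <- pts[hull, , drop = FALSE]
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0L, H, W)
  nv <- nrow(poly)
  if (nv <= 2L) {                          # degenerate: points on a line
    out[poly] <- 1L
    out[pts] <- 1L
    return(out)
  }
  ys <- poly[, "row"]; xs <- poly[, "col"]
  for (r in seq(min(ys), max(ys))) {
    xhit <- numeric(0)
    for (e in seq_len(nv)) {
      e2 <- if (e == nv) 1L else e + 1L
      y1 <- ys[e]; y2 <- ys[e2]
      if ((y1 <= r && y2 >= r) || (y2 <= r && y1 >= r)) {
        if (y1 == y2) xhit <- c(xhit, xs[e], xs[e2])
        else xhit <- c(xhit, xs[e] + (r - y1) * (xs[e2] - xs[e]) / (y2 - y1))
      }
    }
    if (length(xhit) == 0) next
    c1 <- ceiling(min(xhit) - 1e-9); c2 <- floor(max(xhit) + 1e-9)
    if (c2 >= c1) out[r, max(1L, c1):min(W, c2)] <- 1L
  }
  out[mask == 1L] <- 1L                    # guard against rasterization gaps
  out
}

#' Convex-hull Hausdorff distance of a region
#'
#' Hausdorff distance between a region's contour and the contour of its
#' filled convex hull. Near zero (within 1 px of rasterization) for
#' convex regions, and growing with the depth of concavities, it scores
#' the smoothness of a segmented contour. Apply [filter_artifacts()]
#' first when the mask may contain spurious islands.
#'
#' @param region nonempty binary `[H, W]` matrix.
#' @return distance in pixels.
#' @export
chd <- function(region) {
  region <- as_mask(region)
  if (sum(region) == 0L) stop("CHD undefined for an empty region")
  a <- extract_contour(region)
  cc <- extract_contour(convex_hull_mask(region))
  hausdorff(a, cc)
}

#' Evaluate one predicted mask against its ground truth
#'
#' DSC, MAD and Yasnoff are computed on the raw prediction; HD and CHD
#' after artifact filtering (largest-component rule), since both are
#' sensitive to isolated false positives. An empty prediction yields
#' DSC 0 and `NA` for the contour metrics (flagged via a warning and
#' treated as missing in aggregation).
#'
#' @param pred,truth binary `[H, W]` matrices of identical shape.
#' @return list of class `metrics_report` with fields `dsc`, `mad`,
#'   `hd`, `yasnoff`, `chd`.
#' @export
evaluate_pair <- function(pred, truth) {
  pred <- as_mask(pred); truth <- as_mask(truth)
  if (!all(dim(pred) == dim(truth))) stop("mask shapes differ")
  W <- length(truth)
  if (sum(truth) == 0L) stop("ground-truth mask is empty")
  if (sum(pred) == 0L) {
    warning("empty prediction: contour metrics recorded as missing")
    rep <- list(dsc = 0, mad = NA_real_, hd = NA_real_,
                yasnoff = NA_real_, chd = NA_real_)
    class(rep) <- "metrics_report"
    return(rep)
  }
  a <- extract_contour(pred)
  b <- extract_contour(truth)
  pf <- filter_artifacts(pred)
  tf <- filter_artifacts(truth)
  rep <- list(
    dsc = dsc(pred, truth),
    mad = mad_contour(a, b),
    hd = hausdorff(extract_contour(pf), extract_contour(tf)),
    yasnoff = yasnoff(a, b, W),
    chd = chd(pf)
  )
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("DSC %.4f  MAD %.2f px  HD %.2f px  Yasnoff %.4f  CHD %.2f px\n",
              x$dsc, x$mad, x$hd, x$yasnoff, x$chd))
  invisible(x)
}

#' Evaluate a batch of mask pairs
#'
#' @param preds,truths named lists of binary masks (matched by position;
#'   names of `preds` become the image ids).
#' @return data frame with one row per image
#'   (`image_id, dsc, mad, hd, yasnoff, chd`) plus `mean` and `sd`
#'   summary rows computed over the non-missing per-image values.
#' @export
evaluate_batch <- function(preds, truths) {
  if (length(preds) != length(truths)) stop("pred/truth lists differ in length")
  ids <- names(preds) %||% as.character(seq_along(preds))
  rows <- lapply(seq_along(preds), function(i) {
    r <- evaluate_pair(preds[[i]], truths[[i]])
    data.frame(image_id = ids[i], dsc = r$dsc, mad = r$mad, hd = r$hd,
               yasnoff = r$yasnoff, chd = r$chd, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  num <- tab[, -1, drop = FALSE]
  summ <- data.frame(image_id = c("mean", "sd"),
                     rbind(colMeans(num, na.rm = TRUE),
                           apply(num, 2, stats::sd, na.rm = TRUE)),
                     stringsAsFactors = FALSE)
  rbind(tab, summ)
}
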