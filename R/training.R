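# Training: adaptive Gaussian initialization, polynomial learning-rate
# decay, soft-Dice loss, the deeply supervised total objective, and the
# RMSProp loop.

#' Adaptive Gaussian initialization standard deviation
#'
#' `sqrt(2 / ((2r+1)^2 * c_in))` for a square kernel of radius `r` over
#' `c_in` input channels -- He-style scaling that keeps activation
#' variance stable through ReLU layers.
#'
#' @param r kernel radius (filter size is `2r+1`).
#' @param c_in number of input channels (> 0).
#' @return standard deviation (scalar).
#' @export
init_std <- function(r, c_in) {
  if (c_in <= 0) stop("c_in must be positive")
  sqrt(2 / ((2 * r + 1)^2 * c_in))
}

#' Polynomial learning-rate decay
#'
#' `l_n = l_0 * (1 - n / N_e)^alpha` for epoch index `n` (0-based) up to
#' the stopping epoch `N_e`.
#'
#' @param n epoch index, `0 <= n <= N_e`.
#' @param cfg a [train_config()] (fields `l0`, `epochs`, `alpha`).
#' @return learning rate at epoch `n`.
#' @export
lr_at_epoch <- function(n, cfg) {
  if (n > cfg$epochs) stop("epoch index n = ", n, " exceeds stopping epoch ", cfg$epochs)
  if (n < 0) stop("epoch index must be >= 0")
  cfg$l0 * (1 - n / cfg$epochs)^cfg$alpha
}

#' Soft Dice coefficient between a probability map and a binary mask
#'
#' `2 sum(p q) / (sum(p^2) + sum(q^2) + eps)` with labels 1 for object
#' and 0 for background; a small `eps` in the denominator defines the
#' empty/empty case as 0. Equals the Dice similarity coefficient when
#' `p` is binary.
#'
#' @param p numeric array of probabilities in `[0, 1]`.
#' @param q binary mask of the same shape.
#' @param eps denominator smoothing.
#' @return soft Dice value in `[0, 1]`.
#' @export
dice_value <- function(p, q, eps = 1e-6) {
  if (length(p) != length(q)) stop("probability map and mask shapes differ")
  2 * sum(p * q) / (sum(p * p) + sum(q * q) + eps)
}

dice_grad <- function(p, q, eps = 1e-6) {
  num <- 2 * sum(p * q)
  den <- sum(p * p) + sum(q * q) + eps
  (2 * q * den - num * 2 * p) / den^2
}

#' Deeply supervised total loss
#'
#' `(1 - dice_main) + sum_i w_i (1 - dice_supervised_i)`: each Dice
#' coefficient enters as `1 - Dice` so the objective is minimized. The
#' default weights `{1/16, 1/8, 1/4}` put the lowest weight on the
#' coarsest supervision level (`i = 1`).
#'
#' @param main Dice value of the final output.
#' @param supervised numeric vector of the per-head Dice values,
#'   coarsest first; its length must match `weights`.
#' @param weights supervision weights.
#' @return scalar loss.
#' @export
total_loss <- function(main, supervised, weights = c(1 / 16, 1 / 8, 1 / 4)) {
  if (length(supervised) != length(weights))
    stop("expected ", length(weights), " supervised Dice terms, got ", length(supervised))
  (1 - main) + sum(weights * (1 - supervised))
}

#' Training configuration
#'
#' @param batch_size mini-batch size (default 4 images).
#' @param l0 initial learning rate (default 5e-4).
#' @param epochs stopping epoch `N_e` (50 for single-image datasets, 20
#'   for series data in the reference setting).
#' @param alpha polynomial decay exponent (default 1.5).
#' @param weights deep-supervision weights, coarsest level first.
#' @param rmsprop_decay RMSProp moving-average decay.
#' @param rmsprop_eps RMSProp denominator epsilon.
#' @param augment an [augment_spec()] applied online each epoch, or
#'   `NULL` to train on the raw images.
#' @param supervision logical; `FALSE` drops the head terms entirely,
#'   reducing to single-output Dice training.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 4L, l0 = 5e-4, epochs = 50L, alpha = 1.5,
                         weights = c(1 / 16, 1 / 8, 1 / 4),
                         rmsprop_decay = 0.9, rmsprop_eps = 1e-8,
                         augment = NULL, supervision = TRUE) {
  stopifnot(batch_size >= 1, l0 > 0, epochs >= 1, all(weights >= 0))
  cfg <- list(batch_size = as.integer(batch_size), l0 = l0,
              epochs = as.integer(epochs), alpha = alpha, weights = weights,
              rmsprop_decay = rmsprop_decay, rmsprop_eps = rmsprop_eps,
              augment = augment, supervision = isTRUE(supervision))
  class(cfg) <- "train_config"
  cfg
}

#' Train a D2FC-DN on image/mask pairs
#'
#' RMSProp on the deeply supervised soft-Dice objective, with the
#' learning rate following the polynomial decay schedule (updated once
#' per epoch) and, when `cfg$augment` is set, online augmentation
#' redrawn for every sample in every epoch. Fully deterministic given
#' `seed`.
#'
#' @param net a `d2fc_dn` from [build_d2fc_dn()]; its input size must
#'   match the images.
#' @param images list of `[H, W]` numeric matrices with intensities in
#'   `[0, 1]`.
#' @param masks list of paired binary masks.
#' @param cfg a [train_config()].
#' @param seed integer seed controlling shuffling and augmentation.
#' @param verbose print a line per epoch.
#' @return the trained network, with a `log` element: data frame
#'   (epoch, lr, total_loss, main_dice).
#' @export
train_d2fc_dn <- function(net, images, masks, cfg = train_config(), seed = 1L,
                          verbose = FALSE) {
  stopifnot(inherits(net, "d2fc_dn"), inherits(cfg, "train_config"))
  if (length(images) == 0L) stop("empty training dataset")
  if (length(images) != length(masks)) stop("images and masks differ in length")
  H <- net$spec$input_size[1]; W <- net$spec$input_size[2]
  for (im in images)
    if (!all(dim(im) == c(H, W))) stop("all images must be ", H, "x", W)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)

  msq <- lapply(net$params, function(p) p * 0)
  nw <- length(cfg$weights)
  log_rows <- vector("list", cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_at_epoch(epoch - 1L, cfg)
    ord <- sample.int(length(images))
    ep_loss <- 0; ep_dice <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      bidx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      N <- length(bidx)
      xb <- array(0, c(H, W, 1L, N))
      qb <- array(0, c(H, W, 1L, N))
      for (k in seq_len(N)) {
        img <- images[[bidx[k]]]; msk <- masks[[bidx[k]]]
        if (!is.null(cfg$augment)) {
          aug <- online_augment(img, msk, cfg$augment)
          img <- aug$image; msk <- aug$mask
        }
        xb[, , 1L, k] <- img
        qb[, , 1L, k] <- msk
      }
      fw <- d2fc_dn_forward(net, xb, train = TRUE, keep_cache = TRUE)
      net$state[names(fw$cache$state)] <- fw$cache$state

      dmain <- array(0, dim(fw$main))
      dheads <- vector("list", nw)
      batch_loss <- 0; batch_dice <- 0
      for (k in seq_len(N)) {
        p <- fw$main[, , 1L, k]; q <- qb[, , 1L, k]
        dv <- dice_value(p, q)
        batch_dice <- batch_dice + dv
        sup <- numeric(nw)
        if (cfg$supervision) {
          for (i in seq_len(nw)) {
            hp <- fw$heads[[i]][, , 1L, k]
            sup[i] <- dice_value(hp, q)
            if (is.null(dheads[[i]])) dheads[[i]] <- array(0, dim(fw$heads[[i]]))
            dheads[[i]][, , 1L, k] <- -cfg$weights[i] * dice_grad(hp, q) / N
          }
        } else sup <- rep(1, nw)
        batch_loss <- batch_loss + total_loss(dv, sup, cfg$weights)
        dmain[, , 1L, k] <- -dice_grad(p, q) / N
      }
      batch_loss <- batch_loss / N
      if (!is.finite(batch_loss))
        stop("non-finite training loss at epoch ", epoch, "; aborting")
      grads <- d2fc_dn_backward(net, fw$cache, dmain,
                                if (cfg$supervision) dheads else vector("list", nw))
      for (nm in names(net$params)) {
        g <- grads[[nm]]
        if (is.null(g)) next
        msq[[nm]] <- cfg$rmsprop_decay * msq[[nm]] + (1 - cfg$rmsprop_decay) * g * g
        net$params[[nm]] <- net$params[[nm]] - lr * g / (sqrt(msq[[nm]]) + cfg$rmsprop_eps)
      }
      ep_loss <- ep_loss + batch_loss
      ep_dice <- ep_dice + batch_dice / N
      nb <- nb + 1L
    }
    log_rows[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                    total_loss = ep_loss / nb,
                                    main_dice = ep_dice / nb)
    if (verbose)
      message(sprintf("epoch %3d  lr %.3e  loss %.4f  dice %.4f",
                      epoch, lr, ep_loss / nb, ep_dice / nb))
  }
  net$log <- do.call(rbind, log_rows)
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a
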