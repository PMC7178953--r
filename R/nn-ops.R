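# Low-level differentiable layer primitives.
#
# Feature maps are dense arrays [H, W, C, N] (rows, cols, channels, batch).
# Convolutions go through im2col/col2im (src/ops.cpp) so the inner loop is
# a BLAS matrix product; every *_bwd returns exact analytic gradients
# (verified against finite differences in the test suite).

conv_same_pad <- function(k, dil) ((k - 1L) %/% 2L) * dil

# The convolution here follows the discrete-convolution summation
# (F * k)(p) = sum_{s + t = p} F(s) k(t), i.e. the kernel is spatially
# flipped relative to a sliding-window correlation.
flip_kernel <- function(W) {
  kd <- dim(W)
  W[kd[1]:1, kd[2]:1, , , drop = FALSE]
}

#' Dilated 2-D convolution of a feature map
#'
#' Computes `(F *_l k)(p) = sum_{s + l t = p} F(s) k(t)`: a discrete
#' convolution whose kernel taps are spaced `dilation` pixels apart.
#' Zero padding of `r * dilation` per axis keeps the spatial size
#' unchanged, and with `dilation = 1` the operation reduces to ordinary
#' same-padded convolution. The parameter count does not depend on the
#' dilation factor.
#'
#' @param x feature map array `[H, W, C_in, N]` (a `[H, W, C_in]` array or
#'   a plain matrix is promoted).
#' @param W kernel array `[2r+1, 2r+1, C_in, C_out]`.
#' @param b bias vector of length `C_out`.
#' @param dilation integer dilation factor `l >= 1`.
#' @return array `[H, W, C_out, N]`.
#' @export
dilated_conv <- function(x, W, b = NULL, dilation = 1L) {
  x <- as_featuremap(x)
  if (dilation < 1) stop("dilation factor must be >= 1")
  if (is.null(b)) b <- numeric(dim(W)[4])
  nn_conv_fwd(x, W, b, dil = as.integer(dilation))
}

as_featuremap <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L) stop("feature maps must have dims [H, W, C, N]")
  x
}

nn_conv_fwd <- function(x, W, b, dil = 1L, want_cols = FALSE) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  kd <- dim(W); kh <- kd[1]; kw <- kd[2]; Cout <- kd[4]
  if (kd[3] != C) stop("kernel input channels (", kd[3], ") != feature map channels (", C, ")")
  P <- H * Wd
  y <- array(0, c(H, Wd, Cout, N))
  if (kh == 1L && kw == 1L) {
    # pointwise convolution: a plain channel mixing, no patch extraction
    Wm <- matrix(W, C, Cout)
    for (n in seq_len(N)) {
      ym <- matrix(x[, , , n], P, C) %*% Wm + rep(b, each = P)
      y[, , , n] <- array(ym, c(H, Wd, Cout))
    }
    return(if (want_cols) list(y = y, cols = NULL) else y)
  }
  ph <- conv_same_pad(kh, dil); pw <- conv_same_pad(kw, dil)
  Wm <- matrix(flip_kernel(W), ncol = Cout)
  cols_cache <- if (want_cols) vector("list", N) else NULL
  for (n in seq_len(N)) {
    cols <- im2col_cpp(c(x[, , , n]), H, Wd, C, kh, kw, ph, pw, 1L, dil, H, Wd)
    if (want_cols) cols_cache[[n]] <- cols
    ym <- crossprod(Wm, cols) + b
    y[, , , n] <- array(t(ym), c(H, Wd, Cout))
  }
  if (want_cols) list(y = y, cols = cols_cache) else y
}

nn_conv_bwd <- function(x, W, dY, dil = 1L, cols_cache = NULL) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  kd <- dim(W); kh <- kd[1]; kw <- kd[2]; Cout <- kd[4]
  P <- H * Wd
  dx <- array(0, d)
  if (kh == 1L && kw == 1L) {
    Wm <- matrix(W, C, Cout)
    dWm <- matrix(0, C, Cout)
    db <- numeric(Cout)
    for (n in seq_len(N)) {
      dYm <- matrix(dY[, , , n], P, Cout)
      xm <- matrix(x[, , , n], P, C)
      dWm <- dWm + crossprod(xm, dYm)
      db <- db + colSums(dYm)
      dx[, , , n] <- array(tcrossprod(dYm, Wm), c(H, Wd, C))
    }
    return(list(dx = dx, dW = array(dWm, kd), db = db))
  }
  ph <- conv_same_pad(kh, dil); pw <- conv_same_pad(kw, dil)
  Wm <- matrix(flip_kernel(W), ncol = Cout)
  dWm <- matrix(0, nrow(Wm), Cout)
  db <- numeric(Cout)
  for (n in seq_len(N)) {
    cols <- if (!is.null(cols_cache)) cols_cache[[n]]
            else im2col_cpp(c(x[, , , n]), H, Wd, C, kh, kw, ph, pw, 1L, dil, H, Wd)
    dYm <- t(matrix(c(dY[, , , n]), P, Cout))
    dWm <- dWm + cols %*% t(dYm)
    db <- db + rowSums(dYm)
    dcols <- Wm %*% dYm
    dx[, , , n] <- array(col2im_cpp(dcols, H, Wd, C, kh, kw, ph, pw, 1L, dil, H, Wd),
                         c(H, Wd, C))
  }
  list(dx = dx, dW = flip_kernel(array(dWm, kd)), db = db)
}

# Transposed convolution, 3x3 kernel, stride 2, exact spatial doubling
# (the adjoint of a 3x3 / stride-2 / pad-1 convolution with one row and
# column of output padding). Weights are stored as the adjoint kernel
# [3, 3, C_out, C_in].
nn_tconv_fwd <- function(u, Wt, b) {
  d <- dim(u); H <- d[1]; Wd <- d[2]; Cin <- d[3]; N <- d[4]
  kd <- dim(Wt); Cout <- kd[3]
  if (kd[4] != Cin) stop("transposed-conv kernel input channels mismatch")
  Ho <- 2L * H; Wo <- 2L * Wd
  WmA <- matrix(Wt, ncol = Cin)      # (9*Cout) x Cin
  Pin <- H * Wd
  y <- array(0, c(Ho, Wo, Cout, N))
  badd <- rep(b, each = Ho * Wo)
  for (n in seq_len(N)) {
    umat <- t(matrix(c(u[, , , n]), Pin, Cin))
    colsY <- WmA %*% umat
    y[, , , n] <- array(col2im_cpp(colsY, Ho, Wo, Cout, 3L, 3L, 1L, 1L, 2L, 1L, H, Wd),
                        c(Ho, Wo, Cout)) + badd
  }
  y
}

nn_tconv_bwd <- function(u, Wt, dY) {
  d <- dim(u); H <- d[1]; Wd <- d[2]; Cin <- d[3]; N <- d[4]
  kd <- dim(Wt); Cout <- kd[3]
  Ho <- 2L * H; Wo <- 2L * Wd
  WmA <- matrix(Wt, ncol = Cin)
  Pin <- H * Wd
  dWm <- matrix(0, nrow(WmA), Cin)
  db <- numeric(Cout)
  du <- array(0, d)
  for (n in seq_len(N)) {
    dYn <- dY[, , , n, drop = FALSE]
    colsdY <- im2col_cpp(c(dYn), Ho, Wo, Cout, 3L, 3L, 1L, 1L, 2L, 1L, H, Wd)
    umat <- t(matrix(c(u[, , , n]), Pin, Cin))
    dWm <- dWm + colsdY %*% t(umat)
    du[, , , n] <- array(t(crossprod(WmA, colsdY)), c(H, Wd, Cin))
    db <- db + c(colSums(matrix(c(dYn), Ho * Wo, Cout)))
  }
  list(du = du, dW = array(dWm, kd), db = db)
}

# Batch normalization over (H, W, N) per channel. Population variance;
# running statistics tracked with the given momentum for inference.
nn_bn_fwd <- function(x, gamma, beta, rmean, rvar, train = TRUE,
                      momentum = 0.99, eps = 1e-5) {
  d <- dim(x); C <- d[3]; M <- prod(d[-3])
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu * mu
    v[v < 0] <- 0
    rmean <- momentum * rmean + (1 - momentum) * mu
    rvar <- momentum * rvar + (1 - momentum) * v
  } else {
    mu <- rmean; v <- rvar
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (xm - rep(mu, each = M)) * rep(istd, each = M)
  ym <- xhat * rep(gamma, each = M) + rep(beta, each = M)
  y <- aperm(array(ym, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(y = y, cache = list(xhat = xhat, istd = istd, dims = d),
       rmean = rmean, rvar = rvar)
}

nn_bn_bwd <- function(cache, gamma, dY) {
  d <- cache$dims; C <- d[3]; M <- prod(d[-3])
  dym <- matrix(aperm(dY, c(1, 2, 4, 3)), ncol = C)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxm <- rep(gamma * cache$istd, each = M) *
    (dym - rep(dbeta / M, each = M) - xhat * rep(dgamma / M, each = M))
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# 2x2 max pooling with stride 2; ties break to the earliest window
# position in raster order so the argmax (and hence training) is
# deterministic.
nn_maxpool_fwd <- function(x, want_idx = TRUE) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  if (H %% 2L != 0L || W %% 2L != 0L)
    stop("max pooling requires even spatial dims, got ", H, "x", W)
  i1 <- seq(1L, H, by = 2L); j1 <- seq(1L, W, by = 2L)
  a <- x[i1, j1, , , drop = FALSE]
  b <- x[i1 + 1L, j1, , , drop = FALSE]
  cc <- x[i1, j1 + 1L, , , drop = FALSE]
  dd <- x[i1 + 1L, j1 + 1L, , , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  idx <- NULL
  if (want_idx) {
    ro <- ifelse(a >= y, 0, ifelse(b >= y, 1, ifelse(cc >= y, 0, 1)))
    co <- ifelse(a >= y, 0, ifelse(b >= y, 0, 1))
    ii <- 2 * slice.index(y, 1) - 1 + ro
    jj <- 2 * slice.index(y, 2) - 1 + co
    idx <- ii + (jj - 1) * H + (slice.index(y, 3) - 1) * (H * W) +
      (slice.index(y, 4) - 1) * (H * W * C)
  }
  list(y = y, idx = idx, dims = d)
}

nn_maxpool_bwd <- function(pool, dY) {
  dx <- array(0, pool$dims)
  dx[c(pool$idx)] <- c(dY)
  dx
}

# Bilinear interpolation matrix mapping n_in samples to n_out along one
# axis (edge replication at the borders; rows sum to one so constants are
# preserved). Upsampling is then y = A %*% x %*% t(B) per channel.
nn_bilinear_mat <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  s <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  i0 <- floor(s)
  w1 <- s - i0
  i0c <- pmin(pmax(i0, 1), n_in)
  i1c <- pmin(i0 + 1, n_in)
  for (i in seq_len(n_out)) {
    A[i, i0c[i]] <- A[i, i0c[i]] + (1 - w1[i])
    A[i, i1c[i]] <- A[i, i1c[i]] + w1[i]
  }
  A
}

nn_bilinear_fwd <- function(x, A, B) {
  d <- dim(x)
  y <- array(0, c(nrow(A), nrow(B), d[3], d[4]))
  for (n in seq_len(d[4])) for (ci in seq_len(d[3]))
    y[, , ci, n] <- A %*% x[, , ci, n] %*% t(B)
  y
}

nn_bilinear_bwd <- function(dY, A, B, dims_in) {
  dx <- array(0, dims_in)
  for (n in seq_len(dims_in[4])) for (ci in seq_len(dims_in[3]))
    dx[, , ci, n] <- crossprod(A, dY[, , ci, n]) %*% B
  dx
}

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

# Concatenate two [H, W, C, N] maps along the channel axis.
cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}
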