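# The D2FC-DN: a fully convolutional DenseNet encoder with dilated dense
# blocks, a plain transition-up decoder, three-level skip connections and
# three deep-supervision heads.
#
# Encoder: 7x7 conv -> 3 x (dilated dense block, transition down) ->
# bottleneck dilated dense block. Dense-block layer j is
# BN -> ReLU -> 3x3 conv with dilation j; the block output is the
# channel concatenation of the per-layer outputs (n_layers * growth
# channels). The skip tensor at each level is the concatenation of the
# block input and block output, which also feeds the transition down
# (BN -> ReLU -> 1x1 conv -> 2x2 max pool).
#
# Decoder: three transition-ups (BN -> ReLU -> 3x3 transposed conv,
# stride 2); each output is concatenated with the skip at its resolution
# before the next stage; after the last one, two 3x3 convs produce the
# single-channel probability map (sigmoid). A 1x1-conv head after each
# transition-up is bilinearly upsampled to the input resolution and
# squashed to [0, 1] for deep supervision during training.

#' Architecture specification for the D2FC-DN
#'
#' With the defaults this reproduces the reference D2FC-DN architecture exactly:
#' input 384x192x1, dense-block layer counts 4/5/6/7, growth rates
#' 8/16/32/64 (the layer count grows by one and the growth rate doubles
#' at each downsampling), transition-down widths 32/64/128, transition-up
#' widths 448/192/96, and final 3x3 convolutions to 32 and 1 channels.
#' `growth0` and `n0` scale the whole family down for desk-scale
#' experiments while preserving those structural rules.
#'
#' @param input_size integer `(height, width)` of the input image in
#'   pixels; both must be divisible by 8 (three 2x downsamplings).
#' @param growth0 growth rate of the first level (channels contributed
#'   per dense-block layer); doubles at each downsampling.
#' @param n0 number of layers in the first dense block; increases by one
#'   at each downsampling.
#' @param threshold probability threshold for binarizing the output map.
#' @return object of class `d2fc_dn_spec`.
#' @export
d2fc_dn_spec <- function(input_size = c(192L, 384L), growth0 = 8L, n0 = 4L,
                         threshold = 0.5) {
  input_size <- as.integer(input_size)
  growth0 <- as.integer(growth0); n0 <- as.integer(n0)
  if (any(input_size %% 8L != 0L))
    stop("input size must be divisible by 8, got ", paste(input_size, collapse = "x"))
  if (growth0 < 1L || n0 < 1L) stop("growth0 and n0 must be positive")
  n_layers <- n0 + 0:3                  # 3 encoder levels + bottleneck
  growth <- growth0 * 2L^(0:3)
  spec <- list(
    input_size = input_size,
    growth0 = growth0, n0 = n0,
    n_layers = n_layers, growth = growth,
    init_channels = 2L * growth0,
    td_channels = growth0 * c(4L, 8L, 16L),
    tu_channels = c(n_layers[4] * growth[4], 24L * growth0, 12L * growth0),
    final_channels = 4L * growth0,
    threshold = threshold
  )
  class(spec) <- "d2fc_dn_spec"
  spec
}

# Channel/shape arithmetic for every stage; the single source of truth
# used by the builder, the forward pass, describe() and the tests.
d2fc_dn_channels <- function(spec) {
  cur <- spec$init_channels
  enc <- vector("list", 3L)
  skip <- integer(3L)
  for (i in 1:3) {
    blk_out <- spec$n_layers[i] * spec$growth[i]
    skip[i] <- cur + blk_out
    enc[[i]] <- list(blk_in = cur, blk_out = blk_out,
                     td_in = skip[i], td_out = spec$td_channels[i])
    cur <- spec$td_channels[i]
  }
  bot <- list(blk_in = cur, blk_out = spec$n_layers[4] * spec$growth[4])
  tu_in <- c(bot$blk_out,
             spec$tu_channels[1] + skip[3],
             spec$tu_channels[2] + skip[2])
  list(enc = enc, skip = skip, bot = bot,
       tu_in = tu_in, tu_out = spec$tu_channels,
       fin_in = spec$tu_channels[3] + skip[1],
       fin_mid = spec$final_channels)
}

gauss_init <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = init_std((kh - 1L) %/% 2L, cin)),
        c(kh, kw, cin, cout))
}

new_conv <- function(params, prefix, kh, kw, cin, cout, bn = TRUE) {
  if (bn) {
    params[[paste0(prefix, ".gamma")]] <- rep(1, cin)
    params[[paste0(prefix, ".beta")]] <- rep(0, cin)
  }
  params[[paste0(prefix, ".W")]] <- gauss_init(kh, kw, cin, cout)
  params[[paste0(prefix, ".b")]] <- rep(0, cout)
  params
}

#' Build a D2FC-DN with freshly initialized weights
#'
#' Convolution weights are drawn from a zero-mean Gaussian with the
#' adaptive standard deviation `sqrt(2 / ((2r+1)^2 c_in))` (see
#' [init_std()]); biases start at zero, batch-norm scales at one.
#'
#' @param spec a [d2fc_dn_spec()].
#' @param seed optional integer seed for reproducible initialization.
#' @return object of class `d2fc_dn`: list with elements `spec`, `params`
#'   (named list of trainable arrays) and `state` (batch-norm running
#'   statistics).
#' @export
build_d2fc_dn <- function(spec = d2fc_dn_spec(), seed = NULL) {
  stopifnot(inherits(spec, "d2fc_dn_spec"))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  ch <- d2fc_dn_channels(spec)
  params <- list()
  params <- new_conv(params, "init", 7L, 7L, 1L, spec$init_channels, bn = FALSE)
  add_block <- function(params, prefix, cin, n, k) {
    for (j in seq_len(n)) {
      params <- new_conv(params, paste0(prefix, ".l", j), 3L, 3L,
                         cin + (j - 1L) * k, k)
    }
    params
  }
  for (i in 1:3) {
    e <- ch$enc[[i]]
    params <- add_block(params, paste0("enc", i), e$blk_in,
                        spec$n_layers[i], spec$growth[i])
    params <- new_conv(params, paste0("td", i), 1L, 1L, e$td_in, e$td_out)
  }
  params <- add_block(params, "bot", ch$bot$blk_in, spec$n_layers[4], spec$growth[4])
  for (i in 1:3) {
    pre <- paste0("tu", i)
    cin <- ch$tu_in[i]; cout <- ch$tu_out[i]
    params[[paste0(pre, ".gamma")]] <- rep(1, cin)
    params[[paste0(pre, ".beta")]] <- rep(0, cin)
    # adjoint kernel [3, 3, C_out, C_in]; Gaussian std from the stage input width
    params[[paste0(pre, ".W")]] <- array(stats::rnorm(9 * cout * cin, sd = init_std(1L, cin)),
                                         c(3L, 3L, cout, cin))
    params[[paste0(pre, ".b")]] <- rep(0, cout)
    params <- new_conv(params, paste0("head", i), 1L, 1L, cout, 1L, bn = FALSE)
  }
  params <- new_conv(params, "fin1", 3L, 3L, ch$fin_in, ch$fin_mid, bn = FALSE)
  params <- new_conv(params, "fin2", 3L, 3L, ch$fin_mid, 1L, bn = FALSE)
  state <- list()
  for (nm in names(params)) {
    if (endsWith(nm, ".gamma")) {
      pre <- sub("\\.gamma$", "", nm)
      cin <- length(params[[nm]])
      state[[paste0(pre, ".rm")]] <- rep(0, cin)
      state[[paste0(pre, ".rv")]] <- rep(1, cin)
    }
  }
  net <- list(spec = spec, params = params, state = state)
  class(net) <- "d2fc_dn"
  net
}

#' Run a dilated dense block forward
#'
#' A dense block of `n_layers` layers, each batch-norm -> ReLU -> 3x3
#' dilated convolution contributing `growth_rate` channels; the input
#' and the outputs of earlier layers are concatenated to feed each next
#' layer, and the block output is the concatenation of the per-layer
#' outputs only, so it always has `n_layers * growth_rate` channels.
#' The default dilation schedule is 1, 2, ..., `n_layers` (the receptive
#' field widens with depth). Weights are drawn freshly under `seed`,
#' which makes this a convenient single-block probe; inside a network
#' the blocks share the same code path with trained weights.
#'
#' @param x input feature map (matrix, `[H, W, C]` or `[H, W, C, N]`).
#' @param n_layers number of layers in the block.
#' @param growth_rate channels contributed per layer.
#' @param dilation_schedule per-layer dilation factors; length must
#'   equal `n_layers`.
#' @param seed seed for the fresh weights.
#' @return feature map `[H, W, n_layers * growth_rate, N]`.
#' @export
dense_block_forward <- function(x, n_layers, growth_rate,
                                dilation_schedule = seq_len(n_layers),
                                seed = 1L) {
  x <- as_featuremap(x)
  if (length(dilation_schedule) != n_layers)
    stop("dilation_schedule length (", length(dilation_schedule),
         ") must equal n_layers (", n_layers, ")")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  outs <- vector("list", n_layers)
  cur <- x
  for (j in seq_len(n_layers)) {
    cin <- dim(cur)[3]
    bn <- nn_bn_fwd(cur, rep(1, cin), rep(0, cin), rep(0, cin), rep(1, cin),
                    train = TRUE)
    r <- pmax(bn$y, 0)
    W <- gauss_init(3L, 3L, cin, growth_rate)
    outs[[j]] <- nn_conv_fwd(r, W, rep(0, growth_rate),
                             dil = dilation_schedule[j])
    if (j < n_layers) cur <- cat_channels(cur, outs[[j]])
  }
  out <- outs[[1]]
  for (j in seq_len(n_layers)[-1]) out <- cat_channels(out, outs[[j]])
  out
}

#' Transition down / transition up layers
#'
#' `transition_down` halves the spatial resolution: batch-norm, ReLU,
#' 1x1 convolution to `out_channels`, then 2x2 max pooling with
#' stride 2 (requires even spatial dims). `transition_up` doubles it:
#' batch-norm, ReLU, 3x3 transposed convolution with stride 2.
#' Both draw fresh weights under `seed` (see [dense_block_forward()]).
#'
#' @param x input feature map.
#' @param out_channels channels of the produced map.
#' @param seed seed for the fresh weights.
#' @return feature map with halved (resp. doubled) spatial dims and
#'   `out_channels` channels.
#' @export
transition_down <- function(x, out_channels, seed = 1L) {
  x <- as_featuremap(x)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  cin <- dim(x)[3]
  bn <- nn_bn_fwd(x, rep(1, cin), rep(0, cin), rep(0, cin), rep(1, cin),
                  train = TRUE)
  r <- pmax(bn$y, 0)
  cv <- nn_conv_fwd(r, gauss_init(1L, 1L, cin, out_channels), rep(0, out_channels))
  nn_maxpool_fwd(cv, want_idx = FALSE)$y
}

#' @rdname transition_down
#' @export
transition_up <- function(x, out_channels, seed = 1L) {
  x <- as_featuremap(x)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  cin <- dim(x)[3]
  bn <- nn_bn_fwd(x, rep(1, cin), rep(0, cin), rep(0, cin), rep(1, cin),
                  train = TRUE)
  r <- pmax(bn$y, 0)
  Wt <- array(stats::rnorm(9 * out_channels * cin, sd = init_std(1L, cin)),
              c(3L, 3L, out_channels, cin))
  nn_tconv_fwd(r, Wt, rep(0, out_channels))
}

#' Number of trainable parameters of a network
#'
#' Counts every trainable weight and bias, including batch-norm scales
#' and shifts and the three supervision heads. The full reference
#' architecture comes to approximately 4.97 million.
#'
#' @param net a `d2fc_dn` object.
#' @return integer count.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "d2fc_dn"))
  sum(vapply(net$params, length, integer(1)))
}

# ---- forward ---------------------------------------------------------------

bn_relu <- function(net, prefix, x, train, cache_env) {
  p <- net$params
  bn <- nn_bn_fwd(x, p[[paste0(prefix, ".gamma")]], p[[paste0(prefix, ".beta")]],
                  net$state[[paste0(prefix, ".rm")]], net$state[[paste0(prefix, ".rv")]],
                  train = train)
  if (train) {
    cache_env$state[[paste0(prefix, ".rm")]] <- bn$rmean
    cache_env$state[[paste0(prefix, ".rv")]] <- bn$rvar
  }
  r <- pmax(bn$y, 0)
  if (!is.null(cache_env$c)) cache_env$c[[prefix]] <- list(bn = bn$cache, relu_in = bn$y)
  r
}

dense_block_fwd <- function(net, prefix, x, n, k, train, cache_env) {
  outs <- vector("list", n)
  cur <- x
  for (j in seq_len(n)) {
    lp <- paste0(prefix, ".l", j)
    r <- bn_relu(net, lp, cur, train, cache_env)
    keep <- !is.null(cache_env$c)
    cv <- nn_conv_fwd(r, net$params[[paste0(lp, ".W")]],
                      net$params[[paste0(lp, ".b")]], dil = j, want_cols = keep)
    if (keep) {
      cache_env$c[[lp]]$conv_in <- r
      cache_env$c[[lp]]$cols <- cv$cols
      outs[[j]] <- cv$y
    } else outs[[j]] <- cv
    if (j < n) cur <- cat_channels(cur, outs[[j]])
  }
  out <- outs[[1]]
  for (j in seq_len(n)[-1]) out <- cat_channels(out, outs[[j]])
  out
}

# Forward pass. Returns the main probability map, the three head maps
# (full resolution, in [0, 1]), and -- when caching -- everything the
# backward pass needs. `cache_env$state` carries updated BN running stats.
d2fc_dn_forward <- function(net, x, train = FALSE, keep_cache = FALSE) {
  spec <- net$spec
  x <- as_featuremap(x)
  d <- dim(x)
  if (d[1] != spec$input_size[1] || d[2] != spec$input_size[2] || d[3] != 1L)
    stop("input must be ", spec$input_size[1], "x", spec$input_size[2],
         "x1, got ", paste(d[1:3], collapse = "x"))
  ce <- new.env(parent = emptyenv())
  ce$state <- list()
  ce$c <- if (keep_cache) list() else NULL
  p <- net$params

  cur <- nn_conv_fwd(x, p[["init.W"]], p[["init.b"]])
  if (keep_cache) ce$c[["init"]] <- list(conv_in = x)
  skips <- vector("list", 3L)
  for (i in 1:3) {
    blk <- dense_block_fwd(net, paste0("enc", i), cur, spec$n_layers[i],
                           spec$growth[i], train, ce)
    skips[[i]] <- cat_channels(cur, blk)
    tp <- paste0("td", i)
    r <- bn_relu(net, tp, skips[[i]], train, ce)
    if (keep_cache) ce$c[[tp]]$conv_in <- r
    cv <- nn_conv_fwd(r, p[[paste0(tp, ".W")]], p[[paste0(tp, ".b")]])
    pool <- nn_maxpool_fwd(cv, want_idx = keep_cache)
    if (keep_cache) ce$c[[tp]]$pool <- pool[c("idx", "dims")]
    cur <- pool$y
  }
  dec <- dense_block_fwd(net, "bot", cur, spec$n_layers[4], spec$growth[4], train, ce)

  heads <- vector("list", 3L)
  for (i in 1:3) {
    tp <- paste0("tu", i)
    r <- bn_relu(net, tp, dec, train, ce)
    if (keep_cache) ce$c[[tp]]$conv_in <- r
    tu <- nn_tconv_fwd(r, p[[paste0(tp, ".W")]], p[[paste0(tp, ".b")]])
    hp <- paste0("head", i)
    hconv <- nn_conv_fwd(tu, p[[paste0(hp, ".W")]], p[[paste0(hp, ".b")]])
    A <- nn_bilinear_mat(dim(hconv)[1], spec$input_size[1])
    B <- nn_bilinear_mat(dim(hconv)[2], spec$input_size[2])
    hprob <- nn_sigmoid(nn_bilinear_fwd(hconv, A, B))
    heads[[i]] <- hprob
    if (keep_cache)
      ce$c[[hp]] <- list(conv_in = tu, A = A, B = B, prob = hprob,
                         dims_in = dim(hconv))
    dec <- cat_channels(tu, skips[[4L - i]])
  }
  cv1 <- nn_conv_fwd(dec, p[["fin1.W"]], p[["fin1.b"]], want_cols = keep_cache)
  f1 <- if (keep_cache) cv1$y else cv1
  f1r <- pmax(f1, 0)
  cv2 <- nn_conv_fwd(f1r, p[["fin2.W"]], p[["fin2.b"]], want_cols = keep_cache)
  f2 <- if (keep_cache) cv2$y else cv2
  main <- nn_sigmoid(f2)
  if (keep_cache) {
    ce$c[["fin1"]] <- list(conv_in = dec, relu_in = f1, cols = cv1$cols)
    ce$c[["fin2"]] <- list(conv_in = f1r, cols = cv2$cols)
    ce$c[["main_prob"]] <- main
    ce$c[["skip_ch"]] <- vapply(skips, function(s) dim(s)[3], integer(1))
  }
  list(main = main, heads = heads, cache = ce)
}

# ---- backward --------------------------------------------------------------

bwd_conv_unit <- function(net, prefix, cache, dY, grads, dil = 1L, bn = TRUE) {
  cc <- cache[[prefix]]
  cb <- nn_conv_bwd(cc$conv_in, net$params[[paste0(prefix, ".W")]], dY, dil = dil,
                    cols_cache = cc$cols)
  grads[[paste0(prefix, ".W")]] <- grads_add(grads[[paste0(prefix, ".W")]], cb$dW)
  grads[[paste0(prefix, ".b")]] <- grads_add(grads[[paste0(prefix, ".b")]], cb$db)
  dx <- cb$dx
  if (bn) {
    dr <- dx * (cc$relu_in > 0)
    bb <- nn_bn_bwd(cc$bn, net$params[[paste0(prefix, ".gamma")]], dr)
    grads[[paste0(prefix, ".gamma")]] <- grads_add(grads[[paste0(prefix, ".gamma")]], bb$dgamma)
    grads[[paste0(prefix, ".beta")]] <- grads_add(grads[[paste0(prefix, ".beta")]], bb$dbeta)
    dx <- bb$dx
  }
  list(dx = dx, grads = grads)
}

grads_add <- function(a, b) if (is.null(a)) b else a + b

dense_block_bwd <- function(net, prefix, cache, dOut, n, k, c0, grads) {
  dextra <- vector("list", n)   # grads reaching out_j through later layers
  dx_in <- NULL
  for (j in rev(seq_len(n))) {
    dyj <- dOut[, , (j - 1L) * k + seq_len(k), , drop = FALSE]
    if (!is.null(dextra[[j]])) dyj <- dyj + dextra[[j]]
    u <- bwd_conv_unit(net, paste0(prefix, ".l", j), cache, dyj, grads, dil = j)
    grads <- u$grads
    dinp <- u$dx                 # channels: c0 + (j-1)*k
    dx_in <- grads_add(dx_in, dinp[, , seq_len(c0), , drop = FALSE])
    if (j > 1L) for (jj in seq_len(j - 1L)) {
      sl <- dinp[, , c0 + (jj - 1L) * k + seq_len(k), , drop = FALSE]
      dextra[[jj]] <- grads_add(dextra[[jj]], sl)
    }
  }
  list(dx = dx_in, grads = grads)
}

# Backward pass from gradients w.r.t. the main and head probability maps.
d2fc_dn_backward <- function(net, cache_env, dMain, dHeads) {
  spec <- net$spec
  cache <- cache_env$c
  grads <- list()
  ch <- d2fc_dn_channels(spec)
  skip_ch <- cache[["skip_ch"]]

  main <- cache[["main_prob"]]
  df2 <- dMain * main * (1 - main)
  u <- bwd_conv_unit(net, "fin2", cache, df2, grads, bn = FALSE); grads <- u$grads
  df1 <- u$dx * (cache[["fin1"]]$relu_in > 0)
  u <- bwd_conv_unit(net, "fin1", cache, df1, grads, bn = FALSE); grads <- u$grads
  ddec <- u$dx                               # concat(tu3 out, skip 1)

  dskip <- vector("list", 3L)
  for (i in 3:1) {
    tun <- ch$tu_out[i]
    dtu <- ddec[, , seq_len(tun), , drop = FALSE]
    dskip[[4L - i]] <- ddec[, , tun + seq_len(skip_ch[4L - i]), , drop = FALSE]
    hp <- paste0("head", i)
    hc <- cache[[hp]]
    if (!is.null(dHeads[[i]])) {
      dprob <- dHeads[[i]] * hc$prob * (1 - hc$prob)
      dhconv <- nn_bilinear_bwd(dprob, hc$A, hc$B, hc$dims_in)
      u <- bwd_conv_unit(net, hp, cache, dhconv, grads, bn = FALSE)
      grads <- u$grads
      dtu <- dtu + u$dx
    }
    tp <- paste0("tu", i)
    tc <- cache[[tp]]
    tb <- nn_tconv_bwd(tc$conv_in, net$params[[paste0(tp, ".W")]], dtu)
    grads[[paste0(tp, ".W")]] <- grads_add(grads[[paste0(tp, ".W")]], tb$dW)
    grads[[paste0(tp, ".b")]] <- grads_add(grads[[paste0(tp, ".b")]], tb$db)
    dr <- tb$du * (tc$relu_in > 0)
    bb <- nn_bn_bwd(tc$bn, net$params[[paste0(tp, ".gamma")]], dr)
    grads[[paste0(tp, ".gamma")]] <- grads_add(grads[[paste0(tp, ".gamma")]], bb$dgamma)
    grads[[paste0(tp, ".beta")]] <- grads_add(grads[[paste0(tp, ".beta")]], bb$dbeta)
    # grad w.r.t. this stage's input: concat(tu_{i-1} out, skip) for i > 1,
    # the bottleneck output for i == 1
    ddec <- bb$dx
  }
  # ddec is now the gradient w.r.t. the bottleneck block output
  u <- dense_block_bwd(net, "bot", cache, ddec, spec$n_layers[4], spec$growth[4],
                       ch$bot$blk_in, grads)
  grads <- u$grads
  dcur <- u$dx
  for (i in 3:1) {
    tp <- paste0("td", i)
    tc <- cache[[tp]]
    dpool <- nn_maxpool_bwd(list(idx = tc$pool$idx, dims = tc$pool$dims), dcur)
    u <- bwd_conv_unit(net, tp, cache, dpool, grads); grads <- u$grads
    dcat <- u$dx + dskip[[i]]
    c_in <- ch$enc[[i]]$blk_in
    dblk <- dcat[, , c_in + seq_len(ch$enc[[i]]$blk_out), , drop = FALSE]
    u <- dense_block_bwd(net, paste0("enc", i), cache, dblk,
                         spec$n_layers[i], spec$growth[i], c_in, grads)
    grads <- u$grads
    dcur <- dcat[, , seq_len(c_in), , drop = FALSE] + u$dx
  }
  u <- bwd_conv_unit(net, "init", cache, dcur, grads, bn = FALSE)
  u$grads
}

#' Forward inference with probability thresholding
#'
#' Runs the network in inference mode (batch-norm running statistics) and
#' binarizes the main output map at the spec threshold (probability >=
#' threshold is foreground). The supervision heads are not used at
#' inference.
#'
#' @param net a trained (or freshly built) `d2fc_dn`.
#' @param img numeric matrix `[H, W]` with intensities in `[0, 1]`, or an
#'   `[H, W, 1, N]` array for a batch.
#' @return binary mask matrix (or `[H, W, 1, N]` array for batches).
#' @export
predict_mask <- function(net, img) {
  was_matrix <- is.matrix(img)
  x <- as_featuremap(img)
  out <- d2fc_dn_forward(net, x, train = FALSE, keep_cache = FALSE)
  m <- (out$main >= net$spec$threshold) * 1L
  if (was_matrix) matrix(m[, , 1, 1], dim(x)[1], dim(x)[2]) else m
}

#' Probability maps of the three supervision heads
#'
#' @param net a `d2fc_dn`.
#' @param img input image as in [predict_mask()].
#' @return list of three `[H, W, 1, N]` arrays with values in `[0, 1]`,
#'   ordered coarsest to finest supervision level.
#' @export
supervision_heads <- function(net, img) {
  x <- as_featuremap(img)
  d2fc_dn_forward(net, x, train = FALSE)$heads
}

#' Stage-by-stage architecture table
#'
#' Lists every stage of the network with its output size (width x height
#' x channels, matching the reference layout) and parameter count.
#'
#' @param spec a [d2fc_dn_spec()].
#' @return data frame with columns `layer`, `output_size`, `params`.
#' @export
describe_d2fc_dn <- function(spec = d2fc_dn_spec()) {
  stopifnot(inherits(spec, "d2fc_dn_spec"))
  ch <- d2fc_dn_channels(spec)
  H <- spec$input_size[1]; W <- spec$input_size[2]
  sz <- function(h, w, c) sprintf("%d x %d x %d", w, h, c)
  conv_p <- function(kh, kw, cin, cout, bn = TRUE) {
    kh * kw * cin * cout + cout + if (bn) 2 * cin else 0
  }
  block_p <- function(cin, n, k) {
    sum(vapply(seq_len(n), function(j) conv_p(3, 3, cin + (j - 1) * k, k), numeric(1)))
  }
  rows <- list(list("Input", sz(H, W, 1L), 0))
  rows <- c(rows, list(list("Convolution 7x7", sz(H, W, spec$init_channels),
                            conv_p(7, 7, 1, spec$init_channels, bn = FALSE))))
  h <- H; w <- W
  for (i in 1:3) {
    e <- ch$enc[[i]]
    rows <- c(rows, list(
      list(sprintf("Dilated dense block [3x3 dilated conv] x %d, k = %d",
                   spec$n_layers[i], spec$growth[i]),
           sz(h, w, e$blk_out), block_p(e$blk_in, spec$n_layers[i], spec$growth[i]))))
    h <- h %/% 2L; w <- w %/% 2L
    rows <- c(rows, list(
      list("Transition down (1x1 conv, 2x2 max pool)", sz(h, w, e$td_out),
           conv_p(1, 1, e$td_in, e$td_out))))
  }
  rows <- c(rows, list(
    list(sprintf("Dilated dense block [3x3 dilated conv] x %d, k = %d",
                 spec$n_layers[4], spec$growth[4]),
         sz(h, w, ch$bot$blk_out),
         block_p(ch$bot$blk_in, spec$n_layers[4], spec$growth[4]))))
  for (i in 1:3) {
    h <- h * 2L; w <- w * 2L
    rows <- c(rows, list(
      list("Transition up (3x3 transposed conv, stride 2)", sz(h, w, ch$tu_out[i]),
           9 * ch$tu_in[i] * ch$tu_out[i] + ch$tu_out[i] + 2 * ch$tu_in[i])))
    rows <- c(rows, list(
      list(sprintf("Supervision head %d (1x1 conv, bilinear up)", i),
           sz(H, W, 1L), conv_p(1, 1, ch$tu_out[i], 1, bn = FALSE))))
  }
  rows <- c(rows, list(
    list("Convolution 3x3", sz(H, W, ch$fin_mid),
         conv_p(3, 3, ch$fin_in, ch$fin_mid, bn = FALSE)),
    list("Convolution 3x3", sz(H, W, 1L),
         conv_p(3, 3, ch$fin_mid, 1, bn = FALSE))))
  data.frame(layer = vapply(rows, `[[`, character(1), 1),
             output_size = vapply(rows, `[[`, character(1), 2),
             params = vapply(rows, function(r) as.numeric(r[[3]]), numeric(1)),
             stringsAsFactors = FALSE)
}

#' @export
print.d2fc_dn <- function(x, ...) {
  tab <- describe_d2fc_dn(x$spec)
  cat(sprintf("D2FC-DN: input %d x %d, growth %d..%d, layers %s\n",
              x$spec$input_size[2], x$spec$input_size[1],
              x$spec$growth[1], x$spec$growth[4],
              paste(x$spec$n_layers, collapse = "/")))
  print(tab, row.names = FALSE)
  cat(sprintf("Total trainable parameters: %s (%.2f million)\n",
              format(count_parameters(x), big.mark = ","),
              count_parameters(x) / 1e6))
  invisible(x)
}

#' Save / load a network checkpoint
#'
#' The checkpoint embeds the architecture spec, all weights and the
#' batch-norm running statistics, so a reloaded network predicts
#' identically.
#'
#' @param net a `d2fc_dn`.
#' @param path file path for the checkpoint.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the network.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "d2fc_dn"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "d2fc_dn")) stop("not a d2fc_dn checkpoint: ", path)
  net
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
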