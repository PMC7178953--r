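# Architecture construction, shape arithmetic, dilated convolution
# semantics, and inference behavior.

tiny_spec <- function() d2fc_dn_spec(input_size = c(16, 24), growth0 = 1, n0 = 1)

test_that("dilated convolution follows the discrete summation and its special cases", {
  set.seed(5)
  # delta kernel: identity for any dilation factor
  delta <- array(0, c(3, 3, 1, 1)); delta[2, 2, 1, 1] <- 1
  f <- matrix(runif(16 * 16), 16, 16)
  for (l in 1:3) {
    out <- dilated_conv(f, delta, dilation = l)
    expect_equal(out[, , 1, 1], f, tolerance = 1e-14)
  }
  # impulse through a 3x3 all-ones kernel at l = 2: nine taps 2 px apart
  ones <- array(1, c(3, 3, 1, 1))
  imp <- matrix(0, 16, 16); imp[8, 8] <- 1
  out <- dilated_conv(imp, ones, dilation = 2)[, , 1, 1]
  nz <- which(out != 0, arr.ind = TRUE)
  expect_equal(nrow(nz), 9)
  expect_setequal(nz[, 1], c(6, 8, 10))
  expect_setequal(nz[, 2], c(6, 8, 10))
  expect_error(dilated_conv(f, ones, dilation = 0), "dilation")
})

test_that("dilated convolution matches direct summation, and l = 1 is plain convolution", {
  set.seed(6)
  for (rep in 1:5) {
    f <- matrix(rnorm(16 * 16), 16, 16)
    k <- array(rnorm(9), c(3, 3, 1, 1))
    for (l in c(1, 2, 3)) {
      got <- dilated_conv(f, k, dilation = l)[, , 1, 1]
      want <- oracle_dilated_conv(f, k[, , 1, 1], l)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("dense block output channels equal n_layers * growth_rate", {
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  expect_equal(dim(dense_block_forward(x, 4, 4))[3], 16)
  expect_equal(dim(dense_block_forward(x, 1, 1))[3], 1)
  x16 <- array(runif(16 * 24 * 16), c(16, 24, 16))
  out <- dense_block_forward(x16, 4, 8)
  expect_equal(dim(out)[1:3], c(16, 24, 32))
  # randomized sweep of the channel rule
  set.seed(7)
  for (i in 1:5) {
    n <- sample(1:5, 1); k <- sample(1:6, 1)
    expect_equal(dim(dense_block_forward(x, n, k))[3], n * k)
  }
  expect_error(dense_block_forward(x, 3, 4, dilation_schedule = c(1, 2)),
               "dilation_schedule")
})

test_that("transition layers halve and double resolution as specified", {
  x <- array(runif(16 * 24 * 6), c(16, 24, 6))
  dn <- transition_down(x, 4)
  expect_equal(dim(dn)[1:3], c(8, 12, 4))
  up <- transition_up(dn, 6)
  expect_equal(dim(up)[1:3], c(16, 24, 6))        # doubling inverts halving
  same <- transition_down(x, 6)
  expect_equal(dim(same)[3], 6)                   # channel identity allowed
  odd <- array(runif(15 * 24 * 2), c(15, 24, 2))
  expect_error(transition_down(odd, 2), "even")
})

test_that("the built network reproduces the reference stage table", {
  tab <- describe_d2fc_dn(d2fc_dn_spec())
  expect_equal(tab$output_size, c(
    "384 x 192 x 1", "384 x 192 x 16", "384 x 192 x 32", "192 x 96 x 32",
    "192 x 96 x 80", "96 x 48 x 64", "96 x 48 x 192", "48 x 24 x 128",
    "48 x 24 x 448", "96 x 48 x 448", "384 x 192 x 1", "192 x 96 x 192",
    "384 x 192 x 1", "384 x 192 x 96", "384 x 192 x 1", "384 x 192 x 32",
    "384 x 192 x 1"))
  net <- build_d2fc_dn(d2fc_dn_spec(), seed = 1)
  expect_equal(count_parameters(net), sum(tab$params))
  expect_error(d2fc_dn_spec(input_size = c(100, 384)), "divisible by 8")
})

test_that("parameter bookkeeping agrees between builder and analytic table", {
  for (sp in list(tiny_spec(), d2fc_dn_spec(input_size = c(48, 96), growth0 = 2, n0 = 2))) {
    net <- build_d2fc_dn(sp, seed = 3)
    expect_equal(count_parameters(net), sum(describe_d2fc_dn(sp)$params))
  }
})

test_that("forward pass shapes, determinism, and head contracts hold", {
  sp <- tiny_spec()
  net <- build_d2fc_dn(sp, seed = 2)
  img <- matrix(runif(16 * 24), 16, 24)
  m1 <- predict_mask(net, img)
  expect_equal(dim(m1), c(16, 24))
  expect_true(all(m1 %in% c(0L, 1L)))
  expect_identical(m1, predict_mask(net, img))    # deterministic inference
  heads <- supervision_heads(net, img)
  expect_length(heads, 3)
  for (h in heads) {
    expect_equal(dim(h)[1:3], c(16, 24, 1))
    expect_true(all(h >= 0 & h <= 1))
  }
  expect_error(predict_mask(net, matrix(0, 8, 8)), "input must be")
  # same seed rebuilds identical weights
  net2 <- build_d2fc_dn(sp, seed = 2)
  expect_identical(net$params, net2$params)
})

test_that("probability exactly at threshold maps to foreground", {
  sp <- tiny_spec()
  net <- build_d2fc_dn(sp, seed = 4)
  net$params[["fin2.W"]][] <- 0
  net$params[["fin2.b"]][] <- 0                   # logit 0 -> probability 0.5
  m <- predict_mask(net, matrix(runif(16 * 24), 16, 24))
  expect_true(all(m == 1L))
})

test_that("bilinear upsampling preserves constants and head-map averages", {
  A <- tenduseg:::nn_bilinear_mat(6, 24)
  B <- tenduseg:::nn_bilinear_mat(4, 16)
  expect_equal(rowSums(A), rep(1, 24))
  x <- array(3.5, c(6, 4, 1, 1))
  y <- tenduseg:::nn_bilinear_fwd(x, A, B)
  expect_equal(c(y), rep(3.5, 24 * 16))
  # identity when sizes match
  expect_equal(tenduseg:::nn_bilinear_mat(8, 8), diag(8))
})

test_that("checkpoints round-trip the whole network", {
  sp <- tiny_spec()
  net <- build_d2fc_dn(sp, seed = 9)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(net, f)
  net2 <- load_checkpoint(f)
  img <- matrix(runif(16 * 24), 16, 24)
  expect_identical(predict_mask(net, img), predict_mask(net2, img))
  unlink(f)
})
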