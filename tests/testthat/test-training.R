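# Initialization, learning-rate schedule, loss arithmetic, and the
# training loop's contracts.

test_that("adaptive initialization std follows the closed form", {
  expect_equal(init_std(0, 2), 1)
  expect_equal(init_std(1, 16), sqrt(2 / 144))
  expect_equal(init_std(2, 3), sqrt(2 / (25 * 3)))
  expect_equal(init_std(1, 64), init_std(1, 16) / 2)  # 4x channels halves it
  expect_error(init_std(1, 0), "positive")
})

test_that("polynomial decay schedule hits its endpoints and decreases", {
  cfg <- train_config(epochs = 50)
  expect_equal(lr_at_epoch(0, cfg), 5e-4)
  expect_equal(lr_at_epoch(50, cfg), 0)
  expect_equal(lr_at_epoch(25, cfg), 5e-4 * 0.5^1.5)
  expect_error(lr_at_epoch(51, cfg), "exceeds")
  lrs <- vapply(0:50, lr_at_epoch, numeric(1), cfg = cfg)
  expect_true(all(diff(lrs) < 0))
})

test_that("soft Dice value: closed forms, symmetry, permutation invariance", {
  q <- matrix(rbinom(64, 1, 0.5), 8, 8)
  if (sum(q) == 0) q[1, 1] <- 1
  expect_equal(dice_value(q, q), 1, tolerance = 1e-6)
  p_disj <- 1 - q
  expect_equal(dice_value(p_disj * q, q), 0, tolerance = 1e-6)
  # p = 0.5 everywhere, q foreground on exactly half the pixels -> 2/3
  p <- matrix(0.5, 8, 8)
  qh <- matrix(c(rep(1, 32), rep(0, 32)), 8, 8)
  expect_equal(dice_value(p, qh, eps = 0), 2 / 3)
  # symmetric for binary arguments, invariant under joint permutation
  a <- matrix(rbinom(64, 1, 0.4), 8, 8); b <- matrix(rbinom(64, 1, 0.4), 8, 8)
  expect_equal(dice_value(a, b), dice_value(b, a))
  perm <- sample(64)
  expect_equal(dice_value(c(p)[perm], c(qh)[perm], eps = 0), 2 / 3)
  expect_error(dice_value(matrix(0, 2, 2), matrix(0, 3, 3)), "differ")
})

test_that("total loss combines the supervision terms with the stated weights", {
  expect_equal(total_loss(1, c(1, 1, 1)), 0)
  expect_equal(total_loss(0.8, c(1, 1, 1)), 0.2)
  expect_equal(total_loss(1, c(0, 0, 0)), 1 / 16 + 1 / 8 + 1 / 4)
  expect_equal(total_loss(1, c(0, 0, 0)), 0.4375)
  expect_error(total_loss(1, c(1, 1)), "supervised")
  set.seed(14)
  for (i in 1:20) {
    v <- total_loss(runif(1), runif(3))
    expect_gte(v, 0); expect_lte(v, 1.4375)
  }
})

phantom_set <- function(n, seed, size = c(16, 24)) {
  ds <- generate_dataset(n, clear_fraction = 0.5, seed = seed, image_size = size)
  list(images = lapply(ds, function(d) d$image / 255),
       masks = lapply(ds, function(d) d$tendon))
}

test_that("a short training run logs per-epoch losses and tends to decrease", {
  sp <- d2fc_dn_spec(input_size = c(16, 24), growth0 = 1, n0 = 1)
  improved <- 0
  for (seed in 1:3) {
    d <- phantom_set(8, seed)
    net <- build_d2fc_dn(sp, seed = seed)
    cfg <- train_config(epochs = 2, augment = NULL)
    net <- train_d2fc_dn(net, d$images, d$masks, cfg, seed = seed)
    expect_equal(nrow(net$log), 2)
    expect_true(all(is.finite(net$log$total_loss)))
    if (net$log$total_loss[2] <= net$log$total_loss[1]) improved <- improved + 1
  }
  expect_gte(improved, 1)
})

test_that("training is bit-identical under a fixed seed", {
  sp <- d2fc_dn_spec(input_size = c(16, 24), growth0 = 1, n0 = 1)
  d <- phantom_set(6, 5)
  cfg <- train_config(epochs = 2, augment = augment_spec(online_translation = 2L))
  n1 <- train_d2fc_dn(build_d2fc_dn(sp, seed = 5), d$images, d$masks, cfg, seed = 11)
  n2 <- train_d2fc_dn(build_d2fc_dn(sp, seed = 5), d$images, d$masks, cfg, seed = 11)
  expect_identical(n1$log, n2$log)
  expect_identical(n1$params, n2$params)
})

test_that("zero supervision weights reduce exactly to single-output Dice training", {
  sp <- d2fc_dn_spec(input_size = c(16, 24), growth0 = 1, n0 = 1)
  d <- phantom_set(6, 8)
  cfg_w0 <- train_config(epochs = 2, weights = c(0, 0, 0), augment = NULL)
  cfg_off <- train_config(epochs = 2, supervision = FALSE, augment = NULL)
  n1 <- train_d2fc_dn(build_d2fc_dn(sp, seed = 6), d$images, d$masks, cfg_w0, seed = 3)
  n2 <- train_d2fc_dn(build_d2fc_dn(sp, seed = 6), d$images, d$masks, cfg_off, seed = 3)
  expect_equal(n1$params, n2$params, tolerance = 1e-12)
  expect_equal(n1$log$total_loss, n2$log$total_loss, tolerance = 1e-12)
})

test_that("training rejects bad inputs", {
  sp <- d2fc_dn_spec(input_size = c(16, 24), growth0 = 1, n0 = 1)
  net <- build_d2fc_dn(sp, seed = 1)
  expect_error(train_d2fc_dn(net, list(), list(), train_config(epochs = 1)),
               "empty")
  expect_error(train_d2fc_dn(net, list(matrix(0, 8, 8)), list(matrix(0L, 8, 8)),
                             train_config(epochs = 1)),
               "must be 16x24")
})
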