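# Phantom generator: determinism, anatomical containment, convexity of
# the tendon, the clear/fuzzy window classifier, and dataset-level
# properties.

test_that("phantom generation is a pure function of its spec", {
  sp <- phantom_spec(seed = 42)
  p1 <- generate_phantom(sp)
  p2 <- generate_phantom(sp)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$tendon, p2$tendon)
  expect_identical(p1$sheath, p2$sheath)
  expect_true(all(p1$image >= 0 & p1$image <= 255))
})

test_that("phantom spec invariants are enforced by name", {
  expect_error(phantom_spec(bottom_contrast = -1), "bottom_contrast")
  expect_error(phantom_spec(tendon_center = c(10, 192)), "inside the image")
  expect_error(phantom_spec(tendon_center = c(30, 192),
                            tendon_axes = c(28, 50)), "sheath ring")
})

test_that("the tendon lies inside the sheath for randomized specs", {
  ds <- generate_dataset(100, clear_fraction = 0.5, seed = 9,
                         image_size = c(96, 96))
  for (d in ds) {
    expect_gt(sum(d$tendon), 0)
    expect_gt(sum(d$sheath), sum(d$tendon))
    expect_true(all(d$sheath[d$tendon == 1L] == 1L))    # tendon subset of sheath
    expect_true(all(d$tendon %in% c(0L, 1L)))
  }
})

test_that("ring-mode sheath masks exclude the tendon", {
  sp <- phantom_spec(seed = 3)
  ph <- generate_phantom(sp, sheath_mode = "ring")
  expect_equal(sum(ph$sheath & ph$tendon), 0)
})

test_that("elliptical tendons are convex to within rasterization", {
  for (seed in 1:5) {
    ph <- generate_phantom(phantom_spec(seed = seed))
    expect_lte(chd(ph$tendon), 1)
  }
})

test_that("the window classifier implements the strict 30-point rule", {
  H <- 96; W <- 96
  tendon <- matrix(0L, H, W)
  tendon[20:60, 30:70] <- 1L
  img <- matrix(60, H, W)
  img[1:60, ] <- 100                       # above window mean 100, below 60
  expect_equal(classify_clear_fuzzy(img, tendon), "clear")
  expect_equal(classify_clear_fuzzy(matrix(80, H, W), tendon), "fuzzy")
  img30 <- matrix(60, H, W); img30[1:60, ] <- 90
  expect_equal(classify_clear_fuzzy(img30, tendon), "fuzzy")   # tie is fuzzy
  low <- matrix(0L, H, W); low[88:95, 40:60] <- 1L
  expect_error(classify_clear_fuzzy(img, low), "out of image bounds")
})

test_that("generated datasets realize their intended clear fraction", {
  ds <- generate_dataset(10, clear_fraction = 1, seed = 17)
  expect_true(all(vapply(ds, `[[`, character(1), "label") == "clear"))
  expect_true(all(vapply(ds, `[[`, character(1), "realized_label") == "clear"))
  ds2 <- generate_dataset(40, clear_fraction = 0.5, seed = 23)
  intended <- vapply(ds2, `[[`, character(1), "label")
  realized <- vapply(ds2, `[[`, character(1), "realized_label")
  expect_gte(mean(intended == realized, na.rm = TRUE), 0.95)
  # reproducible end to end
  ds3 <- generate_dataset(40, clear_fraction = 0.5, seed = 23)
  expect_identical(ds2[[3]]$image, ds3[[3]]$image)
  expect_identical(ds2[[40]]$tendon, ds3[[40]]$tendon)
})

test_that("series mode drifts smoothly between consecutive slices", {
  ds <- generate_dataset(30, clear_fraction = 1, seed = 31, series = TRUE)
  centroids <- t(vapply(ds, function(d) {
    w <- which(d$tendon == 1L, arr.ind = TRUE)
    colMeans(w)
  }, numeric(2)))
  steps <- sqrt(rowSums(diff(centroids)^2))
  expect_lte(max(steps), 3)
})
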