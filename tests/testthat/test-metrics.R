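# Region/contour metric definitions, closed-form examples, and edge-case
# policies.

sq_mask <- function(H, W, rows, cols) {
  m <- matrix(0L, H, W)
  m[rows, cols] <- 1L
  m
}

test_that("DSC matches direct pixel counting and handles degenerate inputs", {
  m <- sq_mask(10, 10, 3:6, 3:6)
  expect_identical(dsc(m, m), 1)
  expect_identical(dsc(sq_mask(10, 10, 1:2, 1:2), sq_mask(10, 10, 8:9, 8:9)), 0)
  # |X| = 4, |Y| = 4, overlap 2  ->  2*2 / 8
  x <- sq_mask(8, 8, 4, 2:5)
  y <- sq_mask(8, 8, 4, 4:7)
  expect_equal(dsc(x, y), 0.5)
  expect_error(dsc(sq_mask(4, 4, 1, 1), sq_mask(4, 5, 1, 1)), "shapes differ")
  expect_error(dsc(matrix(0L, 4, 4), matrix(0L, 4, 4)), "both masks empty")
  expect_identical(dsc(matrix(0L, 4, 4), sq_mask(4, 4, 2, 2)), 0)
})

test_that("contour extraction follows the inner-boundary convention", {
  one <- sq_mask(5, 5, 3, 3)
  expect_equal(extract_contour(one), cbind(row = 3L, col = 3L))
  sq <- sq_mask(7, 7, 3:5, 3:5)
  ct <- extract_contour(sq)
  expect_equal(nrow(ct), 8)                       # centre excluded
  expect_false(any(ct[, "row"] == 4 & ct[, "col"] == 4))
  line <- sq_mask(6, 9, 4, 2:8)
  expect_equal(nrow(extract_contour(line)), 7)    # every pixel touches background
  expect_error(extract_contour(matrix(0L, 3, 3)), "empty")
  # full-frame mask: image border counts as background
  full <- matrix(1L, 4, 5)
  expect_equal(nrow(extract_contour(full)), 2 * 4 + 2 * 5 - 4)
})

test_that("contour extraction agrees with a per-pixel neighbour scan", {
  set.seed(11)
  for (i in 1:10) {
    m <- random_blob_mask(24, 30)
    got <- extract_contour(m)
    want <- oracle_contour(m)
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 want[order(want[, 1], want[, 2]), , drop = FALSE])
  }
})

test_that("MAD and HD closed forms, symmetry and ordering", {
  a <- cbind(row = c(2L, 3L), col = c(2L, 3L))
  expect_equal(mad_contour(a, a), 0)
  expect_equal(hausdorff(a, a), 0)
  p1 <- cbind(row = 1L, col = 1L)
  p2 <- cbind(row = 1L, col = 6L)
  expect_equal(mad_contour(p1, p2), 5)
  expect_equal(hausdorff(p1, p2), 5)
  set.seed(21)
  for (i in 1:20) {
    a <- cbind(row = sample(1:40, 10, TRUE), col = sample(1:40, 10, TRUE))
    b <- cbind(row = sample(1:40, 12, TRUE), col = sample(1:40, 12, TRUE))
    expect_equal(mad_contour(a, b), mad_contour(b, a))
    expect_equal(hausdorff(a, b), hausdorff(b, a))
    expect_gte(hausdorff(a, b), mad_contour(a, b))
  }
  expect_error(mad_contour(a[0, , drop = FALSE], a), "empty")
})

test_that("Yasnoff closed form, asymmetry and image-size scaling", {
  b <- cbind(row = c(5L, 6L), col = c(5L, 5L))
  expect_equal(yasnoff(b, b, 100), 0)
  a <- cbind(row = 5L, col = 8L)                  # distance 3 from B
  expect_equal(yasnoff(a, b, 100), 3)
  expect_equal(yasnoff(a, b, 200), 1.5)           # doubling W halves it
  a2 <- rbind(a, cbind(row = 5L, col = 5L))
  expect_false(isTRUE(all.equal(yasnoff(a2, b, 100), yasnoff(b, a2, 100))))
  expect_error(yasnoff(a, b, 0), "positive")
})

test_that("artifact filter keeps the largest 8-connected component deterministically", {
  m <- sq_mask(20, 20, 3:12, 3:12)
  m[17, 17] <- 1L
  f <- filter_artifacts(m)
  expect_equal(sum(f), 100)
  expect_equal(f[17, 17], 0L)
  single <- sq_mask(10, 10, 2:4, 2:4)
  expect_identical(filter_artifacts(single), single)
  # diagonal touch is 8-connected: nothing removed
  diagm <- matrix(0L, 6, 6); diagm[2, 2] <- 1L; diagm[3, 3] <- 1L
  expect_identical(filter_artifacts(diagm), diagm)
  # equal-size tie: the component first reached in raster order wins
  tie <- matrix(0L, 10, 10)
  tie[2:3, 2:3] <- 1L
  tie[7:8, 7:8] <- 1L
  f1 <- filter_artifacts(tie)
  expect_equal(sum(f1), 4)
  expect_equal(f1[2, 2], 1L)
  expect_identical(f1, filter_artifacts(tie))
  expect_error(filter_artifacts(matrix(0L, 3, 3)), "empty")
})

test_that("CHD is near zero for convex regions and tracks notch depth", {
  rect <- sq_mask(40, 60, 10:30, 15:45)
  expect_lte(chd(rect), 1)
  notch <- function(depth) {
    m <- sq_mask(40, 60, 10:30, 15:45)
    m[10:(10 + depth - 1), 28:32] <- 0L
    m
  }
  expect_equal(chd(notch(10)), 10, tolerance = 0.1)
  depths <- c(2, 4, 8)
  vals <- vapply(depths, function(d) chd(notch(d)), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_error(chd(matrix(0L, 4, 4)), "empty")
})

test_that("all metrics are invariant under joint translation", {
  set.seed(31)
  base_p <- random_blob_mask(30, 30)
  base_t <- random_blob_mask(30, 30)
  embed <- function(m, dr, dc) {
    out <- matrix(0L, 50, 50)
    out[dr + seq_len(nrow(m)), dc + seq_len(ncol(m))] <- m
    out
  }
  r0 <- evaluate_pair(embed(base_p, 3, 3), embed(base_t, 3, 3))
  r1 <- evaluate_pair(embed(base_p, 12, 9), embed(base_t, 12, 9))
  for (f in c("dsc", "mad", "hd", "yasnoff", "chd"))
    expect_equal(r0[[f]], r1[[f]], tolerance = 1e-12)
})

test_that("evaluate_pair applies artifact filtering to HD/CHD only", {
  truth <- sq_mask(32, 32, 8:24, 8:24)
  pred <- truth
  r <- evaluate_pair(pred, truth)
  expect_equal(r$dsc, 1)
  expect_equal(r$mad, 0)
  expect_equal(r$hd, 0)
  expect_equal(r$yasnoff, 0)
  expect_equal(r$chd, chd(truth))
  # an isolated 1-px artifact changes DSC/MAD/Yasnoff but not HD/CHD
  noisy <- pred
  noisy[2, 30] <- 1L
  rn <- evaluate_pair(noisy, truth)
  expect_equal(rn$hd, r$hd)
  expect_equal(rn$chd, r$chd)
  expect_lt(rn$dsc, 1)
  expect_gt(rn$mad, 0)
})

test_that("empty predictions score DSC 0 and flag contour metrics as missing", {
  truth <- sq_mask(16, 16, 5:10, 5:10)
  expect_warning(r <- evaluate_pair(matrix(0L, 16, 16), truth), "empty prediction")
  expect_equal(r$dsc, 0)
  expect_true(all(is.na(c(r$mad, r$hd, r$yasnoff, r$chd))))
})

test_that("batch aggregation equals the arithmetic mean of per-image rows", {
  set.seed(41)
  preds <- lapply(1:4, function(i) random_blob_mask(24, 24))
  truths <- lapply(1:4, function(i) random_blob_mask(24, 24))
  tab <- evaluate_batch(preds, truths)
  expect_equal(nrow(tab), 6)
  per <- tab[1:4, ]
  expect_equal(tab$dsc[tab$image_id == "mean"], mean(per$dsc))
  expect_equal(tab$hd[tab$image_id == "sd"], sd(per$hd))
})
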