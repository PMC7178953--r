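# Independent brute-force oracles for the contour metrics and the
# dilated convolution. These deliberately use naive per-point scans and
# direct summation -- a different route from the package's vectorised
# implementations -- so agreement is an actual cross-check.

oracle_min_dists <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    best <- Inf
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
      if (d < best) best <- d
    }
    best
  }, numeric(1))
}

oracle_mad <- function(a, b) {
  (mean(oracle_min_dists(a, b)) + mean(oracle_min_dists(b, a))) / 2
}

oracle_hd <- function(a, b) {
  max(max(oracle_min_dists(a, b)), max(oracle_min_dists(b, a)))
}

oracle_yasnoff <- function(a, b, W) {
  100 / W * sqrt(sum(oracle_min_dists(a, b)^2))
}

oracle_contour <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pts <- NULL
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    if (mask[r, cc] == 0) next
    nb <- c(if (r > 1) mask[r - 1, cc] else 0L,
            if (r < H) mask[r + 1, cc] else 0L,
            if (cc > 1) mask[r, cc - 1] else 0L,
            if (cc < W) mask[r, cc + 1] else 0L)
    if (any(nb == 0)) pts <- rbind(pts, c(r, cc))
  }
  colnames(pts) <- c("row", "col")
  pts
}

# Gift-wrapping convex hull of (row, col) points, returned as ordered
# polygon vertices.
oracle_hull <- function(pts) {
  pts <- unique(pts[, 1:2, drop = FALSE])
  n <- nrow(pts)
  if (n <= 2) return(pts)
  x <- pts[, 2]; y <- pts[, 1]
  start <- which.min(x + y * 1e-9)
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (cur == 1) 2 else 1
    for (j in seq_len(n)) {
      if (j == cur) next
      cr <- (x[cand] - x[cur]) * (y[j] - y[cur]) - (y[cand] - y[cur]) * (x[j] - x[cur])
      d_cand <- (x[cand] - x[cur])^2 + (y[cand] - y[cur])^2
      d_j <- (x[j] - x[cur])^2 + (y[j] - y[cur])^2
      if (cr < -1e-9 || (abs(cr) <= 1e-9 && d_j > d_cand)) cand <- j
    }
    cur <- cand
    if (cur == start) break
    if (length(hull) > n) stop("gift wrapping failed to terminate")
  }
  pts[hull, , drop = FALSE]
}

# Fill the convex hull over pixel centers by half-plane tests.
oracle_hull_mask <- function(mask) {
  pts <- oracle_contour(mask)
  poly <- oracle_hull(pts)
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0L, H, W)
  nv <- nrow(poly)
  if (nv <= 2) {
    out[poly] <- 1L
    out[mask == 1L] <- 1L
    return(out)
  }
  px <- poly[, 2]; py <- poly[, 1]
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    inside <- TRUE
    for (e in seq_len(nv)) {
      e2 <- if (e == nv) 1 else e + 1
      cr <- (px[e2] - px[e]) * (r - py[e]) - (py[e2] - py[e]) * (cc - px[e])
      if (cr < -1e-9) { inside <- FALSE; break }
    }
    if (inside) out[r, cc] <- 1L
  }
  out[mask == 1L] <- 1L
  out
}

oracle_chd <- function(mask) {
  a <- oracle_contour(mask)
  cc <- oracle_contour(oracle_hull_mask(mask))
  oracle_hd(a, cc)
}

# Direct summation of the dilated discrete convolution
# (F *_l k)(p) = sum_{s + l t = p} F(s) k(t), zero outside the image.
oracle_dilated_conv <- function(f, k, l) {
  H <- nrow(f); W <- ncol(f)
  r <- (nrow(k) - 1) %/% 2
  out <- matrix(0, H, W)
  for (pr in seq_len(H)) for (pc in seq_len(W)) {
    acc <- 0
    for (tr in -r:r) for (tc in -r:r) {
      sr <- pr - l * tr; sc <- pc - l * tc
      if (sr >= 1 && sr <= H && sc >= 1 && sc <= W)
        acc <- acc + f[sr, sc] * k[tr + r + 1, tc + r + 1]
    }
    out[pr, pc] <- acc
  }
  out
}

# Random soft-tissue-like test mask: union of a few random ellipses,
# guaranteed nonempty.
random_blob_mask <- function(H, W, n_blobs = 2) {
  m <- matrix(0L, H, W)
  for (b in seq_len(n_blobs)) {
    cy <- runif(1, 0.2 * H, 0.8 * H); cx <- runif(1, 0.2 * W, 0.8 * W)
    ay <- runif(1, 0.08 * H, 0.25 * H); ax <- runif(1, 0.08 * W, 0.25 * W)
    rg <- matrix(seq_len(H), H, W); cg <- matrix(seq_len(W), H, W, byrow = TRUE)
    m <- m | (((rg - cy) / ay)^2 + ((cg - cx) / ax)^2 <= 1)
  }
  m <- matrix(as.integer(m), H, W)
  if (sum(m) == 0L) m[round(H / 2), round(W / 2)] <- 1L
  m
}
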