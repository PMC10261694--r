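# Independent brute-force oracles used across the test files. These are
# deliberately written as direct double loops / explicit sums, independent of
# the package's implementation paths.

# symmetric (edge-duplicating) reflection of a 1-based index
oracle_reflect <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# brute-force non-local means on one slice (double loop over pixels and
# search offsets), uniform or supplied patch weights
oracle_nlm <- function(img, patch, search, h, self_rule = "self-zero",
                       patch_w = NULL) {
  H <- nrow(img); W <- ncol(img)
  pr <- (patch - 1) / 2; sr <- (search - 1) / 2
  if (is.null(patch_w)) patch_w <- rep(1 / patch^2, patch^2)
  out <- matrix(0, H, W)
  at <- function(r, c) img[oracle_reflect(r, H), oracle_reflect(c, W)]
  for (r in seq_len(H)) for (c in seq_len(W)) {
    ws <- numeric(0); vs <- numeric(0); self <- NA_integer_
    m <- 0L
    for (ds in -sr:sr) for (dt in -sr:sr) {
      d2 <- 0; pw <- 1L
      for (u in -pr:pr) for (v in -pr:pr) {
        d2 <- d2 + patch_w[pw] * (at(r + u, c + v) -
                                    at(r + ds + u, c + dt + v))^2
        pw <- pw + 1L
      }
      m <- m + 1L
      ws[m] <- exp(-d2 / h^2)
      vs[m] <- at(r + ds, c + dt)
      if (ds == 0 && dt == 0) self <- m
    }
    if (self_rule == "max-neighbor") ws[self] <- max(ws[-self], 0)
    out[r, c] <- if (sum(ws) > 0) sum(ws * vs) / sum(ws) else img[r, c]
  }
  out
}

# box mean over the search window with symmetric reflection (NLM h -> Inf)
oracle_box_mean <- function(img, search) {
  H <- nrow(img); W <- ncol(img)
  sr <- (search - 1) / 2
  out <- matrix(0, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    acc <- 0
    for (ds in -sr:sr) for (dt in -sr:sr)
      acc <- acc + img[oracle_reflect(r + ds, H), oracle_reflect(c + dt, W)]
    out[r, c] <- acc / search^2
  }
  out
}

# explicit-sum mean / sample SD / CV
oracle_stats <- function(v) {
  n <- length(v)
  s <- 0
  for (x in v) s <- s + x
  m <- s / n
  q <- 0
  for (x in v) q <- q + (x - m)^2
  sdv <- sqrt(q / (n - 1))
  list(mean = m, sd = sdv, cv = if (m > 0) sdv / m * 100 else NA_real_)
}

# enumerate pixels whose centres fall within diameter/2 of a centre pixel
oracle_circle_pixels <- function(center_rc, diameter_mm, voxel_mm) {
  rad <- diameter_mm / 2
  out <- NULL
  m <- ceiling(rad / voxel_mm) + 1L
  for (dr in -m:m) for (dc in -m:m)
    if ((dr^2 + dc^2) * voxel_mm^2 <= rad^2)
      out <- rbind(out, c(center_rc[1] + dr, center_rc[2] + dc))
  out
}

# a small phantom spec sized for fast tests
small_spec <- function(...) {
  phantom_spec(n_slices = 24, slice_shape = c(48, 48),
               gland_texture_sigma = 5, ...)
}
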