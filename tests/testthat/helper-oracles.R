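# Independent oracles used across the suite. These deliberately take the
# slow, literal route (double loops, exhaustive scans) so they share no code
# with the implementation they check.

# O(N^4) direct 2-D DFT -> centered power grid, matching the package
# convention: mean subtraction, quadrant shift, squared magnitude.
naive_dft_power <- function(px) {
  n <- nrow(px); m <- ncol(px)
  f <- px - mean(px)
  P <- matrix(0, n, m)
  for (u in 0:(n - 1)) for (v in 0:(m - 1)) {
    acc <- 0 + 0i
    for (x in 0:(n - 1)) for (y in 0:(m - 1)) {
      acc <- acc + f[x + 1, y + 1] * exp(-2i * pi * (u * x / n + v * y / m))
    }
    P[u + 1, v + 1] <- Mod(acc)^2
  }
  idx_r <- c((n / 2 + 1):n, 1:(n / 2))
  idx_c <- c((m / 2 + 1):m, 1:(m / 2))
  P[idx_r, idx_c]
}

# exhaustive Otsu: scan all 256 candidate levels, computing class means
# directly from the binned pixel values
otsu_oracle <- function(px) {
  bins <- pmin(pmax(floor(px), 0), 255)
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:255) {
    lo <- bins[bins < t]; hi <- bins[bins >= t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(bins); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# brute-force 8-connected labeling by breadth-first flood fill
flood_fill_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
            mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- cur
          queue[[length(queue) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# type-7 quantile by explicit sort-and-interpolate
quantile_oracle <- function(x, p) {
  s <- sort(x); n <- length(s)
  hpos <- (n - 1) * p + 1
  lo <- floor(hpos); hi <- ceiling(hpos)
  s[lo] + (hpos - lo) * (s[hi] - s[lo])
}

# all-pairs concordance count AUC
auc_oracle <- function(pos, neg) {
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# seeded random byte image
random_gray <- function(h, w, seed) {
  withr::with_seed(seed, {
    gray_image(matrix(as.numeric(sample(0:255, h * w, replace = TRUE)), h, w))
  })
}

# separable texture crops for CNN fixtures: dark vs bright speckle
speckle_crop <- function(mean_level, seed, h = 100, w = 140) {
  withr::with_seed(seed, {
    px <- pmin(255, pmax(0, mean_level * stats::rgamma(h * w, 4, 4)))
    dim(px) <- c(h, w)
    gray_image(px)
  })
}
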