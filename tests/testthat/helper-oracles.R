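# Independent brute-force oracles used to cross-check the vectorized
# implementations. Deliberately naive: queue-based flood fill, exhaustive
# threshold scans, sort-and-sum statistics.

# Queue-based BFS flood fill labeling (grassfire from each unvisited seed).
bfs_label_oracle <- function(binary, connectivity = 8) {
  fg <- binary != 0
  nr <- nrow(fg)
  nc <- ncol(fg)
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
         c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  }
  lab <- matrix(0L, nr, nc)
  nextlab <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!fg[r0, c0] || lab[r0, c0] > 0) next
    nextlab <- nextlab + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nextlab
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      for (o in offs) {
        r <- p[1] + o[1]
        c <- p[2] + o[2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            fg[r, c] && lab[r, c] == 0) {
          lab[r, c] <- nextlab
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  list(labels = lab, n_components = nextlab)
}

# Exhaustive Otsu: evaluate between-class variance at every threshold t,
# classes {x < t} and {x >= t}; first argmax.
otsu_exhaustive_oracle <- function(values) {
  best_t <- NA_integer_
  best_v <- -Inf
  for (t in 1:255) {
    lo <- values[values < t]
    hi <- values[values >= t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(values)
    v <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) {
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

# Sort-and-sum ROI statistics (population SD, type-7 quantiles).
roi_stats_oracle <- function(values) {
  v <- sort(as.numeric(values))
  n <- length(v)
  qt <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[min(lo + 1, n)] - v[lo])
  }
  list(minimum = v[1], maximum = v[n],
       mean = round(sum(v) / n, 2),
       sd = round(sqrt(sum((v - sum(v) / n)^2) / n), 2),
       median = qt(0.5), q1 = qt(0.25), q3 = qt(0.75), n_pixels = n)
}

# Transitive closure of the |g(p) - g(q)| <= th relation over 8-neighbor
# pairs, grown from the seed set by BFS over all pixels.
edge_closure_oracle <- function(grad, th, seed_quantile = 0.9) {
  g <- grad
  if (max(g) > 0) g <- g * (255 / max(g))
  nz <- g[g > 0]
  if (!length(nz)) return(matrix(FALSE, nrow(g), ncol(g)))
  seed_level <- stats::quantile(nz, seed_quantile, names = FALSE)
  nr <- nrow(g)
  nc <- ncol(g)
  mask <- g >= seed_level
  queue <- which(mask)
  while (length(queue)) {
    idx <- queue[1]
    queue <- queue[-1]
    r0 <- (idx - 1) %% nr + 1
    c0 <- (idx - 1) %/% nr + 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r <- r0 + dr
      c <- c0 + dc
      if (r >= 1 && r <= nr && c >= 1 && c <= nc && !mask[r, c] &&
          abs(g[r0, c0] - g[r, c]) <= th) {
        mask[r, c] <- TRUE
        queue <- c(queue, (c - 1) * nr + r)
      }
    }
  }
  mask
}

# Brute-force histogram-equalization lookup from the 256-bin CDF.
cdf_equalize_oracle <- function(image) {
  n <- length(image)
  lut <- integer(256)
  for (v in 0:255) {
    lut[v + 1] <- floor(255 * sum(image <= v) / n + 0.5)
  }
  matrix(lut[image + 1], nrow(image), ncol(image))
}

iou <- function(a, b) sum(a & b) / sum(a | b)

random_raster <- function(nr = 32, nc = 32, p = 0.4) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

random_image <- function(nr = 24, nc = 24) {
  matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc)
}
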